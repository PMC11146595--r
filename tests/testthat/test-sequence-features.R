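test_that("transcripts normalize T to U and validate their alphabet", {
  tx <- transcript("t", "acgtACGT")
  expect_identical(tx$sequence, "ACGUACGU")
  expect_identical(tx$length, 8L)
  expect_error(transcript("t", "ACGN"), "invalid characters")
  expect_error(transcript("", "ACG"), "non-empty")
})

test_that("start-site scanning matches literal and brute-force expectations", {
  expect_identical(find_start_sites(transcript("t", "AUGUAA"), "AUG"),
                   data.frame(position = 0L, codon = "AUG", frame = 0L,
                              stringsAsFactors = FALSE))
  expect_identical(nrow(find_start_sites(transcript("t", "CCCCCC"),
                                         c("AUG", "CUG"))), 0L)
  got <- find_start_sites(transcript("t", "CCAUGGCCUAGCC"), "AUG")
  expect_identical(got$position, 2L)
  expect_identical(got$frame, 2L)
  expect_error(find_start_sites(transcript("t", "AUG"), character(0)),
               "non-empty")
  expect_error(find_start_sites(transcript("t", "AUG"), "AX"), "3-mers")
})

test_that("start-site scanning agrees with the sliding-window oracle", {
  set.seed(41)
  for (i in 1:25) {
    tx <- transcript("r", random_sequence(sample(30:300, 1)))
    codons <- sample(c("AUG", "CUG", "GUG"), sample(1:3, 1))
    got <- find_start_sites(tx, codons)
    want <- oracle_start_sites(tx$sequence, codons)
    expect_identical(got$position, want$position)
    expect_identical(got$codon, want$codon)
  }
})

test_that("start-stop ORFs pair starts with nearest in-frame stops", {
  one <- find_orfs(transcript("t", "AUGUAA"), "START_STOP")
  expect_identical(one$start, 0L)
  expect_identical(one$end, 6L)
  expect_identical(one$frame, 0L)
  got <- find_orfs(transcript("t", "CCAUGGCCUAGCC"), "START_STOP")
  expect_identical(got$start, 2L)
  expect_identical(got$end, 11L)     # includes the stop codon
  expect_identical((got$end - got$start) / 3 - 1, 2)  # peptide codons
  expect_false(got$open_ended)
  # no in-frame stop: retained and flagged
  open <- find_orfs(transcript("t", "AUGAAAAA"), "START_STOP")
  expect_true(open$open_ended)
  expect_identical(open$end, 6L)     # last complete in-frame codon
})

test_that("stop-stop ORFs are maximal stop-free stretches per frame", {
  got <- find_orfs(transcript("t", "CCAUGGCCUAGCC"), "STOP_STOP")
  f2 <- got[got$frame == 2L, ]
  expect_identical(f2$start, 2L)
  expect_identical(f2$end, 11L)      # bounded above by the UAG at 8
  expect_true(all(is.na(got$start_codon)))
  # frames without stops span the whole frame, flagged open-ended
  expect_true(all(got$open_ended[got$frame != 2L]))
})

test_that("every start-stop ORF is contained in a stop-stop ORF", {
  set.seed(42)
  for (i in 1:20) {
    tx <- transcript("r", random_sequence(sample(60:300, 1)))
    ss <- find_orfs(tx, "START_STOP", start_codons = c("AUG", "CUG"))
    qq <- find_orfs(tx, "STOP_STOP")
    for (j in seq_len(nrow(ss))) {
      host <- qq[qq$frame == ss$frame[j] & qq$start <= ss$start[j] &
                   qq$end >= ss$end[j], ]
      expect_gte(nrow(host), 1L)
    }
  }
})

test_that("start-stop scanning agrees with the brute-force oracle", {
  set.seed(43)
  for (i in 1:20) {
    tx <- transcript("r", random_sequence(sample(30:300, 1)))
    got <- find_orfs(tx, "START_STOP", start_codons = c("AUG", "CUG"))
    want <- oracle_start_stop_orfs(tx$sequence, c("AUG", "CUG"))
    expect_identical(got$start, want$start)
    expect_identical(got$end, want$end)
    expect_identical(got$open_ended, want$open_ended)
  }
})

test_that("next_in_frame_stop scans only the requested frame", {
  expect_identical(next_in_frame_stop(transcript("t", "AUGUAA"), 0, 0), 3L)
  expect_null(next_in_frame_stop(transcript("t", "AUGAAA"), 0, 0))
  expect_identical(next_in_frame_stop(transcript("t", "CCAUGGCCUAGCC"),
                                      2, 2L), 8L)
  # the same stop is invisible from another frame
  expect_null(next_in_frame_stop(transcript("t", "CCAUGGCCUAGCC"), 0, 0L))
})

test_that("Kozak context score is the consensus match fraction", {
  expect_equal(context_score(transcript("t", "GCCGCCAUGG"), 6), 1.0)
  # hand count: AGCAUC|AUG|C matches at -4, -3, -1 only -> 3/7
  expect_equal(context_score(transcript("t", "AGCAUCAUGC"), 6), 3 / 7)
  # start at position 0: only +4 is available (G matches)
  expect_equal(context_score(transcript("t", "AUGGCC"), 0), 1 / 7)
  expect_error(context_score(transcript("t", "AUG"), 2), "outside")
})

test_that("BED export writes one line per feature with scaled scores", {
  tx <- transcript("tx9", "GCCGCCAUGGAAUAA")
  sites <- find_start_sites(tx, "AUG", score_context = TRUE)
  path <- withr::local_tempfile()
  features_to_bed(sites, tx, path)
  bed <- read.table(path, sep = "\t")
  expect_identical(bed$V1, "tx9")
  expect_identical(bed$V2, 6L)
  expect_identical(bed$V3, 9L)
  expect_identical(bed$V5, 1000L)
  expect_identical(bed$V6, "+")
})
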