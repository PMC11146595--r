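test_that("variant application edits the sequence and validates ref", {
  tx <- transcript("t", "AUGUAA")
  ins <- apply_variant(tx, variant_spec("t", 3, "", "C"))
  expect_identical(ins$sequence, "AUGCUAA")
  expect_identical(ins$length, tx$length + 1L)
  del <- apply_variant(tx, variant_spec("t", 3, "UAA", ""))
  expect_identical(del$sequence, "AUG")
  expect_error(apply_variant(tx, variant_spec("t", 0, "C", "G")),
               "ref mismatch")
  expect_error(variant_spec("t", 0, "", ""), "not an edit")
  expect_error(apply_variant(tx, variant_spec("other", 0, "A", "G")),
               "targets")
})

test_that("applying the inverse edit restores the original sequence", {
  set.seed(404)
  for (i in 1:15) {
    tx <- transcript("t", random_sequence(60))
    p <- sample(0:50, 1)
    v <- if (runif(1) < 0.5) {
      variant_spec("t", p, "", random_sequence(sample(1:3, 1)))
    } else {
      variant_spec("t", p, substr(tx$sequence, p + 1, p + sample(1:3, 1)),
                   "")
    }
    edited <- apply_variant(tx, v)
    inverse <- variant_spec(edited$id, v$position, v$alt, v$ref)
    expect_identical(apply_variant(edited, inverse)$sequence, tx$sequence)
  }
})

test_that("an SNV outside every feature leaves the rebuilt graph isomorphic", {
  fx <- make_variant_fixture()
  g <- build_rdg(fx$transcript, fx$events, fx$policy)
  # synonymous-site SNV in filler sequence far from starts and stops
  snv <- variant_spec(fx$transcript$id, 51, "G", "C")
  rb <- rebuild_after_variant(fx$transcript, snv, fx$events)
  vg <- build_rdg(rb$transcript, rb$events, fx$policy)
  expect_identical(g$nodes, vg$nodes)
  expect_identical(g$edges, vg$edges)
  d <- diff_rdg(g, vg, variant = snv, cds_translon = "T3")
  expect_length(d$translons_lost, 0L)
  expect_length(d$translons_gained, 0L)
  expect_identical(nrow(d$translons_modified), 0L)
  expect_true(d$cds_reachable_after)
})

test_that("the diff of a graph with itself is empty", {
  set.seed(405)
  for (i in 1:10) {
    g <- random_rdg()
    d <- diff_rdg(g, g)
    expect_length(d$translons_lost, 0L)
    expect_length(d$translons_gained, 0L)
    expect_identical(nrow(d$translons_modified), 0L)
    expect_length(d$branches_lost, 0L)
  }
})

test_that("the insertion fixture reproduces the leader-extension outcome", {
  fx <- make_variant_fixture()
  g <- build_rdg(fx$transcript, fx$events, fx$policy)
  expect_gt(length(paths_containing(g, fx$cds_translon)), 0)
  rb <- rebuild_after_variant(fx$transcript, fx$variant, fx$events)
  # the insertion introduces one additional AUG upstream of the CDS
  expect_identical(find_start_sites(rb$transcript, "AUG")$position,
                   c(6L, 18L, 23L, 61L))
  vg <- build_rdg(rb$transcript, rb$events, fx$policy)
  expect_valid_rdg(vg)
  d <- diff_rdg(g, vg, variant = fx$variant, cds_translon = fx$cds_translon)
  expect_true(d$cds_reachable_before)
  expect_false(d$cds_reachable_after)
  # both leader translons are strictly extended
  expect_setequal(d$translons_modified$ref_id[
    d$translons_modified$change == "EXTENDED"], c("T1", "T2"))
  ref_len <- translon_table(g)
  var_len <- translon_table(vg)
  for (i in seq_len(nrow(d$translons_modified))) {
    expect_gt(var_len[d$translons_modified$var_id[i], "length_nt"],
              ref_len[d$translons_modified$ref_id[i], "length_nt"])
  }
})

test_that("a stop-destroying deletion is reported as an extension", {
  tx <- transcript("t", paste0("GGC", "AUG", strrep("GGA", 3), "UAA",
                               strrep("GGA", 4), "UAG", "GGC"))
  ev <- list(initiation_event(3))
  g <- build_rdg(tx, ev)
  v <- variant_spec("t", 15, "UAA", "")
  rb <- rebuild_after_variant(tx, v, ev)
  vg <- build_rdg(rb$transcript, rb$events, reinitiation_policy())
  d <- diff_rdg(g, vg, variant = v)
  expect_identical(d$translons_modified$change, "EXTENDED")
})

test_that("translon boundaries downstream of an indel shift by its length", {
  fx <- make_fig3_transcript()
  g <- build_rdg(fx$transcript, fx$events, fx$policy)
  # 3-nt insertion in the spacer between T1's stop and the main start:
  # frames are preserved, every downstream boundary moves by +3
  v <- variant_spec(fx$transcript$id, 19, "", "CCC")
  rb <- rebuild_after_variant(fx$transcript, v, fx$events,
                              start_codons = c("AUG", "CUG"))
  vg <- build_rdg(rb$transcript, rb$events, fx$policy)
  ref <- translon_table(g)
  var <- translon_table(vg)
  expect_identical(nrow(var), nrow(ref))
  for (id in ref$id) {
    shift_start <- if (ref[id, "start"] > 19) 3L else 0L
    shift_end <- if (ref[id, "end"] > 19) 3L else 0L
    expect_identical(var[id, "start"], ref[id, "start"] + shift_start)
    expect_identical(var[id, "end"], ref[id, "end"] + shift_end)
  }
})

test_that("events whose codons are destroyed are dropped with a warning", {
  fx <- make_readthrough_transcript()
  v <- variant_spec(fx$transcript$id, 36, "UGA", "UGG")
  expect_warning(rb <- rebuild_after_variant(fx$transcript, v, fx$events),
                 "SELENOCYSTEINE")
  expect_length(Filter(function(e) e$kind == "SELENOCYSTEINE", rb$events),
                0L)
})

test_that("variant files round-trip through TSV and minimal VCF", {
  vs <- list(variant_spec("tx1", 24, "", "U"),
             variant_spec("tx1", 40, "GG", "A"))
  path <- withr::local_tempfile()
  write_variants(vs, path)
  back <- read_variants(path)
  for (i in seq_along(vs)) {
    expect_identical(back[[i]]$position, vs[[i]]$position)
    expect_identical(back[[i]]$ref, vs[[i]]$ref)
    expect_identical(back[[i]]$alt, vs[[i]]$alt)
  }
  vcf <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT",
               "tx1\t25\t.\tA\tAT"), vcf)
  v <- read_variants(vcf)[[1]]
  expect_identical(v$position, 25L)  # anchored insertion after 1-based 25
  expect_identical(v$ref, "")
  expect_identical(v$alt, "U")
})
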