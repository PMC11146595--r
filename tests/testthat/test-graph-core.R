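test_that("event constructors validate their payloads", {
  expect_error(initiation_event(-1), "non-negative")
  expect_error(frameshift_event(10, 2), "\\+1 or -1")
  expect_error(initiation_event(0, "AUG", probability = 1.5), "\\[0, 1\\]")
  tx <- transcript("t", "AUGUAA")
  expect_error(build_rdg(tx, list(initiation_event(3, "AUG"))),
               "expects codon AUG")
  expect_error(build_rdg(tx, list(selenocysteine_event(0))), "requires UGA")
  expect_error(build_rdg(tx, list(readthrough_event(0))),
               "requires a stop codon")
})

test_that("a single leaky start yields the minimal two-path graph", {
  tx <- transcript("t", paste0("GGC", "AUG", "GGAGGA", "UAA", "GGC"))
  g <- build_rdg(tx, list(initiation_event(3)), reinitiation_policy())
  expect_valid_rdg(g)
  expect_identical(nrow(branch_nodes(g)), 1L)
  expect_length(g$translons, 1L)
  expect_identical(count_paths(g), 2)
  expect_length(translons(g), 1L)
})

test_that("a graph with no events has one unproductive path and no translons", {
  tx <- transcript("t", "GGCGGCGGC")
  g <- build_rdg(tx, list())
  expect_valid_rdg(g)
  expect_length(translons(g), 0L)
  p <- enumerate_paths(g)
  expect_length(p, 1L)
  expect_false(p[[1]]$productive)
})

test_that("the three-start worked example builds the published topology", {
  fx <- make_fig3_transcript()
  g <- build_rdg(fx$transcript, fx$events, fx$policy)
  expect_valid_rdg(g)
  expect_length(g$translons, 3L)
  bn <- branch_nodes(g)
  expect_identical(sum(bn$kind == "BRANCH_INIT"), 3L)
  expect_identical(sum(bn$kind == "BRANCH_REINIT"), 1L)
  tt <- translon_table(g)
  # T3 is an N-terminal extension of T2: same stop, earlier start
  expect_identical(tt["T3", "terminal_stop"], tt["T2", "terminal_stop"])
  expect_lt(tt["T3", "start"], tt["T2", "start"])
  # only T1 is short enough to allow reinitiation
  expect_true(tt["T1", "length_nt"] <= fx$policy$max_translon_nt)
  expect_true(all(tt[c("T2", "T3"), "length_nt"] >
                    fx$policy$max_translon_nt))
})

test_that("readthrough events split a translon into two variants sharing a start", {
  fx <- make_readthrough_transcript()
  g <- build_rdg(fx$transcript, fx$events, fx$policy)
  expect_valid_rdg(g)
  tt <- translon_table(g)
  expect_identical(nrow(tt), 2L)
  expect_identical(tt$start[1], tt$start[2])
  expect_false(tt$end[1] == tt$end[2])
  # the extended variant records the recoded stop it reads through
  tl <- translons(g)
  ext <- tl[[which.max(tt$end)]]
  expect_identical(ext$includes_stops,
                   tl[[which.min(tt$end)]]$terminal_stop)
})

test_that("frameshift events produce a two-segment trans-frame translon", {
  fx <- make_frameshift_transcript()
  g <- build_rdg(fx$transcript, fx$events, fx$policy)
  expect_valid_rdg(g)
  tl <- translons(g)
  nseg <- vapply(tl, function(t) nrow(t$segments), integer(1))
  expect_identical(sum(nseg == 2L), 1L)
  fs <- tl[[which(nseg == 2L)]]
  expect_false(fs$segments$frame[1] == fs$segments$frame[2])
  # -1 slip: second segment starts one nucleotide before the first ends
  expect_identical(fs$segments$start[2], fs$segments$end[1] - 1L)
})

test_that("deterministic starts end the scanning route and prune downstream events", {
  tx <- transcript("t", paste0("GGC", "AUG", "GGA", "AUG", strrep("GGA", 4),
                               "UAA", "GGC"))
  ev <- list(initiation_event(3, probability = 1), initiation_event(9))
  g <- build_rdg(tx, ev)
  expect_valid_rdg(g)
  expect_length(g$translons, 1L)   # the AUG at 9 is never reached
  expect_identical(count_paths(g), 1)
  p <- enumerate_paths(g)
  expect_true(p[[1]]$productive)
})

test_that("rebuilding from identical inputs is bit-stable", {
  fx <- make_fig3_transcript()
  a <- build_rdg(fx$transcript, fx$events, fx$policy)
  b <- build_rdg(fx$transcript, fx$events, fx$policy)
  expect_identical(a$nodes, b$nodes)
  expect_identical(a$edges, b$edges)
  expect_identical(translon_table(a), translon_table(b))
})

test_that("k initiation events without reinitiation give k branches and k translons", {
  set.seed(7)
  for (k in c(1L, 3L, 6L)) {
    g <- chain_fixture(k)
    expect_valid_rdg(g)
    expect_identical(nrow(branch_nodes(g)), k)
    expect_length(g$translons, k)
  }
})

test_that("random graphs always satisfy the structural invariants", {
  set.seed(101)
  for (i in 1:40) expect_valid_rdg(random_rdg())
})

test_that("validate_rdg reports injected violations by node id", {
  fx <- make_fig3_transcript()
  g <- build_rdg(fx$transcript, fx$events, fx$policy)
  cyc <- g
  cyc$edges <- rbind(cyc$edges, within(cyc$edges[1, ], {
    id <- "e999"; from <- "exit"; to <- "entry"; kind <- "SCAN"
    role <- NA_character_; translon <- NA_character_
    probability <- NA_real_
  }))
  v <- validate_rdg(cyc)
  expect_true(any(grepl("^ACYCLICITY", v)))
  tri <- g
  extra <- tri$edges[tri$edges$from == "init@6" & tri$edges$role == "commit", ]
  extra$id <- "e998"
  tri$edges <- rbind(tri$edges, extra)
  expect_true(any(grepl("^BRANCH_ARITY: init@6", validate_rdg(tri))))
})

test_that("co-located elongation events in one codon are rejected", {
  fx <- make_readthrough_transcript()
  ev <- c(fx$events, list(readthrough_event(36)))
  expect_error(build_rdg(fx$transcript, ev, fx$policy), "same codon")
})

test_that("event files round-trip through the BED6-like dialect", {
  fx <- make_fig3_transcript()
  path <- withr::local_tempfile()
  write_events(fx$events, fx$transcript$id, path)
  back <- read_events(path)
  expect_length(back, 3L)
  for (i in seq_along(back)) {
    expect_identical(back[[i]]$position, fx$events[[i]]$position)
    expect_identical(back[[i]]$kind, fx$events[[i]]$kind)
    expect_identical(back[[i]]$name, fx$events[[i]]$name)
  }
  g1 <- build_rdg(fx$transcript, fx$events, fx$policy)
  g2 <- build_rdg(fx$transcript, back, fx$policy)
  expect_identical(g1$edges, g2$edges)
})
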