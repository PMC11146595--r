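# Independent oracles and random-case generators shared across the suite.

# Brute-force sliding-window codon scan, independent of the package's
# vectorized scanner.
oracle_start_sites <- function(sequence, codons) {
  hits <- integer(0)
  found <- character(0)
  n <- nchar(sequence)
  for (p in seq_len(max(n - 2L, 0L))) {
    w <- substr(sequence, p, p + 2L)
    if (w %in% codons) {
      hits <- c(hits, p - 1L)
      found <- c(found, w)
    }
  }
  data.frame(position = hits, codon = found, frame = hits %% 3L,
             stringsAsFactors = FALSE)
}

# Brute-force start-stop ORF scan: for every start occurrence walk codon by
# codon to the first stop.
oracle_start_stop_orfs <- function(sequence, start_codons,
                                   stop_codons = c("UAA", "UAG", "UGA")) {
  n <- nchar(sequence)
  starts <- oracle_start_sites(sequence, start_codons)
  recs <- lapply(seq_len(nrow(starts)), function(i) {
    s <- starts$position[i]
    p <- s + 3L
    while (p + 3L <= n) {
      if (substr(sequence, p + 1L, p + 3L) %in% stop_codons)
        return(data.frame(start = s, end = p + 3L, open_ended = FALSE))
      p <- p + 3L
    }
    data.frame(start = s, end = s + 3L * ((n - s) %/% 3L),
               open_ended = TRUE)
  })
  if (!length(recs))
    return(data.frame(start = integer(0), end = integer(0),
                      open_ended = logical(0)))
  do.call(rbind, recs)
}

random_sequence <- function(len) {
  paste(sample(c("A", "C", "G", "U"), len, replace = TRUE,
               prob = c(0.3, 0.2, 0.25, 0.25)), collapse = "")
}

# Random valid RDG over a random transcript: initiation events sampled from
# real start-site occurrences, occasional readthrough/selenocysteine or
# frameshift event, random reinitiation policy.
random_rdg <- function(max_branches = 12L, max_events = 5L) {
  repeat {
    tx <- transcript(sprintf("rt%06d", sample.int(1e6, 1)),
                     random_sequence(sample(90:400, 1)))
    sites <- find_start_sites(tx, c("AUG", "CUG"))
    if (!nrow(sites)) next
    k <- min(nrow(sites), sample.int(max_events, 1))
    pick <- sort(sample.int(nrow(sites), k))
    events <- lapply(pick, function(i)
      initiation_event(sites$position[i], sites$codon[i]))
    s0 <- sites$position[pick[1]]
    st <- next_in_frame_stop(tx, s0 + 3L, s0 %% 3L)
    if (!is.null(st) && stats::runif(1) < 0.3) {
      ev <- if (substr(tx$sequence, st + 1, st + 3) == "UGA" &&
                stats::runif(1) < 0.5)
        selenocysteine_event(st) else readthrough_event(st)
      events <- c(events, list(ev))
    } else if (!is.null(st) && st - s0 > 6L && stats::runif(1) < 0.2) {
      q <- s0 + 3L * sample.int((st - s0) %/% 3L - 1L, 1)
      events <- c(events, list(frameshift_event(q, sample(c(-1L, 1L), 1))))
    }
    pol <- reinitiation_policy(
      max_translon_nt = sample(c(0L, 30L, 100L, 300L), 1),
      recharge_model = sample(c("NONE", "STEP"), 1),
      recharge_distance_nt = sample(0:50, 1),
      allow_chained = stats::runif(1) < 0.2)
    g <- try(suppressWarnings(build_rdg(tx, events, pol)), silent = TRUE)
    if (inherits(g, "try-error")) next
    if (nrow(branch_nodes(g)) <= max_branches) return(g)
  }
}

# Independent path counter over the raw edge list (igraph DFS), used as the
# brute-force enumeration oracle for count_paths/enumerate_paths.
igraph_path_count <- function(g) {
  ig <- igraph::graph_from_data_frame(g$edges[, c("from", "to")],
                                      vertices = g$nodes$id)
  length(igraph::all_simple_paths(ig, from = g$root, to = g$exit,
                                  mode = "out"))
}

# Transcript with k leaky AUG starts in one frame sharing a stop and no
# reinitiation: the closed-form k+1 path chain.
chain_fixture <- function(k) {
  seq <- paste0("GGC", strrep("AUG", k), strrep("GGA", 3), "UAA", "GGC")
  tx <- transcript(sprintf("chain%d", k), seq)
  events <- lapply(seq_len(k) - 1L, function(i)
    initiation_event(3L + 3L * i, "AUG"))
  build_rdg(tx, events, reinitiation_policy(max_translon_nt = 0L))
}

expect_valid_rdg <- function(g) expect_identical(validate_rdg(g),
                                                 character(0))
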