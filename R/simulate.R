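#' Simulate ribosome-profiling footprint density from an RDG
#'
#' Samples `n_ribosomes` independent passages through the graph (at each
#' branch the ribosome commits with the branch probability) and deposits
#' footprints on the translons each ribosome translates. Elongation is
#' uniform: every codon of a traversed translon receives on average
#' `footprints_per_codon` footprints per traversing ribosome, placed on the
#' codon's first nucleotide so the sub-codon frame phase of the signal is
#' preserved. Scanning edges deposit nothing.
#'
#' Noise models: `"none"` emits the exact expected track (no sampling at
#' all); `"multinomial"` samples path choices multinomially and scatters each
#' translon's (rounded) expected footprint total uniformly over its codons;
#' `"poisson"` samples path choices and then per-codon Poisson counts. Given
#' the same seed the output is bit-identical.
#'
#' @param rdg an [build_rdg()] object.
#' @param probs a complete [branch_probabilities()].
#' @param n_ribosomes number of simulated ribosome passages.
#' @param seed integer seed; required for the stochastic noise models.
#' @param noise `"none"`, `"multinomial"` or `"poisson"`.
#' @param footprints_per_codon expected footprint depth per elongating
#'   ribosome per codon (default 1).
#' @param max_paths passed to [enumerate_paths()].
#' @return A [density_track()].
#' @examples
#' fx <- make_fig3_transcript()
#' g <- build_rdg(fx$transcript, fx$events, fx$policy)
#' tr <- simulate_footprints(g, branch_probabilities(fx$probs), 1000,
#'                           seed = 1, noise = "multinomial")
#' @export
simulate_footprints <- function(rdg, probs, n_ribosomes, seed = NULL,
                                noise = c("none", "multinomial", "poisson"),
                                footprints_per_codon = 1,
                                max_paths = 1e6) {
  stopifnot(inherits(rdg, "rdg"), n_ribosomes >= 1,
            footprints_per_codon > 0)
  noise <- match.arg(noise)
  pp <- path_probabilities(rdg, probs, max_paths = max_paths)
  paths <- enumerate_paths(rdg, max_paths = max_paths)
  tl <- translons(rdg)
  values <- numeric(rdg$transcript$length)

  # ribosome count per translon
  if (noise == "none") {
    rate <- vapply(names(tl), function(t)
      sum(pp[vapply(paths, function(p) t %in% p$translon_ids, logical(1))]),
      numeric(1))
    k <- rate * n_ribosomes
  } else {
    if (is.null(seed))
      stop("stochastic noise models require a `seed`", call. = FALSE)
    set.seed(as.integer(seed))
    draws <- stats::rmultinom(1, n_ribosomes, pp)[, 1]
    k <- vapply(names(tl), function(t)
      sum(draws[vapply(paths, function(p) t %in% p$translon_ids,
                       logical(1))]), numeric(1))
  }

  for (j in seq_along(tl)) {
    pos <- translon_phase_positions(tl[[j]])
    mu <- k[[j]] * footprints_per_codon   # expected footprints per codon
    if (mu == 0) next
    add <- switch(noise,
      none = rep(mu, length(pos)),
      multinomial = {
        total <- round(mu * length(pos))
        if (total > 0)
          stats::rmultinom(1, total, rep(1, length(pos)))[, 1]
        else numeric(length(pos))
      },
      poisson = stats::rpois(length(pos), mu))
    values[pos] <- values[pos] + add
  }
  density_track(rdg$transcript, values)
}

#' Simulate method for RDG objects
#'
#' Thin wrapper around [simulate_footprints()] following the
#' [stats::simulate()] convention; returns a list of `nsim` density tracks.
#'
#' @param object an rdg object.
#' @param nsim number of tracks.
#' @param seed integer seed (consecutive seeds are used per replicate).
#' @param probs,n_ribosomes,... passed to [simulate_footprints()].
#' @return List of [density_track()] objects.
#' @export
simulate.rdg <- function(object, nsim = 1, seed = 1, probs, n_ribosomes,
                         ...) {
  lapply(seq_len(nsim) - 1L, function(i)
    simulate_footprints(object, probs, n_ribosomes, seed = seed + i, ...))
}
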