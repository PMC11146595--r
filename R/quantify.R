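#' Per-nucleotide A-site footprint density track
#'
#' One non-negative value per transcript coordinate (A-site assigned footprint
#' counts, raw or normalized). The per-translon mean of this signal estimates
#' translation flux: a ribosome deposits footprints along the whole translon,
#' so under uniform elongation, initiation events per unit time are
#' proportional to density divided by length.
#'
#' @param transcript a [transcript()] (or its id with `length` given).
#' @param values numeric vector of length `transcript$length`; defaults to
#'   all zero.
#' @return An object of class `density_track` (`transcript_id`, `values`).
#' @export
density_track <- function(transcript, values = NULL) {
  stop_if_not_transcript(transcript)
  if (is.null(values)) values <- numeric(transcript$length)
  if (length(values) != transcript$length)
    stop(sprintf("track length %d does not match transcript length %d",
                 length(values), transcript$length), call. = FALSE)
  if (any(values < 0))
    stop("density values must be non-negative", call. = FALSE)
  structure(list(transcript_id = transcript$id, values = as.numeric(values)),
            class = "density_track")
}

#' @export
print.density_track <- function(x, ...) {
  cat(sprintf("density track %s: %d nt, total %.4g, %d nonzero\n",
              x$transcript_id, length(x$values), sum(x$values),
              sum(x$values > 0)))
  invisible(x)
}

#' Translation flux of a single translon
#'
#' The plain estimator: sum of density over all translon segments divided by
#' total translon length in nucleotides. Multi-segment (trans-frame) translons
#' pool density across segments. This estimator attributes all density on
#' shared nucleotides to each overlapping translon; use [translon_fluxes()]
#' for the overlap-aware decomposition.
#'
#' @param track a [density_track()].
#' @param translon one element of [translons()].
#' @param trim_codons drop this many codons from each translon end before
#'   averaging (default 0: no trimming, keeping the estimator auditable).
#' @return Non-negative flux (mean density per nucleotide).
#' @export
translon_flux <- function(track, translon, trim_codons = 0L) {
  segs <- translon$segments
  if (any(segs$start < 0) || any(segs$end > length(track$values)))
    stop(sprintf("translon %s extends beyond the density track",
                 translon$id), call. = FALSE)
  idx <- unlist(lapply(seq_len(nrow(segs)), function(i)
    seq.int(segs$start[i] + 1L, segs$end[i])))
  if (trim_codons > 0L) {
    drop <- 3L * trim_codons
    if (length(idx) > 2L * drop)
      idx <- idx[(drop + 1L):(length(idx) - drop)]
  }
  sum(track$values[idx]) / length(idx)
}

# Phase positions (1-based indices of codon first nucleotides) of a translon.
translon_phase_positions <- function(translon) {
  segs <- translon$segments
  unlist(lapply(seq_len(nrow(segs)), function(i)
    seq.int(segs$start[i] + 1L, segs$end[i], by = 3L)))
}

#' Translation fluxes of all translons of a graph
#'
#' `method = "decompose"` (default) solves the linear model in which each
#' translon contributes a constant per-codon deposit on the first nucleotide
#' of each of its codons (the sub-codon frame phase), by least squares over
#' the whole track. Overlapping translons -- whether in different frames or
#' nested in the same frame, as with N-terminally extended proteoforms --
#' are separated by their unique regions; a frame-aware attribution falls out
#' as the special case of disjoint phases. Negative solutions are clamped to
#' zero with a warning. `method = "naive"` applies [translon_flux()] per
#' translon, double-counting shared nucleotides.
#'
#' @param track a [density_track()].
#' @param rdg an rdg object whose translons to quantify.
#' @param method `"decompose"` or `"naive"`.
#' @return data.frame with columns `translon` and `flux` (mean density per
#'   nucleotide, the relative translation efficiency of the translon).
#' @export
translon_fluxes <- function(track, rdg, method = c("decompose", "naive")) {
  method <- match.arg(method)
  tl <- translons(rdg)
  if (!length(tl))
    return(data.frame(translon = character(0), flux = numeric(0)))
  if (track$transcript_id != rdg$transcript$id)
    stop(sprintf("track is for '%s' but graph is for '%s'",
                 track$transcript_id, rdg$transcript$id), call. = FALSE)
  if (method == "naive") {
    flux <- vapply(tl, function(t) translon_flux(track, t), numeric(1))
    return(data.frame(translon = names(tl), flux = unname(flux),
                      row.names = NULL))
  }
  n <- length(track$values)
  A <- matrix(0, nrow = n, ncol = length(tl),
              dimnames = list(NULL, names(tl)))
  for (j in seq_along(tl))
    A[translon_phase_positions(tl[[j]]), j] <- 1
  used <- rowSums(A) > 0
  fit <- stats::lm.fit(A[used, , drop = FALSE], track$values[used])
  d <- fit$coefficients
  d[is.na(d)] <- 0
  if (any(d < -1e-8))
    warning("negative flux estimate(s) clamped to zero", call. = FALSE)
  d <- pmax(d, 0)
  # per-codon deposit -> mean per-nucleotide density over the translon
  data.frame(translon = names(tl), flux = unname(d[names(tl)]) / 3,
             row.names = NULL)
}

#' Branch probabilities of an RDG
#'
#' A complete assignment maps every branch node id to its commit probability.
#' `provenance` records whether values were user-assigned or inferred from
#' footprint density.
#'
#' @param x named numeric vector (names = branch node ids, values in `[0,1]`).
#' @param provenance `"ASSIGNED"` or `"INFERRED"` (vector or scalar).
#' @return An object of class `branch_probabilities`.
#' @export
branch_probabilities <- function(x, provenance = "ASSIGNED") {
  if (length(x) && (is.null(names(x)) || any(!nzchar(names(x)))))
    stop("branch probabilities must be a named vector", call. = FALSE)
  if (any(x < 0 | x > 1, na.rm = TRUE))
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  structure(as.numeric(x), names = names(x),
            provenance = rep_len(provenance, length(x)),
            class = "branch_probabilities")
}

#' @export
print.branch_probabilities <- function(x, ...) {
  prov <- attr(x, "provenance")
  for (i in seq_along(x))
    cat(sprintf("  %-18s %.4f (%s)\n", names(x)[i], x[i], prov[i]))
  invisible(x)
}

# Complete per-edge probability lookup: commit edges get p, continue edges
# 1 - p, sole deterministic commits 1, non-branch edges 1.
edge_probabilities <- function(rdg, probs) {
  bn <- branch_nodes(rdg)
  missing <- setdiff(bn$id, names(probs))
  # branches carrying build-time probabilities (deterministic starts,
  # event-assigned values, recharge competence) may be omitted
  for (m in missing) {
    oe <- out_edges(rdg, m)
    if (all(!is.na(oe$probability))) {
      ce <- oe$probability[!is.na(oe$role) & oe$role == "commit"]
      if (length(ce) == 1L) probs[m] <- ce
    }
  }
  missing <- setdiff(bn$id, names(probs))
  if (length(missing))
    stop(sprintf("missing branch probabilities for: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  ep <- rep(1, nrow(rdg$edges))
  names(ep) <- rdg$edges$id
  for (i in seq_len(nrow(rdg$edges))) {
    e <- rdg$edges[i, ]
    if (e$from %in% bn$id && !is.na(e$role)) {
      p <- probs[[e$from]]
      ep[e$id] <- if (e$role == "commit") p else 1 - p
    }
  }
  ep
}

#' Probability of each ribosome path
#'
#' Product of edge probabilities along each root-to-exit path (commit edges
#' carry `p`, continue edges `1 - p`). Probabilities sum to one over all
#' paths, including the unproductive one.
#'
#' @param rdg an rdg object.
#' @param probs a [branch_probabilities()] covering every branch.
#' @param max_paths passed to [enumerate_paths()].
#' @return Named numeric vector, path id -> probability.
#' @export
path_probabilities <- function(rdg, probs, max_paths = 1e6) {
  ep <- edge_probabilities(rdg, probs)
  paths <- enumerate_paths(rdg, max_paths = max_paths)
  out <- vapply(paths, function(p) prod(ep[p$edges]), numeric(1))
  names(out) <- vapply(paths, `[[`, character(1), "id")
  out
}

#' Relative synthesis rate of each translon
#'
#' The probability that a cap-loading ribosome synthesizes the translon's
#' product: the sum of probabilities of all paths containing the translon.
#' Also reported as a percentage of the total productive path probability.
#'
#' @inheritParams path_probabilities
#' @return data.frame with columns `translon`, `rate` and `pct_productive`.
#' @export
relative_synthesis_rates <- function(rdg, probs, max_paths = 1e6) {
  ep <- edge_probabilities(rdg, probs)
  paths <- enumerate_paths(rdg, max_paths = max_paths)
  pp <- vapply(paths, function(p) prod(ep[p$edges]), numeric(1))
  productive_total <- sum(pp[vapply(paths, `[[`, logical(1), "productive")])
  ids <- names(translons(rdg))
  rate <- vapply(ids, function(t)
    sum(pp[vapply(paths, function(p) t %in% p$translon_ids, logical(1))]),
    numeric(1))
  data.frame(
    translon = ids,
    rate = unname(rate),
    pct_productive = if (productive_total > 0)
      unname(100 * rate / productive_total) else NA_real_,
    row.names = NULL)
}

#' Infer branch probabilities from translon fluxes
#'
#' Closed-form flux-balance inversion on the scanning tree: each translon's
#' flux is the flux through its initiation commit edge; the flux arriving at
#' a branch equals commit flux plus continue flux, where the continue flux is
#' the sum of all commit fluxes downstream on the scanning route; the commit
#' probability is commit flux over arriving flux. The unproductive exit flux
#' is unobservable in ribosome profiling and is set to zero, so the inferred
#' probability of the 3'-most branch on each route is an upper bound (exact
#' when that start is deterministic, the usual convention for annotated CDS
#' starts). A reinitiation branch probability is the reinitiated translon's
#' flux divided by the upstream translon's flux.
#'
#' Identifiability requires each translon to be entered by exactly one edge.
#' A translon fed by both leaky scanning and reinitiation is not separable
#' from density alone; supply the reinitiation probability through `fixed`
#' (named vector of branch id -> probability) and the remaining branches are
#' inferred after subtracting the reinitiated flux.
#'
#' @param rdg an rdg object whose branches are initiation or reinitiation
#'   decisions (elongation branches are not quantifiable by this estimator).
#' @param fluxes data.frame from [translon_fluxes()] (columns `translon`,
#'   `flux`), or a named numeric vector.
#' @param fixed optional named numeric vector of branch probabilities to hold
#'   fixed (provenance `ASSIGNED`).
#' @return A [branch_probabilities()] with provenance `INFERRED` for the
#'   estimated entries.
#' @export
infer_branch_probabilities <- function(rdg, fluxes, fixed = NULL) {
  stopifnot(inherits(rdg, "rdg"))
  if (is.data.frame(fluxes))
    fluxes <- stats::setNames(fluxes$flux, fluxes$translon)
  tl_ids <- names(translons(rdg))
  missing <- setdiff(tl_ids, names(fluxes))
  if (length(missing))
    stop(sprintf("no flux for translon(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)

  bn <- branch_nodes(rdg)
  bad <- bn$kind[!bn$kind %in% c("BRANCH_INIT", "BRANCH_REINIT")]
  if (length(bad))
    stop(paste0(
      "flux-balance inference supports initiation/reinitiation branches ",
      "only; graph contains ", paste(unique(bad), collapse = ", ")),
      call. = FALSE)
  if (any(grepl("^rinit@", bn$id)))
    stop(paste0(
      "post-termination competence branches (EXPONENTIAL recharge) are not ",
      "identifiable from density; assign probabilities instead"),
      call. = FALSE)

  edges <- rdg$edges
  commit <- edges[!is.na(edges$role) & edges$role == "commit", , drop = FALSE]

  # upstream translon of each reinitiation branch (reinit@<stop>:<translon>)
  reinit_ids <- bn$id[bn$kind == "BRANCH_REINIT"]
  reinit_upstream <- stats::setNames(
    sub("\\*nr$", "", sub("^reinit@[0-9]+:", "", reinit_ids)), reinit_ids)

  # entry edges per translon
  entries <- split(commit$from, commit$translon)
  out <- numeric(0)
  prov <- character(0)
  push <- function(id, p, pr) {
    out[[id]] <<- p
    prov <<- c(prov, stats::setNames(pr, id))
  }
  for (id in names(fixed)) push(id, fixed[[id]], "ASSIGNED")

  # resolve the flux through each *initiation* commit edge
  cap_flux <- fluxes
  for (t in names(entries)) {
    froms <- entries[[t]]
    rb <- froms[froms %in% reinit_ids]
    ib <- froms[!froms %in% reinit_ids]
    if (length(ib) > 1L)
      stop(sprintf(
        "translon %s is entered by %d initiation edges; not identifiable",
        t, length(ib)), call. = FALSE)
    if (length(rb)) {
      unresolved <- rb[!rb %in% names(out)]
      if (length(ib) && length(unresolved))
        stop(sprintf(paste0(
          "translon %s is entered by both leaky scanning and reinitiation ",
          "(%s); fix one probability via `fixed` to make the flux split ",
          "identifiable"), t, paste(unresolved, collapse = ", ")),
          call. = FALSE)
      if (length(ib) == 0L && length(rb) > 1L && length(unresolved) > 1L)
        stop(sprintf(paste0(
          "translon %s is entered by %d reinitiation edges; fix all but one ",
          "probability via `fixed`"), t, length(rb)), call. = FALSE)
      resolved_flux <- sum(vapply(intersect(rb, names(out)), function(b)
        out[[b]] * fluxes[[reinit_upstream[[b]]]], numeric(1)))
      rest <- fluxes[[t]] - resolved_flux
      if (rest < -1e-9 * max(fluxes[[t]], 1))
        stop(sprintf(
          "reinitiated flux into %s exceeds its observed flux (ratio %.3f)",
          t, resolved_flux / max(fluxes[[t]], .Machine$double.eps)),
          call. = FALSE)
      rest <- max(rest, 0)
      if (length(ib)) {
        cap_flux[[t]] <- rest
      } else if (length(unresolved) == 1L) {
        up <- fluxes[[reinit_upstream[[unresolved]]]]
        if (up == 0 && rest == 0) {
          warning(sprintf("0/0 flux at %s; probability set to 0",
                          unresolved), call. = FALSE)
          push(unresolved, 0, "INFERRED")
        } else {
          ratio <- rest / up
          if (ratio > 1 + 1e-9)
            stop(sprintf(
              "reinitiated flux into %s exceeds upstream flux (ratio %.3f)",
              t, ratio), call. = FALSE)
          push(unresolved, min(ratio, 1), "INFERRED")
        }
        cap_flux[[t]] <- 0
      } else {
        cap_flux[[t]] <- 0
      }
    }
  }

  # scanning-route chains: walk continue edges from each un-entered branch
  init_ids <- bn$id[bn$kind == "BRANCH_INIT"]
  cont_next <- stats::setNames(rep(NA_character_, length(init_ids)), init_ids)
  for (b in init_ids) {
    oe <- out_edges(rdg, b)
    ce <- oe[!is.na(oe$role) & oe$role == "continue", , drop = FALSE]
    if (nrow(ce) && ce$to %in% init_ids) cont_next[[b]] <- ce$to
  }
  commit_translon <- stats::setNames(commit$translon, commit$from)
  heads <- setdiff(init_ids, stats::na.omit(cont_next))
  for (h in heads) {
    chain <- character(0)
    b <- h
    while (!is.na(b)) {
      chain <- c(chain, b)
      b <- cont_next[[b]]
    }
    arriving <- 0   # exit flux assumed zero
    for (b in rev(chain)) {
      c_b <- cap_flux[[commit_translon[[b]]]]
      arriving <- arriving + c_b
      if (b %in% names(out)) next   # user-fixed
      if (arriving == 0) {
        warning(sprintf("0/0 flux at %s; probability set to 0", b),
                call. = FALSE)
        push(b, 0, "INFERRED")
      } else {
        push(b, c_b / arriving, "INFERRED")
      }
    }
  }

  # reinitiation branches whose target translon had a single (reinit) entry
  for (b in reinit_ids) {
    if (b %in% names(out)) next
    oe <- out_edges(rdg, b)
    target <- oe$translon[!is.na(oe$role) & oe$role == "commit"]
    up <- fluxes[[reinit_upstream[[b]]]]
    dn <- fluxes[[target]]
    if (up == 0 && dn == 0) {
      warning(sprintf("0/0 flux at %s; probability set to 0", b),
              call. = FALSE)
      push(b, 0, "INFERRED")
    } else {
      ratio <- dn / up
      if (ratio > 1 + 1e-9)
        stop(sprintf(
          "reinitiated flux into %s exceeds upstream flux (ratio %.3f)",
          target, ratio), call. = FALSE)
      push(b, min(ratio, 1), "INFERRED")
    }
  }

  branch_probabilities(out[bn$id], provenance = unname(prov[bn$id]))
}

#' Quantify an RDG from a density track
#'
#' Convenience pipeline: overlap-aware translon fluxes, inferred branch
#' probabilities, path probabilities and relative synthesis rates.
#'
#' @inheritParams translon_fluxes
#' @inheritParams infer_branch_probabilities
#' @return An object of class `rdg_quantification`: list with `fluxes`,
#'   `probabilities`, `path_probabilities`, `rates` and `assumptions`.
#' @export
quantify_rdg <- function(track, rdg, fixed = NULL,
                         method = c("decompose", "naive")) {
  fluxes <- translon_fluxes(track, rdg, method = match.arg(method))
  probs <- infer_branch_probabilities(rdg, fluxes, fixed = fixed)
  structure(
    list(fluxes = fluxes,
         probabilities = probs,
         path_probabilities = path_probabilities(rdg, probs),
         rates = relative_synthesis_rates(rdg, probs),
         assumptions = c(
           "unproductive exit flux set to 0 (unobservable in Ribo-seq)",
           "uniform elongation; flux = length-normalized density")),
    class = "rdg_quantification"
  )
}

#' @export
print.rdg_quantification <- function(x, ...) {
  cat("RDG quantification\n")
  cat("branch probabilities:\n")
  print(x$probabilities)
  cat("translon synthesis rates:\n")
  print(x$rates, row.names = FALSE)
  invisible(x)
}

#' Write a quantification report as TSV
#'
#' Sections (translon fluxes, branch probabilities, path probabilities,
#' synthesis rates) are stacked with a `section` column; floats are written
#' at 6 significant digits.
#'
#' @param q an `rdg_quantification`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_quantification <- function(q, path) {
  rows <- rbind(
    data.frame(section = "flux", key = q$fluxes$translon,
               value = signif(q$fluxes$flux, 6)),
    data.frame(section = "branch_probability",
               key = names(q$probabilities),
               value = signif(as.numeric(q$probabilities), 6)),
    data.frame(section = "path_probability",
               key = names(q$path_probabilities),
               value = signif(unname(q$path_probabilities), 6)),
    data.frame(section = "synthesis_rate", key = q$rates$translon,
               value = signif(q$rates$rate, 6)),
    data.frame(section = "synthesis_pct_productive", key = q$rates$translon,
               value = signif(q$rates$pct_productive, 6)))
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
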