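#' Translation events
#'
#' A translation event is a tagged nondeterministic ribosome decision placed on
#' a transcript: leaky-scanning initiation at a start codon, readthrough of a
#' stop codon, selenocysteine insertion at a UGA, or a programmed ribosomal
#' frameshift. Events are the branch points of the ribosome decision graph.
#'
#' `position` is the 0-based coordinate of the first nucleotide of the start
#' codon (initiation), of the stop codon (readthrough/selenocysteine), or of
#' the in-frame codon at which the shift takes effect (frameshift).
#' `probability` is the commit probability of the branch, or `NA` when
#' unassigned; an initiation event with `probability = 1` is deterministic (the
#' scanning ribosome always commits; no leak edge is built).
#'
#' @param position 0-based coordinate (see Details).
#' @param codon expected start codon at `position` (validated at build time).
#' @param probability commit probability in `[0, 1]`, or `NA`.
#' @param name optional label for the translon opened by this event.
#' @param shift frameshift direction, `+1` or `-1`.
#' @return An object of class `translation_event`.
#' @name translation_events
NULL

new_event <- function(kind, position, detail = list(), probability = NA_real_,
                      name = NULL) {
  if (!is.numeric(position) || length(position) != 1L || position < 0)
    stop("event `position` must be a single non-negative coordinate",
         call. = FALSE)
  if (!is.na(probability) && (probability < 0 || probability > 1))
    stop("event `probability` must be in [0, 1] or NA", call. = FALSE)
  structure(
    list(kind = kind, position = as.integer(position), detail = detail,
         probability = as.numeric(probability), name = name),
    class = "translation_event"
  )
}

#' @rdname translation_events
#' @export
initiation_event <- function(position, codon = "AUG", probability = NA,
                             name = NULL) {
  new_event("INITIATION", position, list(codon = validate_codons(codon)),
            probability, name)
}

#' @rdname translation_events
#' @export
readthrough_event <- function(position, probability = NA) {
  new_event("READTHROUGH", position, probability = probability)
}

#' @rdname translation_events
#' @export
selenocysteine_event <- function(position, probability = NA) {
  new_event("SELENOCYSTEINE", position, list(codon = "UGA"), probability)
}

#' @rdname translation_events
#' @export
frameshift_event <- function(position, shift, probability = NA) {
  if (!shift %in% c(-1L, 1L))
    stop("frameshift `shift` must be +1 or -1", call. = FALSE)
  new_event("FRAMESHIFT", position, list(shift = as.integer(shift)),
            probability)
}

#' @export
print.translation_event <- function(x, ...) {
  detail <- switch(x$kind,
    INITIATION = x$detail$codon,
    FRAMESHIFT = sprintf("%+d", x$detail$shift),
    SELENOCYSTEINE = "UGA",
    READTHROUGH = "")
  cat(sprintf("%s @ %d %s p=%s%s\n", x$kind, x$position, detail,
              ifelse(is.na(x$probability), "?", format(x$probability)),
              if (!is.null(x$name)) paste0(" (", x$name, ")") else ""))
  invisible(x)
}

sort_events <- function(events) {
  if (!length(events)) return(events)
  # co-located events are ordered INITIATION < FRAMESHIFT < READTHROUGH/SEC
  kind_rank <- c(INITIATION = 1L, FRAMESHIFT = 2L, READTHROUGH = 3L,
                 SELENOCYSTEINE = 3L)
  pos <- vapply(events, `[[`, integer(1), "position")
  rk <- kind_rank[vapply(events, `[[`, character(1), "kind")]
  events[order(pos, rk)]
}

# Event validation against a transcript: codon identity, bounds, co-location.
validate_events <- function(transcript, events) {
  for (i in seq_along(events)) {
    ev <- events[[i]]
    if (!inherits(ev, "translation_event"))
      stop("events must be built with the *_event() constructors",
           call. = FALSE)
    if (ev$position + 3L > transcript$length && ev$kind != "FRAMESHIFT")
      stop(sprintf("%s event at %d does not leave room for a codon",
                   ev$kind, ev$position), call. = FALSE)
    if (ev$position >= transcript$length)
      stop(sprintf("%s event at %d lies outside transcript %s",
                   ev$kind, ev$position, transcript$id), call. = FALSE)
    codon <- codon_at(transcript, ev$position)
    if (ev$kind == "INITIATION" && codon != ev$detail$codon)
      stop(sprintf(
        "INITIATION event at %d expects codon %s but transcript %s has %s",
        ev$position, ev$detail$codon, transcript$id, codon), call. = FALSE)
    if (ev$kind == "SELENOCYSTEINE" && codon != "UGA")
      stop(sprintf(
        "SELENOCYSTEINE event at %d requires UGA, found %s",
        ev$position, codon), call. = FALSE)
    if (ev$kind == "READTHROUGH" && !codon %in% STOP_CODONS)
      stop(sprintf(
        "READTHROUGH event at %d requires a stop codon, found %s",
        ev$position, codon), call. = FALSE)
  }
  # overlapping elongation events in the same codon are ambiguous
  el <- Filter(function(e) e$kind != "INITIATION", events)
  if (length(el) > 1L) {
    pos <- vapply(el, `[[`, integer(1), "position")
    if (anyDuplicated(pos %/% 3L))
      stop("overlapping frameshift/readthrough events in the same codon",
           call. = FALSE)
  }
  invisible(TRUE)
}

#' Reinitiation policy
#'
#' Reinitiation is treated as a general post-termination property of short
#' translons, not a per-site event: after every termination whose translon is
#' at most `max_translon_nt` long, a reinitiation branch offers resumption of
#' scanning strictly downstream of the termination site versus exit. The
#' recharge model expresses delayed reinitiation, i.e. the distance a
#' post-termination small subunit must scan before it re-acquires the ternary
#' complex and becomes initiation-competent:
#'
#' * `NONE` -- immediately competent; reinitiation uses the first eligible
#'   downstream start.
#' * `STEP` -- starts closer than `recharge_distance_nt` to the termination
#'   site are deterministically skipped (the stress-dependent switch between
#'   downstream starts).
#' * `EXPONENTIAL` -- competence at distance `x` with probability
#'   `1 - exp(-x / lambda_nt)`; each downstream start becomes a probabilistic
#'   branch on the post-termination route.
#'
#' @param max_translon_nt translons longer than this (nt) cannot be followed
#'   by reinitiation; default 100.
#' @param recharge_model `"NONE"`, `"STEP"` or `"EXPONENTIAL"`.
#' @param recharge_distance_nt STEP window in nucleotides.
#' @param lambda_nt EXPONENTIAL competence length scale (nt).
#' @param aug_only if `TRUE`, reinitiating ribosomes only use AUG starts.
#' @param allow_chained if `TRUE`, a translon entered by reinitiation may
#'   itself be followed by another reinitiation branch; off by default.
#' @return An object of class `reinitiation_policy`.
#' @export
reinitiation_policy <- function(max_translon_nt = 100L,
                                recharge_model = c("NONE", "STEP",
                                                   "EXPONENTIAL"),
                                recharge_distance_nt = 0L,
                                lambda_nt = NULL,
                                aug_only = FALSE,
                                allow_chained = FALSE) {
  recharge_model <- match.arg(recharge_model)
  stopifnot(max_translon_nt >= 0, recharge_distance_nt >= 0)
  if (recharge_model == "EXPONENTIAL" &&
      (is.null(lambda_nt) || lambda_nt <= 0))
    stop("EXPONENTIAL recharge requires a positive `lambda_nt`",
         call. = FALSE)
  structure(
    list(max_translon_nt = as.integer(max_translon_nt),
         recharge_model = recharge_model,
         recharge_distance_nt = as.integer(recharge_distance_nt),
         lambda_nt = lambda_nt,
         aug_only = isTRUE(aug_only),
         allow_chained = isTRUE(allow_chained)),
    class = "reinitiation_policy"
  )
}

#' @export
print.reinitiation_policy <- function(x, ...) {
  cat(sprintf(
    "reinitiation policy: max translon %d nt, recharge %s%s%s%s\n",
    x$max_translon_nt, x$recharge_model,
    if (x$recharge_model == "STEP")
      sprintf(" (%d nt)", x$recharge_distance_nt) else "",
    if (x$recharge_model == "EXPONENTIAL")
      sprintf(" (lambda %g nt)", x$lambda_nt) else "",
    if (x$aug_only) ", AUG-only" else ""))
  invisible(x)
}

#' Read and write translation events as a BED6-like file
#'
#' Columns: transcript id, start, end (half-open, 0-based), name =
#' `KIND[:detail][:label]`, score = `round(1000 * probability)` (`-1` when
#' unassigned), strand `"+"`. This dialect is bit-equivalent to the in-memory
#' event list.
#'
#' @param path file path.
#' @param events list of [translation_events].
#' @param transcript_id id written to the first column.
#' @return `read_events()` returns a list of events; `write_events()` returns
#'   `path` invisibly.
#' @export
write_events <- function(events, transcript_id, path) {
  events <- sort_events(events)
  rows <- lapply(events, function(ev) {
    detail <- switch(ev$kind,
      INITIATION = ev$detail$codon,
      FRAMESHIFT = sprintf("%+d", ev$detail$shift),
      SELENOCYSTEINE = "UGA",
      READTHROUGH = "-")
    name <- paste(c(ev$kind, detail, ev$name), collapse = ":")
    width <- if (ev$kind == "FRAMESHIFT") 1L else 3L
    data.frame(chrom = transcript_id, start = ev$position,
               end = ev$position + width, name = name,
               score = if (is.na(ev$probability)) -1L
                       else as.integer(round(1000 * ev$probability)),
               strand = "+", stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE,
                           col.names = c("chrom", "start", "end", "name",
                                         "score", "strand"))
  lapply(seq_len(nrow(tab)), function(i) {
    parts <- strsplit(tab$name[i], ":", fixed = TRUE)[[1]]
    kind <- parts[1]
    detail <- if (length(parts) >= 2) parts[2] else NA
    label <- if (length(parts) >= 3) parts[3] else NULL
    p <- if (tab$score[i] < 0) NA_real_ else tab$score[i] / 1000
    switch(kind,
      INITIATION = initiation_event(tab$start[i], detail, p, label),
      READTHROUGH = readthrough_event(tab$start[i], p),
      SELENOCYSTEINE = selenocysteine_event(tab$start[i], p),
      FRAMESHIFT = frameshift_event(tab$start[i], as.integer(detail), p),
      stop(sprintf("unknown event kind '%s' in %s", kind, path),
           call. = FALSE))
  })
}
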