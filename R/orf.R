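#' Find start-codon occurrences in a transcript
#'
#' Scans the transcript in all three reading frames for occurrences of the
#' given start codons (typically AUG, optionally near-cognates such as CUG).
#' Scanning is purely transcript-space: the reverse complement is never
#' consulted.
#'
#' @param transcript a [transcript()] object.
#' @param allowed_codons character vector of 3-mers, e.g. `c("AUG", "CUG")`.
#' @param score_context if `TRUE`, attach a Kozak [context_score()] per site.
#' @return A data.frame with columns `position` (0-based coordinate of the
#'   first codon nucleotide), `codon`, `frame` (`position %% 3`) and, when
#'   requested, `context_score`; sorted by position.
#' @examples
#' find_start_sites(transcript("t", "CCAUGGCCUAGCC"), "AUG")
#' @export
find_start_sites <- function(transcript, allowed_codons = "AUG",
                             score_context = FALSE) {
  stop_if_not_transcript(transcript)
  allowed_codons <- validate_codons(allowed_codons)
  hits <- integer(0)
  codons <- character(0)
  for (codon in allowed_codons) {
    # lookahead so overlapping occurrences are all reported
    pos <- gregexpr(paste0("(?=", codon, ")"), transcript$sequence,
                    perl = TRUE)[[1]]
    pos <- pos[pos > 0]
    if (length(pos)) {
      hits <- c(hits, pos - 1L)
      codons <- c(codons, rep(codon, length(pos)))
    }
  }
  ord <- order(hits)
  out <- data.frame(
    position = hits[ord],
    codon = codons[ord],
    frame = hits[ord] %% 3L,
    stringsAsFactors = FALSE
  )
  if (score_context && nrow(out))
    out$context_score <- vapply(out$position, function(p)
      context_score(transcript, p), numeric(1))
  out
}

validate_codons <- function(codons) {
  if (length(codons) == 0)
    stop("`allowed_codons` must be non-empty", call. = FALSE)
  codons <- toupper(chartr("Tt", "Uu", codons))
  if (any(nchar(codons) != 3L) || any(grepl("[^ACGU]", codons)))
    stop("codons must be 3-mers over the {A,C,G,U} alphabet", call. = FALSE)
  unique(codons)
}

#' First in-frame stop codon at or after a position
#'
#' @param transcript a [transcript()] object.
#' @param position 0-based coordinate to start scanning from.
#' @param frame reading frame in `{0, 1, 2}` (coordinate mod 3).
#' @param stop_codons stop-codon set, default UAA/UAG/UGA.
#' @return 0-based coordinate of the first nucleotide of the stop codon, or
#'   `NULL` when no in-frame stop exists before the 3' end.
#' @export
next_in_frame_stop <- function(transcript, position, frame = position %% 3L,
                               stop_codons = STOP_CODONS) {
  stop_if_not_transcript(transcript)
  if (position < 0 || position > transcript$length)
    stop("`position` outside transcript", call. = FALSE)
  p <- as.integer(position + ((frame - position) %% 3L))
  while (p + 3L <= transcript$length) {
    if (codon_at(transcript, p) %in% stop_codons) return(p)
    p <- p + 3L
  }
  NULL
}

#' Find open reading frames under either formal definition
#'
#' Two formal ORF definitions are supported. `START_STOP`: every occurrence of
#' a start codon paired with its nearest in-frame downstream stop; the record
#' spans `[start, stop + 3)`, i.e. it includes the terminating stop codon, so
#' the encoded peptide has `(end - start)/3 - 1` residues. Starts with no
#' in-frame stop before the 3' end are retained, extended to the last complete
#' in-frame codon and flagged `open_ended` (variants can destroy stops, and
#' such records must survive). `STOP_STOP`: maximal stop-free stretches per
#' frame, bounded by stop codons or by the transcript ends; when a bounding 3'
#' stop exists it is included in the interval, mirroring the START_STOP end
#' convention, and stretches touching a transcript edge are flagged
#' `open_ended`.
#'
#' @param transcript a [transcript()] object.
#' @param definition `"START_STOP"` or `"STOP_STOP"`.
#' @param start_codons start-codon set (START_STOP only).
#' @param stop_codons stop-codon set, default UAA/UAG/UGA.
#' @param min_len minimum ORF length in nucleotides (interval length).
#' @return data.frame with columns `start`, `end` (0-based half-open), `frame`,
#'   `definition`, `start_codon` (`NA` for STOP_STOP) and `open_ended`;
#'   sorted by (start, frame).
#' @examples
#' tx <- transcript("t", "CCAUGGCCUAGCC")
#' find_orfs(tx, "START_STOP")
#' find_orfs(tx, "STOP_STOP")
#' @export
find_orfs <- function(transcript, definition = c("START_STOP", "STOP_STOP"),
                      start_codons = "AUG", stop_codons = STOP_CODONS,
                      min_len = 0L) {
  stop_if_not_transcript(transcript)
  definition <- match.arg(definition)
  stopifnot(min_len >= 0)
  empty <- data.frame(start = integer(0), end = integer(0), frame = integer(0),
                      definition = character(0), start_codon = character(0),
                      open_ended = logical(0), stringsAsFactors = FALSE)
  if (definition == "START_STOP") {
    sites <- find_start_sites(transcript, start_codons)
    if (!nrow(sites)) return(empty)
    recs <- lapply(seq_len(nrow(sites)), function(i) {
      s <- sites$position[i]
      stop_pos <- next_in_frame_stop(transcript, s + 3L, s %% 3L, stop_codons)
      if (is.null(stop_pos)) {
        n_codons <- (transcript$length - s) %/% 3L
        data.frame(start = s, end = s + 3L * n_codons, frame = s %% 3L,
                   definition = "START_STOP", start_codon = sites$codon[i],
                   open_ended = TRUE, stringsAsFactors = FALSE)
      } else {
        data.frame(start = s, end = stop_pos + 3L, frame = s %% 3L,
                   definition = "START_STOP", start_codon = sites$codon[i],
                   open_ended = FALSE, stringsAsFactors = FALSE)
      }
    })
    out <- do.call(rbind, recs)
  } else {
    recs <- list()
    for (f in 0:2) {
      codon_starts <- seq.int(f, transcript$length - 3L, by = 3L)
      if (length(codon_starts) == 0 || transcript$length - 3L < f) next
      is_stop <- vapply(codon_starts, function(p)
        codon_at(transcript, p) %in% stop_codons, logical(1))
      stops <- codon_starts[is_stop]
      bounds <- c(f, stops + 3L)           # candidate stretch starts
      uppers <- c(stops, NA_integer_)      # bounding stop (NA: transcript end)
      for (k in seq_along(bounds)) {
        s <- bounds[k]
        up <- uppers[k]
        e <- if (is.na(up)) f + 3L * ((transcript$length - f) %/% 3L)
             else up + 3L
        if (e <= s) next                   # empty stretch (adjacent stops)
        recs[[length(recs) + 1L]] <- data.frame(
          start = s, end = e, frame = f, definition = "STOP_STOP",
          start_codon = NA_character_,
          open_ended = (k == 1L) || is.na(up),
          stringsAsFactors = FALSE)
      }
    }
    out <- if (length(recs)) do.call(rbind, recs) else empty
  }
  out <- out[(out$end - out$start) >= min_len, , drop = FALSE]
  out <- out[order(out$start, out$frame), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Kozak consensus over positions -6..-1 and +4 relative to the start codon:
# gccRccAUGG (R = A or G). The start codon itself is not scored.
KOZAK_OFFSETS <- c(-6L, -5L, -4L, -3L, -2L, -1L, 3L)
KOZAK_CONSENSUS <- list("G", "C", "C", c("A", "G"), "C", "C", "G")

#' Kozak context score of a start site
#'
#' Fraction of the seven scored Kozak consensus positions (`gccRccAUGG`:
#' -6..-1 and +4 relative to the first start-codon nucleotide; `R` = A or G)
#' matched by the transcript. The denominator is fixed at seven; positions
#' falling outside the transcript contribute zero, so a start at the 5' edge
#' is scored from the available positions only. This is a fixed
#' consensus-match fraction, not a trained model.
#'
#' @param transcript a [transcript()] object.
#' @param position 0-based coordinate of the first start-codon nucleotide.
#' @return numeric in `[0, 1]`.
#' @examples
#' context_score(transcript("t", "GCCGCCAUGG"), 6)  # perfect consensus: 1
#' @export
context_score <- function(transcript, position) {
  stop_if_not_transcript(transcript)
  if (position < 0 || position + 3L > transcript$length)
    stop("start position outside transcript", call. = FALSE)
  matches <- 0
  for (k in seq_along(KOZAK_OFFSETS)) {
    p <- position + KOZAK_OFFSETS[k]
    if (p < 0 || p >= transcript$length) next
    base <- substr(transcript$sequence, p + 1L, p + 1L)
    if (base %in% KOZAK_CONSENSUS[[k]]) matches <- matches + 1
  }
  matches / length(KOZAK_OFFSETS)
}

#' Export ORFs or start sites as BED6
#'
#' The transcript id is used as the BED "chromosome"; the score column holds
#' `1000 * context_score` (0 when unscored) and the strand is always `"+"`
#' (transcript space is single-stranded).
#'
#' @param x data.frame from [find_orfs()] or [find_start_sites()].
#' @param transcript the [transcript()] the features belong to.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
features_to_bed <- function(x, transcript, path) {
  stop_if_not_transcript(transcript)
  if (!nrow(x)) {
    file.create(path)
    return(invisible(path))
  }
  is_orf <- "end" %in% names(x)
  start <- x$start %||% x$position
  end <- if (is_orf) x$end else x$position + 3L
  name <- if (is_orf) {
    paste0(x$definition, ":", ifelse(is.na(x$start_codon), "-", x$start_codon))
  } else {
    paste0("start:", x$codon)
  }
  score <- if (!is.null(x$context_score)) round(1000 * x$context_score) else 0L
  bed <- data.frame(chrom = transcript$id, start = start, end = end,
                    name = name, score = score, strand = "+")
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
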