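#' Read and write transcripts as FASTA
#'
#' Multi-record FASTA; the first whitespace-delimited token of each header is
#' the transcript id. `T` (and lowercase) is normalized to `U` on read;
#' sequences are written back as stored, wrapped at 60 columns.
#'
#' @param path file path.
#' @param transcripts list of [transcript()] objects (writer).
#' @return `read_fasta()` returns a named list of transcripts.
#' @export
read_fasta <- function(path) {
  seqs <- tryCatch(Biostrings::readBStringSet(path),
                   error = function(e)
                     stop(sprintf("cannot read FASTA '%s': %s", path,
                                  conditionMessage(e)), call. = FALSE))
  if (length(seqs) == 0)
    stop(sprintf("FASTA '%s' contains no records", path), call. = FALSE)
  ids <- vapply(strsplit(names(seqs), "\\s+"), `[[`, character(1), 1L)
  if (anyDuplicated(ids))
    stop(sprintf("duplicate transcript id(s) in '%s': %s", path,
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")),
         call. = FALSE)
  out <- lapply(seq_along(seqs), function(i)
    transcript(ids[i], as.character(seqs[[i]])))
  stats::setNames(out, ids)
}

#' @rdname read_fasta
#' @export
write_fasta <- function(transcripts, path) {
  if (inherits(transcripts, "transcript")) transcripts <- list(transcripts)
  seqs <- Biostrings::BStringSet(vapply(transcripts, `[[`, character(1),
                                        "sequence"))
  names(seqs) <- vapply(transcripts, `[[`, character(1), "id")
  Biostrings::writeXStringSet(seqs, path, width = 60L)
  invisible(path)
}

#' Read and write per-nucleotide density tracks
#'
#' Supported dialects: bedGraph (0-based, half-open intervals) and fixed-step
#' wiggle (1-based starts, converted internally). Positions not listed
#' default to zero; overlapping intervals and negative values are rejected;
#' intervals beyond the transcript length are an error. The transcript id is
#' used as the "chromosome" name.
#'
#' @param path file path; format chosen by extension (`.wig` = wiggle,
#'   otherwise bedGraph) unless `format` is given.
#' @param transcript the [transcript()] the track belongs to.
#' @param format `"auto"`, `"bedgraph"` or `"wig"`.
#' @param track a [density_track()] (writer; bedGraph of nonzero runs).
#' @return `read_density()` returns a [density_track()].
#' @export
read_density <- function(path, transcript, format = c("auto", "bedgraph",
                                                      "wig")) {
  stop_if_not_transcript(transcript)
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.wig(\\.gz)?$", path, ignore.case = TRUE)) "wig"
              else "bedgraph"
  if (file.size(path) == 0)
    return(density_track(transcript))
  gr <- rtracklayer::import(path,
                            format = if (format == "wig") "wig"
                                     else "bedGraph")
  gr <- gr[as.character(GenomicRanges::seqnames(gr)) == transcript$id]
  values <- numeric(transcript$length)
  if (length(gr)) {
    starts <- GenomicRanges::start(gr)   # 1-based
    ends <- GenomicRanges::end(gr)
    if (any(ends > transcript$length) || any(starts < 1))
      stop(sprintf(
        "density interval beyond transcript %s (length %d)",
        transcript$id, transcript$length), call. = FALSE)
    cov <- integer(transcript$length)
    for (i in seq_along(gr)) {
      idx <- starts[i]:ends[i]
      cov[idx] <- cov[idx] + 1L
      values[idx] <- values[idx] + gr$score[i]
    }
    if (any(cov > 1L))
      stop(sprintf("overlapping density intervals in '%s'", path),
           call. = FALSE)
    if (any(values < 0))
      stop(sprintf("negative density values in '%s'", path), call. = FALSE)
  }
  density_track(transcript, values)
}

#' @rdname read_density
#' @export
write_density <- function(track, path, format = c("bedgraph", "wig")) {
  format <- match.arg(format)
  v <- track$values
  if (!any(v != 0)) {
    file.create(path)
    return(invisible(path))
  }
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values != 0
  gr <- GenomicRanges::GRanges(
    seqnames = track$transcript_id,
    ranges = IRanges::IRanges(start = starts[keep], end = ends[keep]),
    score = signif(r$values[keep], 6))
  if (format == "bedgraph") {
    rtracklayer::export(gr, path, format = "bedGraph")
  } else {
    # wiggle spans must be uniform: emit per-nucleotide positions
    nz <- which(v != 0)
    gp <- GenomicRanges::GRanges(
      seqnames = track$transcript_id,
      ranges = IRanges::IRanges(start = nz, width = 1L),
      score = signif(v[nz], 6))
    rtracklayer::export(gp, path, format = "wig")
  }
  invisible(path)
}

#' Export translons as GFF3
#'
#' Each translon becomes a `translon` parent feature spanning its full
#' extent, with one `CDS` part per segment (so trans-frame translons carry
#' their segments explicitly); the transcript id is the seqid. Segments are
#' codon-aligned by construction, so every CDS part has phase 0.
#'
#' @param rdg an rdg object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
translons_to_gff3 <- function(rdg, path) {
  tl <- translons(rdg)
  feats <- list()
  for (t in tl) {
    span <- range(c(t$segments$start, t$segments$end))
    parent <- GenomicRanges::GRanges(
      seqnames = rdg$transcript$id,
      ranges = IRanges::IRanges(start = span[1] + 1L, end = span[2]),
      strand = "+", type = "translon", ID = t$id)
    parts <- GenomicRanges::GRanges(
      seqnames = rdg$transcript$id,
      ranges = IRanges::IRanges(start = t$segments$start + 1L,
                                end = t$segments$end),
      strand = "+", type = "CDS",
      ID = paste0(t$id, ".seg", seq_len(nrow(t$segments))),
      Parent = t$id, phase = 0L)
    feats[[length(feats) + 1L]] <- parent
    feats[[length(feats) + 1L]] <- parts
  }
  gr <- if (length(feats)) suppressWarnings(do.call(c, feats))
        else GenomicRanges::GRanges()
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

RDG_SCHEMA_VERSION <- "1.0"

sequence_checksum <- function(sequence) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(sequence, tmp)
  unname(tools::md5sum(tmp))
}

#' Serialize an RDG to a versioned JSON document
#'
#' The document carries the schema version, transcript metadata (id, length
#' and an md5 checksum of the sequence, plus the sequence itself unless
#' suppressed), the reinitiation policy, events, nodes, edges, translons, an
#' optional quantification block and provenance. `rdg_from_json()` rebuilds
#' an isomorphic graph and verifies the checksum.
#'
#' @param rdg an rdg object.
#' @param path optional output file; when `NULL` the JSON text is returned.
#' @param quantification optional `rdg_quantification` to embed.
#' @param include_sequence store the sequence (default `TRUE`; the checksum
#'   is always stored).
#' @return JSON text (invisibly when written to `path`).
#' @export
rdg_to_json <- function(rdg, path = NULL, quantification = NULL,
                        include_sequence = TRUE) {
  stopifnot(inherits(rdg, "rdg"))
  ev <- lapply(rdg$events, function(e)
    list(kind = e$kind, position = e$position, detail = e$detail,
         probability = e$probability, name = e$name))
  tl <- lapply(translons(rdg), function(t)
    list(id = t$id, segments = t$segments, start_codon = t$start_codon,
         terminal_stop = t$terminal_stop,
         includes_stops = I(t$includes_stops),
         open_ended = t$open_ended, length_nt = t$length_nt))
  doc <- list(
    schema_version = RDG_SCHEMA_VERSION,
    transcript = list(
      id = rdg$transcript$id,
      length = rdg$transcript$length,
      checksum = sequence_checksum(rdg$transcript$sequence),
      sequence = if (include_sequence) rdg$transcript$sequence else NULL),
    policy = unclass(rdg$policy),
    events = ev,
    nodes = rdg$nodes,
    edges = rdg$edges,
    translons = tl,
    provenance = list(tool = "rdgraph",
                      version = as.character(utils::packageVersion("rdgraph")))
  )
  if (!is.null(quantification))
    doc$quantification <- list(
      fluxes = quantification$fluxes,
      branch_probabilities = as.list(quantification$probabilities),
      path_probabilities = as.list(quantification$path_probabilities),
      rates = quantification$rates,
      assumptions = quantification$assumptions)
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA,
                           null = "null", pretty = TRUE)
  if (!is.null(path)) {
    writeLines(json, path)
    return(invisible(as.character(json)))
  }
  as.character(json)
}

#' @param json JSON text or file path produced by [rdg_to_json()].
#' @param transcript optionally, the [transcript()] to attach when the
#'   document was written without its sequence (validated by checksum).
#' @rdname rdg_to_json
#' @export
rdg_from_json <- function(json, transcript = NULL) {
  if (length(json) == 1L && !grepl("^\\s*\\{", json) && file.exists(json))
    json <- paste(readLines(json), collapse = "\n")
  doc <- jsonlite::fromJSON(json, simplifyDataFrame = TRUE)
  if (!identical(doc$schema_version, RDG_SCHEMA_VERSION))
    stop(sprintf(
      "RDG document schema version '%s' is not supported (expected '%s')",
      doc$schema_version, RDG_SCHEMA_VERSION), call. = FALSE)
  if (!is.null(transcript)) {
    tx <- transcript
  } else if (!is.null(doc$transcript$sequence)) {
    tx <- transcript(doc$transcript$id, doc$transcript$sequence)
  } else {
    stop(paste0("document stores no sequence; supply `transcript`"),
         call. = FALSE)
  }
  if (!identical(sequence_checksum(tx$sequence), doc$transcript$checksum))
    stop("sequence checksum mismatch: wrong transcript for this document",
         call. = FALSE)
  pol <- doc$policy
  policy <- reinitiation_policy(pol$max_translon_nt, pol$recharge_model,
                                pol$recharge_distance_nt, pol$lambda_nt,
                                isTRUE(pol$aug_only),
                                isTRUE(pol$allow_chained))
  events <- lapply(seq_len(nrow(doc$events)), function(i) {
    e <- doc$events[i, ]
    p <- if (is.null(e$probability) || is.na(e$probability)) NA_real_
         else e$probability
    nm <- if (is.null(e$name) || is.na(e$name)) NULL else e$name
    switch(e$kind,
      INITIATION = initiation_event(e$position, e$detail$codon, p, nm),
      READTHROUGH = readthrough_event(e$position, p),
      SELENOCYSTEINE = selenocysteine_event(e$position, p),
      FRAMESHIFT = frameshift_event(e$position, e$detail$shift, p))
  })
  build_rdg(tx, events, policy)
}

#' Render an RDG as Graphviz DOT
#'
#' Deterministic, diff-stable output: nodes in topological (position, id)
#' order, shapes by node kind, edges labeled with the translon id or "scan".
#' Branches whose only edge is a probability-1 commit render without a
#' decision shape when `collapse_deterministic` is set.
#'
#' @param rdg an rdg object.
#' @param collapse_deterministic render probability-1 initiation branches as
#'   plain points (default `TRUE`).
#' @return A single DOT string.
#' @export
rdg_to_dot <- function(rdg, collapse_deterministic = TRUE) {
  shape_for <- function(kind) switch(kind,
    ENTRY = "circle", EXIT = "doublecircle", TERMINATION = "box",
    "diamond")
  nd <- rdg$nodes[order(rdg$nodes$position, rdg$nodes$id), , drop = FALSE]
  outdeg <- table(factor(rdg$edges$from, levels = nd$id))
  lines <- c("digraph rdg {", "  rankdir=LR;",
             sprintf("  label=\"%s\";", rdg$transcript$id))
  for (i in seq_len(nrow(nd))) {
    shape <- shape_for(nd$kind[i])
    if (collapse_deterministic && grepl("^BRANCH_", nd$kind[i]) &&
        outdeg[[nd$id[i]]] == 1L)
      shape <- "point"
    lines <- c(lines, sprintf(
      "  \"%s\" [shape=%s, label=\"%s\"];", nd$id[i], shape,
      if (shape == "point") "" else nd$id[i]))
  }
  ed <- rdg$edges[order(rdg$edges$id), , drop = FALSE]
  for (i in seq_len(nrow(ed))) {
    lab <- if (!is.na(ed$translon[i])) ed$translon[i] else "scan"
    p <- ed$probability[i]
    if (!is.na(p)) lab <- sprintf("%s (%.6g)", lab, p)
    style <- if (ed$kind[i] == "TRANSLATE") "solid" else "dashed"
    lines <- c(lines, sprintf(
      "  \"%s\" -> \"%s\" [label=\"%s\", style=%s];",
      ed$from[i], ed$to[i], lab, style))
  }
  paste(c(lines, "}"), collapse = "\n")
}

#' Plot an RDG as a layered translon diagram
#'
#' Base-graphics rendering: the transcript as a baseline, translon segments
#' as frame-colored arrows stacked above it, branch points marked on the
#' baseline.
#'
#' @param x an rdg object.
#' @param ... ignored.
#' @return `x`, invisibly.
#' @export
plot.rdg <- function(x, ...) {
  tl <- translons(x)
  n <- max(length(tl), 1)
  L <- x$transcript$length
  graphics::plot(NA, xlim = c(0, L), ylim = c(-1.5, n + 0.5),
                 xlab = "transcript position (nt)", ylab = "",
                 yaxt = "n", main = x$transcript$id, bty = "n")
  graphics::segments(0, 0, L, 0, lwd = 2)
  cols <- c("#1b9e77", "#d95f02", "#7570b3")
  for (i in seq_along(tl)) {
    t <- tl[[i]]
    for (s in seq_len(nrow(t$segments)))
      graphics::arrows(t$segments$start[s], i, t$segments$end[s], i,
                       length = if (s == nrow(t$segments)) 0.08 else 0,
                       lwd = 3, col = cols[t$segments$frame[s] + 1L])
    graphics::text(t$start, i + 0.3, t$id, adj = 0, cex = 0.8)
  }
  bn <- branch_nodes(x)
  if (nrow(bn))
    graphics::points(bn$position, rep(0, nrow(bn)), pch = 18, cex = 1.4,
                     col = "firebrick")
  graphics::axis(2, at = seq_along(tl), labels = FALSE)
  invisible(x)
}
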