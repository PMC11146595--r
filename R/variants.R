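#' Transcript-space variant
#'
#' A minimal variant record in transcript coordinates: at 0-based `position`,
#' `ref` (possibly empty for a pure insertion) is replaced by `alt` (possibly
#' empty for a pure deletion). Genomic VCF coordinates must be lifted to
#' transcript space by the caller; splicing liftover is out of scope.
#'
#' @param transcript_id id of the transcript the variant applies to.
#' @param position 0-based coordinate of the first replaced base (for a pure
#'   insertion, the base before which `alt` is inserted).
#' @param ref reference allele (`""` for insertion); validated on apply.
#' @param alt alternate allele (`""` for deletion).
#' @return An object of class `variant_spec`.
#' @export
variant_spec <- function(transcript_id, position, ref, alt) {
  ref <- if (nzchar(ref)) normalize_rna(ref) else ""
  alt <- if (nzchar(alt)) normalize_rna(alt) else ""
  if (!nzchar(ref) && !nzchar(alt))
    stop("variant with empty ref and alt is not an edit", call. = FALSE)
  structure(
    list(transcript_id = transcript_id, position = as.integer(position),
         ref = ref, alt = alt),
    class = "variant_spec"
  )
}

#' @export
print.variant_spec <- function(x, ...) {
  cat(sprintf("%s:%d %s>%s\n", x$transcript_id, x$position,
              ifelse(nzchar(x$ref), x$ref, "-"),
              ifelse(nzchar(x$alt), x$alt, "-")))
  invisible(x)
}

variant_shift <- function(variant) nchar(variant$alt) - nchar(variant$ref)

# Map a variant-transcript coordinate back to reference space (identity
# upstream of the edit, offset by the indel length downstream).
correct_offset <- function(pos, variant) {
  ifelse(pos <= variant$position, pos, pos - variant_shift(variant))
}

# Composed corrector for one variant or a coordinate-sorted list applied
# sequentially: undoes the edits in reverse application order.
offset_corrector <- function(variants) {
  if (inherits(variants, "variant_spec")) variants <- list(variants)
  pos <- vapply(variants, `[[`, integer(1), "position")
  variants <- variants[order(pos)]
  shift <- 0L
  adjusted <- list()
  for (v in variants) {
    v$position <- v$position + shift     # position in applied space
    adjusted[[length(adjusted) + 1L]] <- v
    shift <- shift + variant_shift(v)
  }
  function(p) {
    for (v in rev(adjusted)) p <- correct_offset(p, v)
    p
  }
}

#' Apply a variant to a transcript
#'
#' @param transcript a [transcript()] object.
#' @param variant a [variant_spec()]; `ref` must match the sequence at
#'   `position`.
#' @return A new [transcript()] whose id carries a variant tag; length
#'   changes by `nchar(alt) - nchar(ref)`.
#' @examples
#' tx <- transcript("t", "AUGUAA")
#' apply_variant(tx, variant_spec("t", 3, "", "C"))$sequence
#' @export
apply_variant <- function(transcript, variant) {
  stop_if_not_transcript(transcript)
  stopifnot(inherits(variant, "variant_spec"))
  if (variant$transcript_id != transcript$id)
    stop(sprintf("variant targets '%s' but transcript is '%s'",
                 variant$transcript_id, transcript$id), call. = FALSE)
  p <- variant$position
  nref <- nchar(variant$ref)
  if (p < 0 || p + nref > transcript$length)
    stop("variant lies outside the transcript", call. = FALSE)
  observed <- substr(transcript$sequence, p + 1L, p + nref)
  if (observed != variant$ref)
    stop(sprintf(
      "ref mismatch at %d: expected '%s', observed '%s'",
      p, variant$ref, observed), call. = FALSE)
  new_seq <- paste0(substr(transcript$sequence, 1L, p), variant$alt,
                    substr(transcript$sequence, p + nref + 1L,
                           transcript$length))
  tag <- sprintf("%s:%d%s>%s", transcript$id, p + 1L,
                 ifelse(nzchar(variant$ref), variant$ref, "-"),
                 ifelse(nzchar(variant$alt), variant$alt, "-"))
  transcript(tag, new_seq)
}

#' Re-derive events after applying a variant
#'
#' Edits create and destroy codons, so events must be re-derived rather than
#' merely shifted. Initiation sites are rediscovered on the edited sequence
#' over `start_codons` plus any codon used by an existing initiation event;
#' rediscovered sites matching a carried-over event (offset-corrected
#' position, same codon) inherit its probability and name, new sites start
#' unassigned. Non-initiation events are shifted by the indel offset when
#' downstream of the edit and dropped with a warning when the edit destroys
#' their codon.
#'
#' @param transcript the reference [transcript()].
#' @param variant a [variant_spec()].
#' @param events reference event list.
#' @param start_codons codon set for start-site rediscovery (the event
#'   derivation policy); defaults to `"AUG"`.
#' @return `list(transcript = <edited>, events = <re-derived>)`.
#' @export
rebuild_after_variant <- function(transcript, variant, events,
                                  start_codons = "AUG") {
  new_tx <- apply_variant(transcript, variant)
  shift <- variant_shift(variant)
  shift_pos <- function(p) if (p > variant$position) p + shift else p

  init_ev <- Filter(function(e) e$kind == "INITIATION", events)
  other_ev <- Filter(function(e) e$kind != "INITIATION", events)

  codon_set <- unique(c(validate_codons(start_codons),
                        vapply(init_ev, function(e) e$detail$codon,
                               character(1))))
  sites <- find_start_sites(new_tx, codon_set)

  carried <- lapply(init_ev, function(e) {
    np <- shift_pos(e$position)
    if (np + 3L <= new_tx$length && codon_at(new_tx, np) == e$detail$codon)
      list(position = np, event = e)
    else {
      warning(sprintf(
        "variant destroys the %s start codon of the initiation event at %d; dropped",
        e$detail$codon, e$position), call. = FALSE)
      NULL
    }
  })
  carried <- Filter(Negate(is.null), carried)
  carried_pos <- vapply(carried, `[[`, integer(1), "position")

  new_events <- lapply(seq_len(nrow(sites)), function(i) {
    hit <- match(sites$position[i], carried_pos)
    if (!is.na(hit)) {
      old <- carried[[hit]]$event
      initiation_event(sites$position[i], old$detail$codon,
                       old$probability, old$name)
    } else {
      initiation_event(sites$position[i], sites$codon[i])
    }
  })

  for (e in other_ev) {
    np <- shift_pos(e$position)
    ok <- switch(e$kind,
      SELENOCYSTEINE = np + 3L <= new_tx$length &&
        codon_at(new_tx, np) == "UGA",
      READTHROUGH = np + 3L <= new_tx$length &&
        codon_at(new_tx, np) %in% STOP_CODONS,
      FRAMESHIFT = np < new_tx$length)
    if (ok) {
      e$position <- np
      new_events[[length(new_events) + 1L]] <- e
    } else {
      warning(sprintf("variant destroys the codon of the %s event at %d; dropped",
                      e$kind, e$position), call. = FALSE)
    }
  }
  list(transcript = new_tx, events = sort_events(new_events))
}

#' Diff two ribosome decision graphs
#'
#' Compares a reference graph with the graph rebuilt after a variant and
#' reports the topology differences: translons lost, gained or modified, and
#' whether a designated CDS translon remains reachable by any ribosome path.
#'
#' Translons are matched in two stages, both after correcting variant-graph
#' coordinates for the indel offset: first by (terminal stop, frame) --
#' capturing proteoforms with alternative N termini, whose starts move but
#' stops do not -- then the remainder by (start, start codon), capturing
#' C-terminal extension or truncation when a frame shift or stop loss moves
#' the stop itself. Matched pairs with unequal spans are classified
#' `EXTENDED`/`TRUNCATED` by length (or `FRAME_CHANGED` when only the
#' terminal frame differs); unmatched translons are lost/gained.
#'
#' @param reference_rdg,variant_rdg graphs built from the same transcript
#'   lineage (the variant transcript id must extend the reference id).
#' @param variant the [variant_spec()] used, for offset correction; when
#'   `NULL` the offset is taken as zero.
#' @param cds_translon id (in the reference graph) of the translon regarded
#'   as the CDS, for reachability reporting; optional.
#' @return An object of class `rdg_diff` with fields `translons_lost`,
#'   `translons_gained`, `translons_modified` (data.frame: ref_id, var_id,
#'   change), `branches_lost`, `branches_gained`, `cds_reachable_before`,
#'   `cds_reachable_after`.
#' @export
diff_rdg <- function(reference_rdg, variant_rdg, variant = NULL,
                     cds_translon = NULL) {
  stopifnot(inherits(reference_rdg, "rdg"), inherits(variant_rdg, "rdg"))
  ref_id <- reference_rdg$transcript$id
  var_id <- variant_rdg$transcript$id
  if (!identical(ref_id, var_id) && !startsWith(var_id, ref_id))
    stop(sprintf(
      "graphs are from unrelated transcripts ('%s' vs '%s')",
      ref_id, var_id), call. = FALSE)
  corr <- if (is.null(variant)) identity else offset_corrector(variant)

  ref_tl <- translons(reference_rdg)
  var_tl <- translons(variant_rdg)

  key_stop <- function(t, correct = FALSE) {
    if (t$open_ended) return(NA_character_)
    stop_pos <- if (correct) corr(t$terminal_stop) else t$terminal_stop
    sprintf("s%d.f%d", stop_pos, stop_pos %% 3L)
  }
  key_start <- function(t, correct = FALSE) {
    start <- if (correct) corr(t$start) else t$start
    sprintf("p%d.%s", start, t$start_codon)
  }

  ref_left <- names(ref_tl)
  var_left <- names(var_tl)
  pairs <- list()
  match_stage <- function(keyfun) {
    rk <- vapply(ref_tl[ref_left], keyfun, character(1), correct = FALSE)
    vk <- vapply(var_tl[var_left], keyfun, character(1), correct = TRUE)
    for (i in seq_along(rk)) {
      if (is.na(rk[i])) next
      j <- which(vk == rk[i])
      if (length(j) >= 1L) {
        pairs[[length(pairs) + 1L]] <<- c(ref = ref_left[i],
                                          var = var_left[j[1]])
        vk[j[1]] <- NA_character_
      }
    }
    matched_ref <- vapply(pairs, `[[`, character(1), "ref")
    matched_var <- vapply(pairs, `[[`, character(1), "var")
    ref_left <<- setdiff(ref_left, matched_ref)
    var_left <<- setdiff(var_left, matched_var)
  }
  match_stage(key_stop)
  match_stage(key_start)

  modified <- data.frame(ref_id = character(0), var_id = character(0),
                         change = character(0), stringsAsFactors = FALSE)
  for (p in pairs) {
    rt <- ref_tl[[p[["ref"]]]]
    vt <- var_tl[[p[["var"]]]]
    same_span <- rt$start == corr(vt$start) && rt$length_nt == vt$length_nt
    if (same_span) next
    change <-
      if (vt$length_nt > rt$length_nt) "EXTENDED"
      else if (vt$length_nt < rt$length_nt) "TRUNCATED"
      else "FRAME_CHANGED"
    modified <- rbind(modified, data.frame(
      ref_id = p[["ref"]], var_id = p[["var"]], change = change,
      stringsAsFactors = FALSE))
  }

  branch_key <- function(rdg, correct) {
    nd <- branch_nodes(rdg)
    if (!nrow(nd)) return(character(0))
    pos <- if (correct) corr(nd$position) else nd$position
    sprintf("%s@%d", nd$kind, pos)
  }
  rb <- branch_key(reference_rdg, FALSE)
  vb <- branch_key(variant_rdg, TRUE)

  cds_before <- NA
  cds_after <- NA
  if (!is.null(cds_translon)) {
    if (!cds_translon %in% names(ref_tl))
      stop(sprintf("unknown CDS translon '%s' in reference graph",
                   cds_translon), call. = FALSE)
    cds_before <- length(paths_containing(reference_rdg, cds_translon)) > 0
    hit <- Filter(function(p) p[["ref"]] == cds_translon, pairs)
    cds_after <- if (length(hit))
      length(paths_containing(variant_rdg, hit[[1]][["var"]])) > 0
    else FALSE
  }

  structure(
    list(translons_lost = ref_left,
         translons_gained = var_left,
         translons_modified = modified,
         branches_lost = setdiff(rb, vb),
         branches_gained = setdiff(vb, rb),
         cds_translon = cds_translon,
         cds_reachable_before = cds_before,
         cds_reachable_after = cds_after),
    class = "rdg_diff"
  )
}

#' @export
print.rdg_diff <- function(x, ...) {
  cat("RDG diff\n")
  cat(sprintf("  translons lost:   %s\n",
              if (length(x$translons_lost))
                paste(x$translons_lost, collapse = ", ") else "-"))
  cat(sprintf("  translons gained: %s\n",
              if (length(x$translons_gained))
                paste(x$translons_gained, collapse = ", ") else "-"))
  if (nrow(x$translons_modified)) {
    cat("  translons modified:\n")
    for (i in seq_len(nrow(x$translons_modified)))
      cat(sprintf("    %s -> %s: %s\n", x$translons_modified$ref_id[i],
                  x$translons_modified$var_id[i],
                  x$translons_modified$change[i]))
  }
  if (!is.null(x$cds_translon))
    cat(sprintf("  CDS translon %s reachable: before %s, after %s\n",
                x$cds_translon, x$cds_reachable_before, x$cds_reachable_after))
  invisible(x)
}

#' Read and write variants as 4-column TSV or minimal VCF
#'
#' TSV columns: transcript_id, position (0-based), ref, alt (`"-"` or empty
#' for absent allele). Files whose first data line starts with `#` or that
#' end in `.vcf` are parsed as minimal VCF (CHROM = transcript id, 1-based
#' POS, anchored-base indel convention converted to the internal pure
#' insertion/deletion form).
#'
#' @param path file path.
#' @param variants list of [variant_spec()] (writer).
#' @return `read_variants()` returns a list of [variant_spec()].
#' @export
read_variants <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\\.vcf$", path, ignore.case = TRUE) || startsWith(first, "#")) {
    lines <- readLines(path)
    lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
    recs <- strsplit(lines, "\t", fixed = TRUE)
    return(lapply(recs, function(f) {
      pos1 <- as.integer(f[2])
      ref <- normalize_rna(f[4])
      alt <- normalize_rna(f[5])
      # strip the shared anchor base of VCF-style indels
      while (nchar(ref) && nchar(alt) &&
             substr(ref, 1, 1) == substr(alt, 1, 1) &&
             (nchar(ref) > 1 || nchar(alt) > 1)) {
        ref <- substr(ref, 2, nchar(ref))
        alt <- substr(alt, 2, nchar(alt))
        pos1 <- pos1 + 1L
      }
      variant_spec(f[1], pos1 - 1L, ref, alt)
    }))
  }
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE, comment.char = "",
                           col.names = c("transcript_id", "position", "ref",
                                         "alt"))
  lapply(seq_len(nrow(tab)), function(i) {
    clean <- function(x) if (is.na(x) || x %in% c("-", ".", "")) "" else x
    variant_spec(tab$transcript_id[i], tab$position[i],
                 clean(tab$ref[i]), clean(tab$alt[i]))
  })
}

#' @rdname read_variants
#' @export
write_variants <- function(variants, path) {
  tab <- do.call(rbind, lapply(variants, function(v) data.frame(
    transcript_id = v$transcript_id, position = v$position,
    ref = ifelse(nzchar(v$ref), v$ref, "-"),
    alt = ifelse(nzchar(v$alt), v$alt, "-"), stringsAsFactors = FALSE)))
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
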