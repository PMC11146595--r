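#' Create a transcript object
#'
#' A transcript is the universe over which a single ribosome decision graph is
#' defined: one mRNA sequence with an identifier. Sequences are stored in the
#' RNA alphabet; `T` is accepted on input and normalized to `U`. All
#' coordinates used throughout the package are 0-based, half-open and in
#' transcript space.
#'
#' @param id single character identifier.
#' @param sequence nucleotide string over \{A, C, G, U\} (or T, normalized).
#' @return An object of class `transcript` with fields `id`, `sequence` and
#'   `length`.
#' @examples
#' tx <- transcript("tx1", "CCAUGGCCUAGCC")
#' tx$length
#' @export
transcript <- function(id, sequence) {
  if (!is.character(id) || length(id) != 1L || is.na(id) || !nzchar(id))
    stop("transcript `id` must be a single non-empty string", call. = FALSE)
  if (!is.character(sequence) || length(sequence) != 1L || is.na(sequence))
    stop("transcript `sequence` must be a single string", call. = FALSE)
  seq <- normalize_rna(sequence)
  structure(
    list(id = id, sequence = seq, length = nchar(seq)),
    class = "transcript"
  )
}

# T -> U normalization plus alphabet validation; used by every sequence entry
# point so downstream code can assume a clean {A,C,G,U} string.
normalize_rna <- function(sequence) {
  seq <- chartr("t", "u", toupper(sequence))
  seq <- chartr("T", "U", seq)
  bad <- gsub("[ACGU]", "", seq)
  if (nzchar(bad))
    stop(sprintf("sequence contains invalid characters: %s",
                 paste(unique(strsplit(bad, "")[[1]]), collapse = ", ")),
         call. = FALSE)
  seq
}

#' @export
print.transcript <- function(x, ...) {
  head_seq <- if (x$length > 60) paste0(substr(x$sequence, 1, 57), "...")
              else x$sequence
  cat(sprintf("transcript %s (%d nt)\n  %s\n", x$id, x$length, head_seq))
  invisible(x)
}

#' @export
as.character.transcript <- function(x, ...) x$sequence

is_transcript <- function(x) inherits(x, "transcript")

stop_if_not_transcript <- function(x) {
  if (!is_transcript(x))
    stop("expected a `transcript` object (see transcript())", call. = FALSE)
  invisible(x)
}

# Codon starting at 0-based position `pos` (must leave 3 nt).
codon_at <- function(transcript, pos) {
  substr(transcript$sequence, pos + 1L, pos + 3L)
}

STOP_CODONS <- c("UAA", "UAG", "UGA")
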