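#' Enumerate ribosome paths
#'
#' A ribosome path (RiboPath) is one complete passage of a small-subunit
#' containing ribosomal complex from the 5' cap (entry) to final dissociation
#' (exit); it carries the ordered, possibly empty, set of translons it
#' translated. Paths are enumerated depth-first in 5'-committed order: at each
#' branch the commit edge is explored before the continue edge, so path ids
#' are stable across runs. Path identity is the edge sequence, not the
#' translon set: two paths with identical products but different decisions
#' are distinct.
#'
#' @param rdg an [build_rdg()] object.
#' @param include_unproductive keep paths with no translons (default `TRUE`).
#' @param max_paths refuse to enumerate more than this many paths; the error
#'   carries the exact count from [count_paths()]. Default `1e6`; conceptual
#'   graphs over exhaustive start sets need an explicit override.
#' @return List of class `ribo_paths`; each element has `id`, `edges`
#'   (ordered edge ids), `nodes`, `translon_ids` (5'->3') and `productive`.
#' @examples
#' fx <- make_fig3_transcript()
#' g <- build_rdg(fx$transcript, fx$events, fx$policy)
#' length(enumerate_paths(g))  # 5
#' @export
enumerate_paths <- function(rdg, include_unproductive = TRUE,
                            max_paths = 1e6) {
  stopifnot(inherits(rdg, "rdg"))
  n <- count_paths(rdg, include_unproductive = TRUE)
  if (n > max_paths)
    stop(sprintf(
      "graph has %d root-to-exit paths, above max_paths = %g; raise max_paths to enumerate",
      n, max_paths), call. = FALSE)
  edges_by_from <- split(rdg$edges, rdg$edges$from)
  term_translon <- term_node_translons(rdg)
  acc <- vector("list", n)
  k <- 0L
  walk <- function(node, edge_ids, node_ids) {
    if (node == rdg$exit) {
      k <<- k + 1L
      tr <- unname(term_translon[node_ids])
      tr <- tr[!is.na(tr)]
      acc[[k]] <<- list(id = NA_character_, edges = edge_ids,
                        nodes = c(node_ids, node),
                        translon_ids = tr, productive = length(tr) > 0)
      return(invisible(NULL))
    }
    oe <- edges_by_from[[node]]
    oe <- oe[order(match(oe$role, c("commit", "continue")), oe$id), ,
             drop = FALSE]
    for (i in seq_len(nrow(oe)))
      walk(oe$to[i], c(edge_ids, oe$id[i]), c(node_ids, node))
    invisible(NULL)
  }
  walk(rdg$root, character(0), character(0))
  for (i in seq_len(k)) acc[[i]]$id <- sprintf("P%d", i)
  if (!include_unproductive)
    acc <- Filter(function(p) p$productive, acc[seq_len(k)])
  structure(acc, class = "ribo_paths")
}

# Translon terminated at each TERMINATION node (NA for other nodes).
term_node_translons <- function(rdg) {
  out <- rep(NA_character_, nrow(rdg$nodes))
  names(out) <- rdg$nodes$id
  tn <- rdg$nodes$id[rdg$nodes$kind == "TERMINATION"]
  out[tn] <- sub("\\*nr$", "", sub("^term@[0-9]+:", "", tn))
  out
}

#' @export
print.ribo_paths <- function(x, ...) {
  cat(sprintf("%d ribosome path(s)\n", length(x)))
  for (p in x)
    cat(sprintf("  %s: {%s}%s\n", p$id,
                paste(p$translon_ids, collapse = ", "),
                if (p$productive) "" else " (unproductive)"))
  invisible(x)
}

#' Count ribosome paths without enumeration
#'
#' Exact root-to-exit path count by dynamic programming in topological order;
#' scales to conceptual graphs whose path counts grow exponentially with the
#' number of branch points.
#'
#' @inheritParams enumerate_paths
#' @return A numeric count (exact; may exceed integer range).
#' @export
count_paths <- function(rdg, include_unproductive = TRUE) {
  stopifnot(inherits(rdg, "rdg"))
  total <- dp_path_count(rdg, drop_terminations = FALSE)
  if (include_unproductive) return(total)
  unproductive <- dp_path_count(rdg, drop_terminations = TRUE)
  total - unproductive
}

# Paths root->exit; with drop_terminations, only paths avoiding every
# TERMINATION node (i.e. unproductive paths) are counted.
dp_path_count <- function(rdg, drop_terminations = FALSE) {
  ids <- rdg$nodes$id
  kind <- setNames(rdg$nodes$kind, ids)
  memo <- new.env(parent = emptyenv())
  edges_by_from <- split(rdg$edges$to, rdg$edges$from)
  rec <- function(node) {
    if (drop_terminations && kind[[node]] == "TERMINATION") return(0)
    if (node == rdg$exit) return(1)
    got <- memo[[node]]
    if (!is.null(got)) return(got)
    val <- sum(vapply(edges_by_from[[node]] %||% character(0), rec,
                      numeric(1)))
    memo[[node]] <- val
    val
  }
  rec(rdg$root)
}

#' Are two translons mutually exclusive?
#'
#' Translons are mutually exclusive when no ribosome path contains both (a
#' single ribosome can never translate both regions).
#'
#' @param rdg an rdg object.
#' @param translon_a,translon_b translon ids.
#' @param max_paths passed to [enumerate_paths()].
#' @return `TRUE` or `FALSE`. A translon is never exclusive with itself.
#' @export
mutually_exclusive <- function(rdg, translon_a, translon_b,
                               max_paths = 1e6) {
  for (t in c(translon_a, translon_b))
    if (!t %in% names(rdg$translons))
      stop(sprintf("unknown translon id '%s'", t), call. = FALSE)
  if (translon_a == translon_b) return(FALSE)
  paths <- enumerate_paths(rdg, max_paths = max_paths)
  !any(vapply(paths, function(p)
    all(c(translon_a, translon_b) %in% p$translon_ids), logical(1)))
}

#' Paths containing a translon
#'
#' @param rdg an rdg object.
#' @param translon_id translon id.
#' @param max_paths passed to [enumerate_paths()].
#' @return A `ribo_paths` list (subset of [enumerate_paths()]).
#' @export
paths_containing <- function(rdg, translon_id, max_paths = 1e6) {
  if (!translon_id %in% names(rdg$translons))
    stop(sprintf("unknown translon id '%s'", translon_id), call. = FALSE)
  paths <- enumerate_paths(rdg, max_paths = max_paths)
  structure(Filter(function(p) translon_id %in% p$translon_ids, paths),
            class = "ribo_paths")
}

#' Write a path report as TSV
#'
#' Columns: path id, probability (from `probs` when supplied, else `NA`),
#' comma-joined translon ids, productive flag.
#'
#' @param paths a `ribo_paths` list.
#' @param path output file.
#' @param probs optional named probability vector from
#'   [path_probabilities()].
#' @return `path`, invisibly.
#' @export
write_paths <- function(paths, path, probs = NULL) {
  tab <- do.call(rbind, lapply(paths, function(p) data.frame(
    path_id = p$id,
    probability = if (!is.null(probs) && p$id %in% names(probs))
      signif(probs[[p$id]], 6) else NA_real_,
    translons = paste(p$translon_ids, collapse = ","),
    productive = p$productive, stringsAsFactors = FALSE)))
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
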