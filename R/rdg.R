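#' Build a ribosome decision graph
#'
#' Constructs the rooted directed acyclic graph describing every decision a
#' single scanning/elongating ribosome can make on a transcript. The entry
#' node is the 5' cap; the scanning route visits initiation events in 5'->3'
#' order, each becoming a branch with a commit edge (open the translon) and a
#' continue edge (keep scanning). A translon elongates to its next in-frame
#' stop unless a readthrough/selenocysteine event at that stop, or a
#' frameshift event within its span, inserts an elongation branch. Stop codons
#' without events are deterministic ends of translons. After a termination
#' whose translon satisfies the reinitiation policy, a reinitiation branch
#' offers resumption of scanning strictly downstream of the termination site
#' (the target start is selected by the recharge model) versus exit; the final
#' leaky continue edge ends at the exit node, the unproductive path.
#'
#' An initiation event with `probability = 1` is deterministic: the branch
#' node is retained but no leak edge is built, so scanning cannot proceed past
#' it (annotated CDS starts are conventionally treated this way). Initiation
#' events that no scanning route can reach -- downstream of a deterministic
#' start and never selected as a reinitiation target -- contribute no branch
#' and no translon.
#'
#' @param transcript a [transcript()] object.
#' @param events list of [translation_events].
#' @param policy a [reinitiation_policy()].
#' @return An object of class `rdg` with fields `transcript`, `events`,
#'   `policy`, `nodes` (data.frame: id, kind, position), `edges` (data.frame:
#'   id, from, to, kind, role, translon, probability), and `translons`
#'   (named list).
#' @examples
#' fx <- make_fig3_transcript()
#' g <- build_rdg(fx$transcript, fx$events, fx$policy)
#' g
#' @export
build_rdg <- function(transcript, events, policy = reinitiation_policy()) {
  stop_if_not_transcript(transcript)
  if (!inherits(policy, "reinitiation_policy"))
    stop("`policy` must be a reinitiation_policy()", call. = FALSE)
  events <- sort_events(events)
  validate_events(transcript, events)

  init_events <- Filter(function(e) e$kind == "INITIATION", events)
  elong_events <- Filter(function(e) e$kind != "INITIATION", events)

  # iterate to a fixed point so events unreachable by any scanning route
  # (behind a deterministic start) contribute no translon
  repeat {
    built <- build_rdg_impl(transcript, init_events, elong_events, policy,
                            events)
    if (length(built$used_idx) == length(init_events)) break
    init_events <- init_events[built$used_idx]
  }
  built$rdg
}

build_rdg_impl <- function(transcript, init_events, elong_events, policy,
                           events) {
  # --- phase 1: decision trees of translon variants, one per initiation site
  trees <- vector("list", length(init_events))
  registry <- new.env(parent = emptyenv())   # leaf_key -> translon
  used_elong <- new.env(parent = emptyenv())
  for (i in seq_along(init_events)) {
    trees[[i]] <- translon_tree(transcript, elong_events, init_events[[i]],
                                sprintf("ev%d", i), registry, used_elong)
  }
  for (ev in elong_events) {
    key <- sprintf("pos%d", ev$position)
    if (is.null(used_elong[[key]]))
      warning(sprintf(
        "%s event at %d is not crossed in frame by any translon; ignored",
        ev$kind, ev$position), call. = FALSE)
  }

  translons <- assign_translon_ids(registry, trees, init_events)

  # --- phase 2: materialize nodes and edges
  b <- graph_builder(transcript, translons)
  ctx <- list(policy = policy, init_events = init_events, trees = trees,
              registry = registry, builder = b,
              used = new.env(parent = emptyenv()))

  b$add_node("entry", "ENTRY", 0L)
  b$add_node("exit", "EXIT", transcript$length)

  cur <- "entry"
  cur_p <- NA_real_
  for (i in seq_along(init_events)) {
    ev <- init_events[[i]]
    bid <- sprintf("init@%d", ev$position)
    b$add_node(bid, "BRANCH_INIT", ev$position)
    b$add_edge(cur, bid, "SCAN",
               role = if (cur == "entry") NA_character_ else "continue",
               probability = if (is.na(cur_p)) NA_real_ else 1 - cur_p)
    entry <- chain_entry(ctx, i, allow_reinit = TRUE)
    b$add_edge(bid, entry$node, "TRANSLATE", role = "commit",
               translon = entry$translon, probability = ev$probability)
    if (!is.na(ev$probability) && ev$probability == 1) {
      cur <- NULL   # deterministic start: scanning cannot proceed past it
      break
    }
    cur <- bid
    cur_p <- ev$probability
  }
  if (!is.null(cur)) {
    b$add_edge(cur, "exit", "SCAN",
               role = if (cur == "entry") NA_character_ else "continue",
               probability = if (is.na(cur_p)) NA_real_ else 1 - cur_p)
  }

  g <- structure(
    list(transcript = transcript, events = events, policy = policy,
         nodes = b$nodes(), edges = b$edges(),
         translons = translons, root = "entry", exit = "exit"),
    class = "rdg"
  )
  used_idx <- sort(as.integer(ls(ctx$used)))
  list(rdg = g, used_idx = used_idx)
}

# ---------------------------------------------------------------------------
# translon decision trees

# Recursive walk of one elongating ribosome from a start codon. Branches are
# frameshift sites within the span (commit = shift, continue = stay in frame)
# and readthrough/selenocysteine events at the next in-frame stop (commit =
# decode through, continue = terminate). Leaves are complete translons.
translon_tree <- function(transcript, elong_events, init_event, key_prefix,
                          registry, used_elong) {
  counter <- new.env(parent = emptyenv())
  counter$n <- 0L
  walk <- function(seg_start, scan_from, frame, segs_done, includes) {
    stop_pos <- next_in_frame_stop(transcript, scan_from, frame)
    fs <- Filter(function(e)
      e$kind == "FRAMESHIFT" && e$position >= scan_from &&
        e$position %% 3L == frame &&
        (is.null(stop_pos) || e$position < stop_pos),
      elong_events)
    if (length(fs)) {
      q <- min(vapply(fs, `[[`, integer(1), "position"))
      ev <- fs[[which.min(vapply(fs, `[[`, integer(1), "position"))]]
      used_elong[[sprintf("pos%d", ev$position)]] <- TRUE
      shift <- ev$detail$shift
      new_start <- q + shift
      list(type = "branch", kind = "FRAMESHIFT", pos = q, event = ev,
           continue = walk(seg_start, q + 3L, frame, segs_done, includes),
           commit = walk(new_start, new_start, new_start %% 3L,
                         c(segs_done,
                           list(c(start = seg_start, end = q, frame = frame))),
                         includes))
    } else if (!is.null(stop_pos)) {
      rt <- Filter(function(e)
        e$kind %in% c("READTHROUGH", "SELENOCYSTEINE") &&
          e$position == stop_pos,
        elong_events)
      if (length(rt)) {
        ev <- rt[[1]]
        used_elong[[sprintf("pos%d", ev$position)]] <- TRUE
        list(type = "branch", kind = "READTHROUGH", pos = stop_pos,
             event = ev,
             continue = leaf(seg_start, stop_pos + 3L, frame, segs_done,
                             includes, stop_pos),
             commit = walk(seg_start, stop_pos + 3L, frame, segs_done,
                           c(includes, stop_pos)))
      } else {
        leaf(seg_start, stop_pos + 3L, frame, segs_done, includes, stop_pos)
      }
    } else {
      # no in-frame stop before the 3' end: open-ended translon
      end <- seg_start + 3L * ((transcript$length - seg_start) %/% 3L)
      leaf(seg_start, end, frame, segs_done, includes, NA_integer_)
    }
  }
  leaf <- function(seg_start, end, frame, segs_done, includes, stop_pos) {
    counter$n <- counter$n + 1L
    key <- sprintf("%s.%d", key_prefix, counter$n)
    segs <- c(segs_done, list(c(start = seg_start, end = end, frame = frame)))
    segdf <- as.data.frame(do.call(rbind, segs))
    registry[[key]] <- list(
      id = NA_character_,
      start = segdf$start[1],
      segments = segdf,
      start_codon = init_event$detail$codon,
      terminal_stop = stop_pos,
      includes_stops = includes,
      open_ended = is.na(stop_pos),
      length_nt = sum(segdf$end - segdf$start)
    )
    list(type = "leaf", leaf_key = key)
  }
  p <- init_event$position
  walk(p, p + 3L, p %% 3L, list(), integer(0))
}

base_leaf_key <- function(tree) {
  while (tree$type == "branch") tree <- tree$continue
  tree$leaf_key
}

tree_leaf_keys <- function(tree) {
  if (tree$type == "leaf") return(tree$leaf_key)
  c(tree_leaf_keys(tree$continue), tree_leaf_keys(tree$commit))
}

# Stable translon naming: explicit event names label the base (all-continue)
# variant; everything else is numbered T<k> in 5' order (start, then span end).
assign_translon_ids <- function(registry, trees, init_events) {
  keys <- unlist(lapply(trees, tree_leaf_keys))
  if (!length(keys)) return(list())
  tl <- lapply(keys, function(k) registry[[k]])
  starts <- vapply(tl, `[[`, numeric(1), "start")
  ends <- vapply(tl, function(t) max(t$segments$end), numeric(1))
  ord <- order(starts, ends)
  names_out <- rep(NA_character_, length(keys))
  for (i in seq_along(trees)) {
    ev <- init_events[[i]]
    if (is.null(ev$name)) next
    lk <- tree_leaf_keys(trees[[i]])
    bk <- base_leaf_key(trees[[i]])
    names_out[match(bk, keys)] <- ev$name
    extra <- setdiff(lk, bk)
    if (length(extra))
      names_out[match(extra, keys)] <- paste0(ev$name, ".v",
                                              seq_along(extra) + 1L)
  }
  k <- 0L
  for (j in ord) {
    if (is.na(names_out[j])) {
      repeat {
        k <- k + 1L
        cand <- paste0("T", k)
        if (!cand %in% names_out) break
      }
      names_out[j] <- cand
    }
  }
  if (anyDuplicated(names_out))
    stop("duplicate translon names", call. = FALSE)
  out <- list()
  for (j in ord) {
    tr <- tl[[j]]
    tr$id <- names_out[j]
    registry[[keys[j]]]$id <- names_out[j]
    out[[names_out[j]]] <- tr
  }
  out
}

# ---------------------------------------------------------------------------
# graph materialization

graph_builder <- function(transcript, translons) {
  env <- new.env(parent = emptyenv())
  env$nodes <- list()
  env$edges <- list()
  env$n_edge <- 0L
  add_node <- function(id, kind, position) {
    if (!is.null(env$nodes[[id]])) return(invisible(id))
    env$nodes[[id]] <- data.frame(id = id, kind = kind,
                                  position = as.integer(position),
                                  stringsAsFactors = FALSE)
    invisible(id)
  }
  add_edge <- function(from, to, kind, role = NA_character_,
                       translon = NA_character_, probability = NA_real_) {
    env$n_edge <- env$n_edge + 1L
    id <- sprintf("e%03d", env$n_edge)
    env$edges[[id]] <- data.frame(
      id = id, from = from, to = to, kind = kind, role = role,
      translon = translon, probability = probability,
      stringsAsFactors = FALSE)
    invisible(id)
  }
  list(
    add_node = add_node,
    add_edge = add_edge,
    has_node = function(id) !is.null(env$nodes[[id]]),
    nodes = function() {
      df <- do.call(rbind, unname(env$nodes))
      rownames(df) <- NULL
      df
    },
    edges = function() {
      df <- do.call(rbind, unname(env$edges))
      if (is.null(df))
        df <- data.frame(id = character(0), from = character(0),
                         to = character(0), kind = character(0),
                         role = character(0), translon = character(0),
                         probability = numeric(0), stringsAsFactors = FALSE)
      rownames(df) <- NULL
      df
    },
    memo_get = function(key) env$nodes_memo[[key]],
    memo_set = function(key, val) {
      if (is.null(env$nodes_memo)) env$nodes_memo <- list()
      env$nodes_memo[[key]] <- val
    }
  )
}

# Entry point of the elongation chain of initiation event `i`, materializing
# it on demand. `allow_reinit` is the post-termination context: FALSE when the
# translon was entered by reinitiation and chaining is disabled. The context
# is normalized so that chains without any reinitiation-eligible leaf are
# shared between contexts. Returns list(node = entry node id, translon = base
# translon id for the incoming TRANSLATE edge).
chain_entry <- function(ctx, i, allow_reinit) {
  ctx$used[[as.character(i)]] <- TRUE
  tree <- ctx$trees[[i]]
  reg <- ctx$registry
  eligible <- any(vapply(tree_leaf_keys(tree), function(k)
    reinit_eligible(reg[[k]], ctx$policy), logical(1)))
  if (!eligible) allow_reinit <- FALSE
  key <- sprintf("chain%d.%s", i, if (allow_reinit) "r" else "nr")
  memo <- ctx$builder$memo_get(key)
  base_id <- reg[[base_leaf_key(tree)]]$id
  if (!is.null(memo)) return(list(node = memo, translon = base_id))
  node <- materialize_tree(ctx, tree, allow_reinit,
                           suffix = if (allow_reinit || !eligible) ""
                                    else "*nr")
  ctx$builder$memo_set(key, node)
  list(node = node, translon = base_id)
}

reinit_eligible <- function(translon, policy) {
  !translon$open_ended && translon$length_nt <= policy$max_translon_nt
}

# Materialize one decision (sub)tree; returns the id of its entry node.
materialize_tree <- function(ctx, tree, allow_reinit, suffix) {
  b <- ctx$builder
  reg <- ctx$registry
  if (tree$type == "leaf") {
    tr <- reg[[tree$leaf_key]]
    pos <- if (tr$open_ended) max(tr$segments$end) else tr$terminal_stop
    nid <- paste0("term@", pos, ":", tr$id, suffix)
    if (b$has_node(nid)) return(nid)
    b$add_node(nid, "TERMINATION", pos)
    attach_termination(ctx, nid, tr, allow_reinit, suffix)
    return(nid)
  }
  base_id <- reg[[base_leaf_key(tree)]]$id
  kind <- if (tree$kind == "FRAMESHIFT") "BRANCH_FRAMESHIFT"
          else "BRANCH_READTHROUGH"
  short <- if (tree$kind == "FRAMESHIFT") "fs" else "rt"
  nid <- paste0(short, "@", tree$pos, ":", base_id, suffix)
  if (b$has_node(nid)) return(nid)
  b$add_node(nid, kind, tree$pos)
  p <- tree$event$probability
  cont <- materialize_tree(ctx, tree$continue, allow_reinit, suffix)
  b$add_edge(nid, cont, "TRANSLATE", role = "continue",
             translon = reg[[base_leaf_key(tree$continue)]]$id,
             probability = if (is.na(p)) NA_real_ else 1 - p)
  comm <- materialize_tree(ctx, tree$commit, allow_reinit, suffix)
  b$add_edge(nid, comm, "TRANSLATE", role = "commit",
             translon = reg[[base_leaf_key(tree$commit)]]$id,
             probability = p)
  nid
}

# Post-termination wiring: reinitiation branch (policy permitting) or exit.
attach_termination <- function(ctx, term_node, translon, allow_reinit,
                               suffix) {
  b <- ctx$builder
  policy <- ctx$policy
  if (!allow_reinit || !reinit_eligible(translon, policy)) {
    b$add_edge(term_node, "exit", "SCAN")
    return(invisible(NULL))
  }
  stop_pos <- translon$terminal_stop
  cand_idx <- which(vapply(ctx$init_events, function(e) {
    e$position >= stop_pos + 3L &&
      (!policy$aug_only || e$detail$codon == "AUG")
  }, logical(1)))

  chained_ok <- isTRUE(policy$allow_chained)

  if (policy$recharge_model %in% c("NONE", "STEP")) {
    if (policy$recharge_model == "STEP")
      cand_idx <- cand_idx[vapply(cand_idx, function(j)
        ctx$init_events[[j]]$position - stop_pos >=
          policy$recharge_distance_nt, logical(1))]
    if (!length(cand_idx)) {
      b$add_edge(term_node, "exit", "SCAN")
      return(invisible(NULL))
    }
    target <- cand_idx[1]
    rid <- paste0("reinit@", stop_pos, ":", translon$id)
    b$add_node(rid, "BRANCH_REINIT", stop_pos)
    b$add_edge(term_node, rid, "SCAN")
    entry <- chain_entry(ctx, target, allow_reinit = chained_ok)
    b$add_edge(rid, entry$node, "TRANSLATE", role = "commit",
               translon = entry$translon)
    b$add_edge(rid, "exit", "SCAN", role = "continue")
  } else {  # EXPONENTIAL: competence branch at every downstream start
    if (!length(cand_idx)) {
      b$add_edge(term_node, "exit", "SCAN")
      return(invisible(NULL))
    }
    rid <- paste0("reinit@", stop_pos, ":", translon$id)
    b$add_node(rid, "BRANCH_REINIT", stop_pos)
    b$add_edge(term_node, rid, "SCAN")
    prev <- rid
    prev_role <- "commit"
    prev_p <- NA_real_
    for (j in cand_idx) {
      ev <- ctx$init_events[[j]]
      comp <- 1 - exp(-(ev$position - stop_pos) / policy$lambda_nt)
      cid <- paste0("rinit@", ev$position, ":", translon$id)
      b$add_node(cid, "BRANCH_INIT", ev$position)
      b$add_edge(prev, cid, "SCAN", role = prev_role, probability = prev_p)
      entry <- chain_entry(ctx, j, allow_reinit = chained_ok)
      b$add_edge(cid, entry$node, "TRANSLATE", role = "commit",
                 translon = entry$translon, probability = comp)
      prev <- cid
      prev_role <- "continue"
      prev_p <- 1 - comp
    }
    b$add_edge(prev, "exit", "SCAN", role = "continue",
               probability = prev_p)
    b$add_edge(rid, "exit", "SCAN", role = "continue")
  }
  invisible(NULL)
}

# ---------------------------------------------------------------------------
# accessors and validation

#' Translons of an RDG
#'
#' @param rdg an [build_rdg()] object.
#' @return Named list of translons in 5' order of their first segment; each
#'   has `id`, `segments` (data.frame start/end/frame), `start_codon`,
#'   `terminal_stop`, `includes_stops`, `open_ended` and `length_nt`.
#' @export
translons <- function(rdg) {
  stopifnot(inherits(rdg, "rdg"))
  tl <- rdg$translons
  if (!length(tl)) return(tl)
  starts <- vapply(tl, `[[`, numeric(1), "start")
  ends <- vapply(tl, function(t) max(t$segments$end), numeric(1))
  tl[order(starts, ends)]
}

#' Translon summary table
#'
#' @param rdg an rdg object.
#' @return data.frame with one row per translon.
#' @export
translon_table <- function(rdg) {
  tl <- translons(rdg)
  if (!length(tl))
    return(data.frame(id = character(0), start = integer(0),
                      end = integer(0), n_segments = integer(0),
                      length_nt = integer(0), start_codon = character(0),
                      terminal_stop = integer(0), open_ended = logical(0)))
  do.call(rbind, lapply(tl, function(t) data.frame(
    id = t$id, start = t$start, end = max(t$segments$end),
    n_segments = nrow(t$segments), length_nt = t$length_nt,
    start_codon = t$start_codon, terminal_stop = t$terminal_stop,
    open_ended = t$open_ended, row.names = NULL)))
}

#' Branch nodes of an RDG
#'
#' @param rdg an rdg object.
#' @param deterministic include branches with a single (probability-1)
#'   outgoing edge.
#' @return data.frame of branch nodes (id, kind, position).
#' @export
branch_nodes <- function(rdg, deterministic = TRUE) {
  nd <- rdg$nodes[grepl("^BRANCH_", rdg$nodes$kind), , drop = FALSE]
  if (!deterministic) {
    deg <- table(factor(rdg$edges$from, levels = nd$id))
    nd <- nd[deg[nd$id] == 2L, , drop = FALSE]
  }
  rownames(nd) <- NULL
  nd
}

out_edges <- function(rdg, node) {
  rdg$edges[rdg$edges$from == node, , drop = FALSE]
}

#' Validate RDG structural invariants
#'
#' Diagnostics, not exceptions: returns a character vector of violations,
#' empty when the graph is well formed. Checked invariants: single ENTRY root
#' with no incoming edges; acyclicity; every node reachable from the root;
#' every maximal path ends at the single EXIT node; branch nodes have exactly
#' two outgoing edges (one, flagged deterministic, is allowed when it is a
#' probability-1 commit); TRANSLATE edges carry a known translon id; edge
#' endpoints exist.
#'
#' @param rdg an rdg object (or a hand-modified copy).
#' @return character vector of violations, each `"CODE: detail"`.
#' @export
validate_rdg <- function(rdg) {
  v <- character(0)
  nodes <- rdg$nodes
  edges <- rdg$edges
  bad_from <- setdiff(edges$from, nodes$id)
  bad_to <- setdiff(edges$to, nodes$id)
  if (length(c(bad_from, bad_to)))
    v <- c(v, sprintf("EDGE_ENDPOINT: unknown node(s) %s",
                      paste(unique(c(bad_from, bad_to)), collapse = ", ")))
  roots <- setdiff(nodes$id, edges$to)
  if (length(roots) != 1L || nodes$kind[match(roots, nodes$id)][1] != "ENTRY")
    v <- c(v, sprintf("ROOT: expected a single ENTRY root, found [%s]",
                      paste(roots, collapse = ", ")))
  exits <- nodes$id[nodes$kind == "EXIT"]
  if (length(exits) != 1L)
    v <- c(v, sprintf("EXIT: expected one EXIT node, found %d",
                      length(exits)))
  # acyclicity (Kahn) over valid endpoints only
  ed <- edges[edges$from %in% nodes$id & edges$to %in% nodes$id, ]
  indeg <- table(factor(ed$to, levels = nodes$id))
  queue <- nodes$id[indeg == 0]
  seen <- character(0)
  indeg <- as.list(indeg)
  while (length(queue)) {
    n <- queue[1]; queue <- queue[-1]
    seen <- c(seen, n)
    for (m in ed$to[ed$from == n]) {
      indeg[[m]] <- indeg[[m]] - 1L
      if (indeg[[m]] == 0L) queue <- c(queue, m)
    }
  }
  if (length(seen) < nrow(nodes))
    v <- c(v, sprintf("ACYCLICITY: cycle involving node(s) %s",
                      paste(setdiff(nodes$id, seen), collapse = ", ")))
  # reachability from root
  if (length(roots) == 1L) {
    reach <- roots
    frontier <- roots
    while (length(frontier)) {
      nxt <- setdiff(ed$to[ed$from %in% frontier], reach)
      reach <- c(reach, nxt)
      frontier <- nxt
    }
    if (length(reach) < nrow(nodes))
      v <- c(v, sprintf("REACHABILITY: unreachable node(s) %s",
                        paste(setdiff(nodes$id, reach), collapse = ", ")))
  }
  # terminal nodes and arity
  outdeg <- table(factor(edges$from, levels = nodes$id))
  for (i in seq_len(nrow(nodes))) {
    id <- nodes$id[i]; kind <- nodes$kind[i]; d <- outdeg[[id]]
    if (kind == "EXIT") {
      if (d != 0) v <- c(v, sprintf("EXIT_OUT: %s has %d outgoing edges",
                                    id, d))
    } else if (d == 0) {
      v <- c(v, sprintf("DEAD_END: non-EXIT node %s has no outgoing edge",
                        id))
    }
    if (grepl("^BRANCH_", kind)) {
      if (d == 1L) {
        e <- edges[edges$from == id, ]
        det_ok <- identical(e$role, "commit") &&
          (!is.na(e$probability) && e$probability == 1)
        if (!det_ok)
          v <- c(v, sprintf(
            "BRANCH_ARITY: %s has 1 outgoing edge and is not a probability-1 commit",
            id))
      } else if (d != 2L) {
        v <- c(v, sprintf("BRANCH_ARITY: %s has %d outgoing edges", id, d))
      }
    }
    if (kind %in% c("ENTRY", "TERMINATION") && d > 1L)
      v <- c(v, sprintf("LINEAR_ARITY: %s has %d outgoing edges", id, d))
  }
  # translate edges carry known translons
  te <- edges[edges$kind == "TRANSLATE", , drop = FALSE]
  bad <- te$id[is.na(te$translon) | !te$translon %in% names(rdg$translons)]
  if (length(bad))
    v <- c(v, sprintf("TRANSLON_EDGE: edge(s) %s lack a known translon id",
                      paste(bad, collapse = ", ")))
  v
}

#' @export
print.rdg <- function(x, ...) {
  cat(sprintf(
    "ribosome decision graph: %s (%d nt)\n  %d nodes (%d branches), %d edges, %d translons\n",
    x$transcript$id, x$transcript$length, nrow(x$nodes),
    nrow(branch_nodes(x)), nrow(x$edges), length(x$translons)))
  invisible(x)
}

#' @export
summary.rdg <- function(object, ...) {
  np <- count_paths(object)
  cat(sprintf("ribosome decision graph for %s\n", object$transcript$id))
  print(object$policy)
  cat(sprintf("nodes: %d  edges: %d  ribosome paths: %d (%d productive)\n",
              nrow(object$nodes), nrow(object$edges), np,
              count_paths(object, include_unproductive = FALSE)))
  tt <- translon_table(object)
  if (nrow(tt)) {
    cat("translons:\n")
    print(tt, row.names = FALSE)
  }
  invisible(object)
}
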