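#' Test whether a node is strictly linear
#'
#' A non-terminal node is strictly linear when it has exactly one distinct
#' predecessor, exactly one distinct successor, and total in-flow and out-flow
#' both equal to 1. Such nodes carry no branching information and can be
#' collapsed into a single merged edge. A node on a self-loop is never
#' collapsible (the merge presumes three distinct path nodes).
#'
#' @param graph A `vmus_graph`.
#' @param node An anchor node id; passing a terminal node is an error.
#' @return Logical.
#' @export
is_strictly_linear <- function(graph, node) {
  if (node %in% c(.NODE_START, .NODE_END)) stop("terminal nodes cannot be strictly linear")
  .check_node(graph, node)
  e <- graph$edges
  preds <- unique(e$from[e$to == node])
  succs <- unique(e$to[e$from == node])
  length(preds) == 1L && length(succs) == 1L &&
    sum(e$to == node) == 1L && sum(e$from == node) == 1L &&
    preds != node && succs != node
}

.empty_records <- function() {
  data.frame(iid = integer(0), node = character(0), from = character(0),
             to = character(0), delta = integer(0), tau = character(0),
             read_id = character(0),
             left_iid = integer(0), left_delta = integer(0), left_tau = character(0),
             right_iid = integer(0), right_delta = integer(0), right_tau = character(0),
             stringsAsFactors = FALSE)
}

#' Collapse one strictly linear node
#'
#' Removes `v` together with its unique incoming edge `(u, v)` and outgoing
#' edge `(v, w)` and adds a merged edge `(u, w)` with weight
#' `delta1 + delta2` and tag `tau1 + v + tau2` (string concatenation). If an
#' edge `(u, w)` already exists the merged instance is appended to it. The
#' returned collapse record retains both source instances so that merged tags
#' can be expanded back to original edge labels during contig spelling.
#'
#' @param graph A `vmus_graph`.
#' @param node A strictly linear node.
#' @return A list with elements `graph` and `record` (a one-row data frame).
#' @export
collapse_once <- function(graph, node) {
  if (!is_strictly_linear(graph, node)) {
    stop(sprintf("node '%s' is not strictly linear", node))
  }
  e <- graph$edges
  e1 <- e[e$to == node, , drop = FALSE]
  e2 <- e[e$from == node, , drop = FALSE]
  merged_read <- if (identical(e1$read_id, e2$read_id)) e1$read_id else
    paste(e1$read_id, e2$read_id, sep = "+")
  merged <- data.frame(
    from = e1$from, to = e2$to,
    delta = e1$delta + e2$delta,
    tau = paste0(e1$tau, node, e2$tau),
    read_id = merged_read, iid = NA_integer_, stringsAsFactors = FALSE)
  record <- data.frame(
    iid = NA_integer_, node = node, from = e1$from, to = e2$to,
    delta = merged$delta, tau = merged$tau, read_id = merged_read,
    left_iid = e1$iid, left_delta = e1$delta, left_tau = e1$tau,
    right_iid = e2$iid, right_delta = e2$delta, right_tau = e2$tau,
    stringsAsFactors = FALSE)
  graph$edges <- e[e$to != node & e$from != node, , drop = FALSE]
  graph <- .append_instances(graph, merged)
  record$iid <- graph$edges$iid[nrow(graph$edges)]
  graph$nodes <- setdiff(graph$nodes, node)
  graph$anchors <- setdiff(graph$anchors, node)
  graph$props[[node]] <- NULL
  rownames(graph$edges) <- NULL
  list(graph = graph, record = record)
}

.linear_candidates <- function(graph) {
  e <- graph$edges
  cand <- setdiff(graph$nodes, c(.NODE_START, .NODE_END))
  if (!length(cand) || nrow(e) == 0L) return(character(0))
  tin <- table(e$to)
  tout <- table(e$from)
  pairs <- unique(e[c("from", "to")])
  uin <- table(pairs$to)
  uout <- table(pairs$from)
  get <- function(tab, n) { v <- tab[n]; ifelse(is.na(v), 0L, as.integer(v)) }
  ok <- get(tin, cand) == 1L & get(tout, cand) == 1L &
    get(uin, cand) == 1L & get(uout, cand) == 1L
  cand <- cand[ok]
  noself <- vapply(cand, function(n) {
    e$from[e$to == n] != n && e$to[e$from == n] != n
  }, logical(1))
  sort(cand[noself], method = "radix")
}

#' Collapse all strictly linear nodes
#'
#' Applies [collapse_once()] iteratively until no strictly linear node
#' remains. Candidates are processed in lexicographic order for byte-stable
#' output; the final graph does not depend on the order (collapsing is
#' confluent up to instance-list order).
#'
#' @param graph A `vmus_graph`.
#' @return A list with the simplified `graph` and `records`, a data frame of
#'   collapse records (one row per removed node) usable by [spell_path()] and
#'   [assemble_contigs()] to expand merged tags.
#' @examples
#' a <- extract_mus(toy_genome(), uniqueness_config("genome", circular = TRUE))
#' g <- build_graph(toy_reads(), a)
#' simplify_graph(g)$records  # toy flows >= 2 block collapsing almost everywhere
#' @export
simplify_graph <- function(graph) {
  records <- .empty_records()
  repeat {
    cand <- .linear_candidates(graph)
    if (!length(cand)) break
    res <- collapse_once(graph, cand[1L])
    graph <- res$graph
    records <- rbind(records, res$record)
  }
  rownames(records) <- NULL
  list(graph = graph, records = records)
}
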