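#' @title The MUS assembly multigraph
#'
#' @description A directed multigraph whose nodes are the anchor words plus two
#' terminal nodes (see [node_start()], [node_end()]). Every read-supported
#' transition between consecutive anchor occurrences contributes one *edge
#' instance* `(delta, tau)`: `delta` is the start-position offset between the
#' two occurrences and `tau` the intervening sequence (the empty string when
#' the anchors overlap or abut). The flow `f(u, v)` of an edge is the number of
#' its instances. Each node additionally carries the longest prefix/suffix
#' observed around it at read boundaries.
#'
#' @details Internally the graph is a flat instance table with columns `from`,
#' `to`, `delta`, `tau`, `read_id` and a stable instance id `iid`; instance
#' order is read input order then occurrence position.
#'
#' @name vmus_graph
NULL

.empty_props <- function() {
  list(max_prefix = list(seq = "", len = 0L), max_suffix = list(seq = "", len = 0L))
}

.empty_edges <- function() {
  data.frame(from = character(0), to = character(0), delta = integer(0),
             tau = character(0), read_id = character(0), iid = integer(0),
             stringsAsFactors = FALSE)
}

.new_graph <- function(anchor_words) {
  anchor_words <- sort(unique(as.character(anchor_words)), method = "radix")
  nodes <- c(anchor_words, .NODE_START, .NODE_END)
  props <- stats::setNames(lapply(nodes, function(x) .empty_props()), nodes)
  structure(
    list(nodes = nodes, edges = .empty_edges(), props = props,
         anchors = anchor_words, skipped_reads = 0L, next_iid = 1L),
    class = "vmus_graph"
  )
}

#' @export
print.vmus_graph <- function(x, ...) {
  np <- nrow(unique(x$edges[c("from", "to")]))
  cat(sprintf("vmus_graph: %d node(s) (%d anchors + 2 terminals), %d distinct edge(s), %d instance(s)\n",
              length(x$nodes), length(x$anchors), np, nrow(x$edges)))
  if (x$skipped_reads > 0L) cat(sprintf("  %d read(s) contributed no occurrences\n", x$skipped_reads))
  invisible(x)
}

.check_node <- function(graph, node) {
  if (!node %in% graph$nodes) stop(sprintf("unknown node '%s'", node))
}

.append_instances <- function(graph, rows) {
  if (nrow(rows) == 0L) return(graph)
  rows$iid <- graph$next_iid + seq_len(nrow(rows)) - 1L
  graph$next_iid <- graph$next_iid + nrow(rows)
  graph$edges <- rbind(graph$edges, rows)
  rownames(graph$edges) <- NULL
  graph
}

.update_max <- function(graph, node, which, s) {
  if (nchar(s) > graph$props[[node]][[which]]$len) {
    graph$props[[node]][[which]] <- list(seq = s, len = nchar(s))
  }
  graph
}

# Instance rows contributed by one read: prefix rule, internal rule per
# consecutive occurrence pair, suffix rule.
.read_instances <- function(seqc, read_id, occ) {
  p <- nrow(occ)
  len <- nchar(seqc)
  rows <- list()
  if (occ$start[1L] > 1L) {
    s1 <- occ$start[1L]
    rows[[length(rows) + 1L]] <- data.frame(
      from = .NODE_START, to = occ$word[1L], delta = s1 - 1L,
      tau = substr(seqc, 1L, s1 - 1L), read_id = read_id, iid = NA_integer_,
      stringsAsFactors = FALSE)
  }
  if (p >= 2L) {
    u <- occ$word[-p]
    delta <- occ$start[-1L] - occ$start[-p]
    gap <- delta > nchar(u)
    tau <- ifelse(gap, substring(seqc, occ$end[-p] + 1L, occ$start[-1L] - 1L), "")
    rows[[length(rows) + 1L]] <- data.frame(
      from = u, to = occ$word[-1L], delta = as.integer(delta), tau = tau,
      read_id = read_id, iid = NA_integer_, stringsAsFactors = FALSE)
  }
  ep <- occ$end[p]
  if (ep < len) {
    rows[[length(rows) + 1L]] <- data.frame(
      from = occ$word[p], to = .NODE_END, delta = len - ep,
      tau = substr(seqc, ep + 1L, len), read_id = read_id, iid = NA_integer_,
      stringsAsFactors = FALSE)
  }
  if (length(rows)) do.call(rbind, rows) else .empty_edges()
}

#' Build the MUS assembly graph from reads and an anchor set
#'
#' For each read, anchor occurrences are located and sorted by start position;
#' the prefix, internal and suffix edge rules are then applied in order. A read
#' whose first anchor starts after position 1 contributes a source edge tagged
#' with the uncovered read prefix; each consecutive occurrence pair contributes
#' an internal edge weighted by the start offset; a read whose last anchor ends
#' before the read end contributes a sink edge tagged with the uncovered read
#' suffix. Reads with no anchor occurrences contribute nothing (they are
#' counted in `skipped_reads`).
#'
#' @param reads A [read_set()].
#' @param anchors An [anchor_set()].
#' @return A `vmus_graph`.
#' @examples
#' a <- extract_mus(toy_genome(), uniqueness_config("genome", circular = TRUE))
#' g <- build_graph(toy_reads(), a)
#' edge_flow(g, "AT", "TG")  # 2
#' @export
build_graph <- function(reads, anchors) {
  if (!inherits(reads, "read_set") || nrow(reads) == 0L) stop("read set is empty")
  stopifnot(inherits(anchors, "anchor_set"))
  g <- .new_graph(anchors$words)
  chunks <- list()
  for (k in seq_len(nrow(reads))) {
    seqc <- reads$seq[k]
    occ <- locate_occurrences(seqc, k, anchors)
    if (nrow(occ) == 0L) {
      g$skipped_reads <- g$skipped_reads + 1L
      next
    }
    rows <- .read_instances(seqc, reads$id[k], occ)
    chunks[[length(chunks) + 1L]] <- rows
    s1 <- occ$start[1L]
    ep <- occ$end[nrow(occ)]
    if (s1 > 1L) {
      pre <- substr(seqc, 1L, s1 - 1L)
      g <- .update_max(g, occ$word[1L], "max_prefix", pre)
      g <- .update_max(g, .NODE_START, "max_prefix", pre)
    }
    if (ep < nchar(seqc)) {
      suf <- substr(seqc, ep + 1L, nchar(seqc))
      g <- .update_max(g, occ$word[nrow(occ)], "max_suffix", suf)
      g <- .update_max(g, .NODE_END, "max_suffix", suf)
    }
  }
  if (length(chunks)) g <- .append_instances(g, do.call(rbind, chunks))
  g
}

#' Single edge-rule applications
#'
#' `add_prefix_edge()`, `add_internal_edge()` and `add_suffix_edge()` apply one
#' construction rule to an existing graph; [build_graph()] is the bulk driver.
#' Each errors when called outside its precondition (e.g. a prefix edge for a
#' read whose first anchor starts the read).
#'
#' @param graph A `vmus_graph`.
#' @param read A list or one-row data frame with fields `id` and `seq`.
#' @param first_occ,last_occ,occ_i,occ_next One-row occurrence data frames as
#'   produced by [locate_occurrences()].
#' @return The updated graph.
#' @export
add_prefix_edge <- function(graph, read, first_occ) {
  s1 <- first_occ$start[1L]
  if (s1 <= 1L) stop("prefix edge requires the first occurrence to start after position 1")
  .check_node(graph, first_occ$word[1L])
  seqc <- as.character(read$seq)[1L]
  tau <- substr(seqc, 1L, s1 - 1L)
  rows <- data.frame(from = .NODE_START, to = first_occ$word[1L], delta = s1 - 1L,
                     tau = tau, read_id = as.character(read$id)[1L],
                     iid = NA_integer_, stringsAsFactors = FALSE)
  graph <- .append_instances(graph, rows)
  graph <- .update_max(graph, first_occ$word[1L], "max_prefix", tau)
  .update_max(graph, .NODE_START, "max_prefix", tau)
}

#' @rdname add_prefix_edge
#' @export
add_internal_edge <- function(graph, read, occ_i, occ_next) {
  if (occ_next$start[1L] <= occ_i$start[1L]) {
    stop("internal edge requires occurrences in increasing start order")
  }
  .check_node(graph, occ_i$word[1L])
  .check_node(graph, occ_next$word[1L])
  seqc <- as.character(read$seq)[1L]
  delta <- occ_next$start[1L] - occ_i$start[1L]
  tau <- if (delta > nchar(occ_i$word[1L])) {
    substr(seqc, occ_i$end[1L] + 1L, occ_next$start[1L] - 1L)
  } else ""
  rows <- data.frame(from = occ_i$word[1L], to = occ_next$word[1L],
                     delta = as.integer(delta), tau = tau,
                     read_id = as.character(read$id)[1L],
                     iid = NA_integer_, stringsAsFactors = FALSE)
  .append_instances(graph, rows)
}

#' @rdname add_prefix_edge
#' @export
add_suffix_edge <- function(graph, read, last_occ) {
  seqc <- as.character(read$seq)[1L]
  ep <- last_occ$end[1L]
  if (ep >= nchar(seqc)) stop("suffix edge requires the last occurrence to end before the read end")
  .check_node(graph, last_occ$word[1L])
  tau <- substr(seqc, ep + 1L, nchar(seqc))
  rows <- data.frame(from = last_occ$word[1L], to = .NODE_END,
                     delta = nchar(seqc) - ep, tau = tau,
                     read_id = as.character(read$id)[1L],
                     iid = NA_integer_, stringsAsFactors = FALSE)
  graph <- .append_instances(graph, rows)
  graph <- .update_max(graph, last_occ$word[1L], "max_suffix", tau)
  .update_max(graph, .NODE_END, "max_suffix", tau)
}

#' Edge flow and instance access
#'
#' `edge_flow()` returns the multiplicity `f(u, v)` (0 when the edge is
#' absent); `edge_instances()` returns the instance table for one edge;
#' `graph_edges()` lists all distinct edges with their flows.
#'
#' @param graph A `vmus_graph`.
#' @param from,to Node identifiers.
#' @return An integer, a data frame of instances, or a data frame of edges.
#' @export
edge_flow <- function(graph, from, to) {
  sum(graph$edges$from == from & graph$edges$to == to)
}

#' @rdname edge_flow
#' @export
edge_instances <- function(graph, from, to) {
  graph$edges[graph$edges$from == from & graph$edges$to == to, , drop = FALSE]
}

#' @rdname edge_flow
#' @export
graph_edges <- function(graph) {
  if (nrow(graph$edges) == 0L) {
    return(data.frame(from = character(0), to = character(0), flow = integer(0),
                      stringsAsFactors = FALSE))
  }
  key <- paste(graph$edges$from, graph$edges$to, sep = "\r")
  tab <- table(key)
  parts <- strsplit(names(tab), "\r", fixed = TRUE)
  out <- data.frame(from = vapply(parts, `[`, "", 1L),
                    to = vapply(parts, `[`, "", 2L),
                    flow = as.integer(tab), stringsAsFactors = FALSE)
  out[order(out$from, out$to, method = "radix"), , drop = FALSE]
}

#' Export a graph as GFA 1.0
#'
#' One `S` line per anchor node (segment sequence = anchor word), zero-length
#' `S` lines flagged `TN:i:1` for the two terminal nodes, and one `L` line per
#' distinct edge carrying the flow (`FC:i`) and the best instance's weight
#' (`DW:i`) and tag (`DT:Z`, `.` for the empty tag). A graph with no anchors
#' and no edges yields the header line only.
#'
#' @param graph A `vmus_graph`.
#' @param path Optional file to write to.
#' @return Invisibly, the GFA lines.
#' @export
export_gfa <- function(graph, path = NULL) {
  lines <- "H\tVN:Z:1.0"
  if (length(graph$anchors) > 0L || nrow(graph$edges) > 0L) {
    for (w in graph$anchors) {
      lines <- c(lines, sprintf("S\t%s\t%s\tLN:i:%d", w, w, nchar(w)))
    }
    lines <- c(lines,
               sprintf("S\t%s\t*\tLN:i:0\tTN:i:1", .NODE_START),
               sprintf("S\t%s\t*\tLN:i:0\tTN:i:1", .NODE_END))
    el <- graph_edges(graph)
    for (i in seq_len(nrow(el))) {
      best <- best_instance(graph, el$from[i], el$to[i])
      lines <- c(lines, sprintf("L\t%s\t+\t%s\t+\t*\tFC:i:%d\tDW:i:%d\tDT:Z:%s",
                                el$from[i], el$to[i], el$flow[i], best$delta,
                                if (nzchar(best$tau)) best$tau else "."))
    }
  }
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

#' Parse a GFA file written by [export_gfa()]
#'
#' Reconstructs the node set and edge flows (instances are not representable
#' in GFA and are not recovered).
#'
#' @param path File, or a character vector of GFA lines.
#' @return A list with `nodes` and an edge data frame with `from`, `to`, `flow`.
#' @export
read_gfa <- function(path) {
  lines <- if (length(path) == 1L && file.exists(path)) readLines(path) else path
  nodes <- character(0)
  ef <- list()
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (f[1] == "S") nodes <- c(nodes, f[2])
    if (f[1] == "L") {
      fc <- sub("^FC:i:", "", grep("^FC:i:", f, value = TRUE))
      ef[[length(ef) + 1L]] <- data.frame(from = f[2], to = f[4],
                                          flow = as.integer(fc),
                                          stringsAsFactors = FALSE)
    }
  }
  edges <- if (length(ef)) do.call(rbind, ef) else
    data.frame(from = character(0), to = character(0), flow = integer(0))
  list(nodes = nodes, edges = edges[order(edges$from, edges$to, method = "radix"), , drop = FALSE])
}

#' Lossless JSON dump of a graph
#'
#' @param graph A `vmus_graph`.
#' @param path File to write (for `graph_to_json`) or read (`graph_from_json`).
#' @return `graph_from_json()` returns the reconstructed `vmus_graph`.
#' @export
graph_to_json <- function(graph, path) {
  obj <- list(
    anchors = graph$anchors,
    nodes = graph$nodes,
    edges = as.list(graph$edges),
    props = graph$props,
    skipped_reads = graph$skipped_reads,
    next_iid = graph$next_iid
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname graph_to_json
#' @export
graph_from_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  g <- .new_graph(obj$anchors)
  e <- obj$edges
  g$edges <- data.frame(from = as.character(e$from), to = as.character(e$to),
                        delta = as.integer(e$delta), tau = as.character(e$tau),
                        read_id = as.character(e$read_id), iid = as.integer(e$iid),
                        stringsAsFactors = FALSE)
  if (length(e$from) == 0L) g$edges <- .empty_edges()
  g$nodes <- as.character(obj$nodes)
  for (n in names(obj$props)) {
    p <- obj$props[[n]]
    g$props[[n]] <- list(
      max_prefix = list(seq = as.character(p$max_prefix$seq), len = as.integer(p$max_prefix$len)),
      max_suffix = list(seq = as.character(p$max_suffix$seq), len = as.integer(p$max_suffix$len)))
  }
  g$skipped_reads <- as.integer(obj$skipped_reads)
  g$next_iid <- as.integer(obj$next_iid)
  g
}
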