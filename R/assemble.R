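#' Degree summary of a node
#'
#' Distinguishes *unique* degrees (number of distinct predecessor/successor
#' nodes) from *total* degrees (summed flow, i.e. number of edge instances,
#' counting parallel instances separately). Unique degrees determine
#' branching; total degrees measure read support.
#'
#' @param graph A `vmus_graph`.
#' @param node A node id (terminals allowed).
#' @return A list with `unique_in`, `unique_out`, `total_in`, `total_out`.
#' @examples
#' a <- extract_mus(toy_genome(), uniqueness_config("genome", circular = TRUE))
#' g <- build_graph(toy_reads(), a)
#' degree_summary(g, "AT")  # one distinct successor (TG), total out-flow 2
#' @export
degree_summary <- function(graph, node) {
  .check_node(graph, node)
  e <- graph$edges
  list(unique_in = length(unique(e$from[e$to == node])),
       unique_out = length(unique(e$to[e$from == node])),
       total_in = sum(e$to == node),
       total_out = sum(e$from == node))
}

#' Is a node a junction?
#'
#' A node is a junction when it is one of the two terminal nodes, or when its
#' unique in-degree or unique out-degree differs from 1. Junctions delimit the
#' maximal non-branching paths that become unitigs.
#'
#' @inheritParams degree_summary
#' @return Logical.
#' @export
is_junction <- function(graph, node) {
  .check_node(graph, node)
  if (node %in% c(.NODE_START, .NODE_END)) return(TRUE)
  d <- degree_summary(graph, node)
  d$unique_in != 1L || d$unique_out != 1L
}

# Order instance rows best-first. Terminal edges (from the source or into the
# sink) prefer the longest tag (they carry otherwise-unrepresented sequence),
# tie-broken by smallest weight; internal edges prefer the smallest weight,
# tie-broken by longest tag. Remaining ties break lexicographically by tag
# then read id, for determinism.
.rank_instances <- function(rows, terminal) {
  if (terminal) {
    order(-nchar(rows$tau), rows$delta, rows$tau, rows$read_id, method = "radix")
  } else {
    order(rows$delta, -nchar(rows$tau), rows$tau, rows$read_id, method = "radix")
  }
}

#' Select the best instance of an edge
#'
#' @param graph A `vmus_graph`.
#' @param from,to Node ids of an existing edge.
#' @return A one-row data frame (the chosen instance).
#' @export
best_instance <- function(graph, from, to) {
  rows <- edge_instances(graph, from, to)
  if (nrow(rows) == 0L) stop(sprintf("no edge (%s, %s) in graph", from, to))
  terminal <- from == .NODE_START || to == .NODE_END
  rows[.rank_instances(rows, terminal)[1L], , drop = FALSE]
}

#' Extract maximal non-branching paths (unitigs)
#'
#' Decomposes the (simplified) graph into maximal non-branching paths: every
#' path starts and ends at a junction and all interior nodes have exactly one
#' distinct predecessor and successor. Every hop consumes one edge instance,
#' selected best-first among the instances not yet used; across all extracted
#' paths each instance is used at most once, and instances left over are
#' reported rather than forced into additional paths. Cycles made entirely of
#' non-branching nodes are unreachable from any junction and are emitted as
#' circular unitigs starting at their lexicographically smallest node.
#'
#' @param graph A `vmus_graph`, normally after [simplify_graph()].
#' @return A list of `unitig_path` objects (fields `nodes`, `iids`,
#'   `circular`), with attribute `unused_iids` listing unconsumed instances.
#' @export
extract_mnbps <- function(graph) {
  e <- graph$edges
  paths <- list()
  if (nrow(e) == 0L) {
    attr(paths, "unused_iids") <- integer(0)
    return(paths)
  }
  used <- rep.int(FALSE, nrow(e))
  junction <- stats::setNames(vapply(graph$nodes, function(n) is_junction(graph, n), logical(1)),
                              graph$nodes)
  pick <- function(u, v) {
    idx <- which(e$from == u & e$to == v & !used)
    if (!length(idx)) return(NA_integer_)
    rows <- e[idx, , drop = FALSE]
    idx[.rank_instances(rows, u == .NODE_START || v == .NODE_END)[1L]]
  }
  succ_of <- function(u) sort(unique(e$to[e$from == u]), method = "radix")
  for (u in sort(graph$nodes, method = "radix")) {
    if (!junction[[u]]) next
    for (v in succ_of(u)) {
      i0 <- pick(u, v)
      if (is.na(i0)) next
      nodes <- c(u, v)
      iids <- e$iid[i0]
      used[i0] <- TRUE
      repeat {
        last <- nodes[length(nodes)]
        if (junction[[last]]) break
        nxt <- succ_of(last)
        if (length(nxt) != 1L) break
        if (nxt %in% nodes[-1L]) break
        i <- pick(last, nxt)
        if (is.na(i)) break
        nodes <- c(nodes, nxt)
        iids <- c(iids, e$iid[i])
        used[i] <- TRUE
      }
      paths[[length(paths) + 1L]] <- structure(
        list(nodes = nodes, iids = iids, circular = FALSE), class = "unitig_path")
    }
  }
  visited <- unique(unlist(lapply(paths, `[[`, "nodes")))
  leftover <- setdiff(names(junction)[!junction], visited)
  leftover <- leftover[leftover %in% unique(c(e$from, e$to))]
  while (length(leftover)) {
    v0 <- sort(leftover, method = "radix")[1L]
    nodes <- v0
    iids <- integer(0)
    cur <- v0
    repeat {
      nxt <- succ_of(cur)[1L]
      i <- pick(cur, nxt)
      if (is.na(i)) break
      iids <- c(iids, e$iid[i])
      used[i] <- TRUE
      if (nxt == v0) break
      nodes <- c(nodes, nxt)
      cur <- nxt
    }
    paths[[length(paths) + 1L]] <- structure(
      list(nodes = nodes, iids = iids, circular = TRUE), class = "unitig_path")
    leftover <- setdiff(leftover, nodes)
  }
  attr(paths, "unused_iids") <- e$iid[!used]
  paths
}

# Expand one instance row into its base-level hops using collapse records:
# a merged instance becomes (u, v) then (v, w), recursively.
.expand_hops <- function(row, records) {
  if (!is.null(records) && nrow(records) > 0L && row$iid %in% records$iid) {
    r <- records[match(row$iid, records$iid), , drop = FALSE]
    left <- data.frame(from = r$from, to = r$node, delta = r$left_delta,
                       tau = r$left_tau, iid = r$left_iid, stringsAsFactors = FALSE)
    right <- data.frame(from = r$node, to = r$to, delta = r$right_delta,
                        tau = r$right_tau, iid = r$right_iid, stringsAsFactors = FALSE)
    rbind(.expand_hops(left, records), .expand_hops(right, records))
  } else {
    row[, c("from", "to", "delta", "tau", "iid")]
  }
}

# Core spelling of a hop table (columns from, to, delta, tau). The node
# sequence is c(hops$from[1], hops$to). Returns the spelled string.
.spell_hops <- function(hops) {
  m <- nrow(hops)
  nodes <- c(hops$from[1L], hops$to)
  if (nodes[1L] == .NODE_START) {
    if (nodes[2L] == .NODE_END) {
      if (m != 1L) stop("terminal-only path must be a single hop")
      return(hops$tau[1L])
    }
    s <- paste0(hops$tau[1L], nodes[2L])
    h0 <- 2L
  } else {
    s <- nodes[1L]
    h0 <- 1L
  }
  if (m < h0) return(s)
  for (h in h0:m) {
    u <- nodes[h]
    v <- nodes[h + 1L]
    delta <- hops$delta[h]
    tau <- hops$tau[h]
    if (v == .NODE_END) {
      if (h != m) stop("sink node may only terminate a path")
      s <- paste0(s, tau)
    } else {
      phi <- nchar(u) - delta
      if (phi > nchar(v)) {
        stop(sprintf("impossible overlap at hop %d (%s -> %s): phi=%d exceeds |%s|",
                     h, u, v, phi, v))
      }
      s <- if (phi > 0L) {
        paste0(s, substr(v, phi + 1L, nchar(v)))
      } else if (phi == 0L) {
        paste0(s, v)
      } else {
        paste0(s, tau, v)
      }
    }
  }
  s
}

#' Spell a unitig path into its contig sequence
#'
#' Reconstructs the sequence of a path: the base is the first node's word (or
#' the source tag concatenated with the first anchor when the path starts at
#' the source node); each subsequent hop appends the non-overlapping suffix of
#' the next anchor (overlap `phi = |u| - delta`), the whole next anchor when
#' the anchors abut, or the gap tag followed by the next anchor when
#' `phi < 0`. A trailing sink hop appends its tag verbatim. Merged instances
#' from collapsed nodes are first expanded back to original edge labels via
#' the collapse records; spelling a merged tag directly would double-count
#' anchor overlaps. An overlap larger than the next anchor indicates a
#' corrupted graph and is a hard error naming the hop.
#'
#' For circular unitigs the closing hop is spelled as well and the duplicated
#' leading anchor is trimmed from the end, yielding one rotation of the cycle.
#'
#' @param path A `unitig_path` from [extract_mnbps()].
#' @param graph The graph the path was extracted from.
#' @param records Optional collapse records from [simplify_graph()].
#' @return A list with `seq`, `length`, `circular` and the expanded `hops`.
#' @export
spell_path <- function(path, graph, records = NULL) {
  if (length(path$nodes) == 1L && length(path$iids) == 0L) {
    w <- path$nodes[1L]
    return(list(seq = w, length = nchar(w), circular = FALSE,
                hops = .empty_edges()[, c("from", "to", "delta", "tau", "iid")]))
  }
  rows <- graph$edges[match(path$iids, graph$edges$iid), , drop = FALSE]
  if (anyNA(rows$iid)) stop("path refers to instances not present in the graph")
  hops <- do.call(rbind, lapply(seq_len(nrow(rows)), function(i) {
    .expand_hops(rows[i, , drop = FALSE], records)
  }))
  rownames(hops) <- NULL
  s <- .spell_hops(hops)
  circular <- isTRUE(path$circular)
  if (circular) {
    w <- nchar(path$nodes[1L])
    if (nchar(s) > w && substr(s, nchar(s) - w + 1L, nchar(s)) == substr(s, 1L, w)) {
      s <- substr(s, 1L, nchar(s) - w)
    }
  }
  list(seq = s, length = nchar(s), circular = circular, hops = hops)
}

#' Spell a single read from its own occurrence path
#'
#' Builds the occurrence path of one read against an anchor set (source tag,
#' internal hops, sink tag) and spells it. For any read this reproduces the
#' read exactly; the identity is the basic soundness check of the edge rules
#' and the spelling recursion.
#'
#' @param read A read sequence (string).
#' @param anchors An [anchor_set()].
#' @return The spelled string.
#' @examples
#' a <- extract_mus(toy_genome(), uniqueness_config("genome", circular = TRUE))
#' spell_read("GCACAT", a) == "GCACAT"
#' @export
spell_read <- function(read, anchors) {
  seqc <- as.character(read)[1L]
  occ <- locate_occurrences(seqc, 1L, anchors)
  if (nrow(occ) == 0L) stop("read contains no anchor occurrence")
  hops <- .read_instances(seqc, "r", occ)
  if (nrow(hops) == 0L) return(occ$word[1L])  # read equals its single anchor
  .spell_hops(hops)
}

#' Assemble contigs from a simplified graph
#'
#' Extracts maximal non-branching paths and spells each into a contig, using
#' the collapse records to expand merged edge labels. Contigs are sorted by
#' decreasing length and named `contig_1`, `contig_2`, ...
#'
#' @param graph A simplified `vmus_graph`.
#' @param records Collapse records from [simplify_graph()] (may be `NULL` or
#'   empty when the graph was not simplified).
#' @return A `contig_set` data frame with columns `id`, `length`, `circular`,
#'   `seq`; attributes `paths` and `unused_instances`.
#' @examples
#' a <- extract_mus(toy_genome(), uniqueness_config("genome", circular = TRUE))
#' g <- build_graph(toy_reads(), a)
#' s <- simplify_graph(g)
#' assemble_contigs(s$graph, s$records)
#' @export
assemble_contigs <- function(graph, records = NULL) {
  paths <- extract_mnbps(graph)
  seqs <- character(0)
  circ <- logical(0)
  for (p in paths) {
    sp <- spell_path(p, graph, records)
    seqs <- c(seqs, sp$seq)
    circ <- c(circ, sp$circular)
  }
  ord <- order(-nchar(seqs), seqs, method = "radix")
  out <- data.frame(
    id = if (length(ord)) paste0("contig_", seq_along(ord)) else character(0),
    length = nchar(seqs)[ord],
    circular = circ[ord],
    seq = seqs[ord],
    stringsAsFactors = FALSE)
  structure(out, class = c("contig_set", "data.frame"),
            paths = paths[ord], unused_instances = attr(paths, "unused_iids"))
}

#' @export
print.contig_set <- function(x, ...) {
  st <- assembly_stats(x)
  cat(sprintf("contig_set: %d contig(s), total %d bp, largest %d bp, N50 %d bp\n",
              st$contigs, st$total_length, st$largest, st$n50))
  invisible(x)
}

#' Basic assembly statistics
#'
#' N50 is the contig length L such that contigs of length at least L together
#' cover at least half of the total assembly length.
#'
#' @param contigs A `contig_set`, or a numeric vector of contig lengths.
#' @param reference_length Optional known reference length, echoed in the
#'   output for context.
#' @return A list with `contigs`, `total_length`, `largest`, `n50` (and
#'   `reference_length` when supplied).
#' @examples
#' assembly_stats(c(10, 6, 4))$n50  # 10
#' @export
assembly_stats <- function(contigs, reference_length = NULL) {
  lens <- if (is.numeric(contigs)) as.integer(contigs) else as.integer(contigs$length)
  lens <- sort(lens, decreasing = TRUE)
  total <- sum(lens)
  n50 <- if (length(lens)) lens[which(cumsum(lens) >= total / 2)[1L]] else 0L
  out <- list(contigs = length(lens),
              total_length = as.integer(total),
              largest = if (length(lens)) lens[1L] else 0L,
              n50 = as.integer(n50))
  if (!is.null(reference_length)) out$reference_length <- as.integer(reference_length)
  out
}
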