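# Shared fixtures: the worked-example circular genome, its anchor set, and
# small constructors for hand-built graphs.

toy_cfg <- function(backend = "suffix_array") {
  uniqueness_config("genome", circular = TRUE, backend = backend)
}

toy_anchors <- function() extract_mus(toy_genome(), toy_cfg())

toy_graph <- function() build_graph(toy_reads(), toy_anchors())

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Build a graph directly from an edge table (columns from, to, delta, tau,
# and optionally read_id) over the given anchor words.
mk_graph <- function(anchor_words, edges) {
  if (is.null(edges$read_id)) edges$read_id <- paste0("r", seq_len(nrow(edges)))
  edges$iid <- NA_integer_
  g <- vmusdbg:::.new_graph(anchor_words)
  vmusdbg:::.append_instances(g, edges[c("from", "to", "delta", "tau", "read_id", "iid")])
}

# Order-independent signature of a graph: multisets of instances, sorted
# nodes, props, skip counter. Instance ids are excluded on purpose.
graph_sig <- function(g) {
  e <- g$edges[c("from", "to", "delta", "tau", "read_id")]
  e <- e[do.call(order, c(unname(as.list(e)), list(method = "radix"))), , drop = FALSE]
  rownames(e) <- NULL
  list(nodes = sort(g$nodes, method = "radix"), edges = e,
       props = g$props[sort(names(g$props), method = "radix")],
       skipped = g$skipped_reads)
}

# A source-to-sink chain whose hops are all gaps (no anchor overlap), so
# merged tags literally spell everything between the endpoints.
chain_graph <- function() {
  mk_graph(c("AAT", "CCG", "GTT"), data.frame(
    from = c(node_start(), "AAT", "CCG", "GTT"),
    to = c("AAT", "CCG", "GTT", node_end()),
    delta = c(2L, 5L, 5L, 2L),
    tau = c("GC", "AC", "TG", "AG"),
    read_id = "r1", stringsAsFactors = FALSE))
}

is_rotation_of <- function(contig, genome) {
  nchar(contig) == nchar(genome) && grepl(contig, paste0(genome, genome), fixed = TRUE)
}
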