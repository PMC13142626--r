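test_that("toy graph flows and instance lists match the worked example", {
  g <- toy_graph()
  expect_identical(edge_flow(g, "AT", "TG"), 2L)
  expect_identical(edge_flow(g, "CT", "TA"), 2L)
  expect_identical(edge_flow(g, "AC", "AT"), 2L)
  expect_identical(edge_flow(g, "TG", "CT"), 1L)
  expect_identical(edge_flow(g, "TA", "AG"), 2L)
  expect_identical(edge_flow(g, "AG", "GCA"), 1L)
  expect_identical(edge_flow(g, "GCA", "AC"), 2L)
  # I(AT,TG) = {(1, e), (1, e)}; I(TG,CT) = {(2, e)}
  at_tg <- edge_instances(g, "AT", "TG")
  expect_identical(at_tg$delta, c(1L, 1L))
  expect_identical(at_tg$tau, c("", ""))
  tg_ct <- edge_instances(g, "TG", "CT")
  expect_identical(tg_ct$delta, 2L)
  expect_identical(tg_ct$tau, "")
  # terminal edges: GCTAGC enters through the source, two reads exit early
  expect_identical(edge_flow(g, node_start(), "CT"), 1L)
  expect_identical(edge_instances(g, node_start(), "CT")$tau, "G")
  expect_identical(edge_flow(g, "TG", node_end()), 1L)
  expect_identical(edge_instances(g, "TG", node_end())$tau, "C")
  expect_identical(edge_flow(g, "AG", node_end()), 1L)
  expect_identical(nrow(g$edges), 15L)
  expect_identical(g$skipped_reads, 0L)
})

test_that("edge rules respect their boundary conditions", {
  a <- toy_anchors()
  # a read equal to one anchor span: node presence only, no edges
  g1 <- build_graph(read_set("AT"), a)
  expect_identical(nrow(g1$edges), 0L)
  expect_true("AT" %in% g1$nodes)
  # first anchor at position 3: prefix edge with delta 2 and the leading bases
  g2 <- build_graph(read_set("CCCTAG"), a)
  pre <- edge_instances(g2, node_start(), "CT")
  expect_identical(pre$delta, 2L)
  expect_identical(pre$tau, "CC")
  # gap between anchors: delta exceeds |u|, tag records the interior
  g3 <- build_graph(read_set("ATGGGCT"), anchor_set(c("AT", "CT")))
  gap <- edge_instances(g3, "AT", "CT")
  expect_identical(gap$delta, 5L)
  expect_identical(gap$tau, "GGG")
  expect_identical(nchar(gap$tau), gap$delta - nchar("AT"))
  # trailing uncovered bases: suffix edge carries them
  g4 <- build_graph(read_set("ATGGGCTAAAA"), anchor_set(c("AT", "CT")))
  suf <- edge_instances(g4, "CT", node_end())
  expect_identical(suf$delta, 4L)
  expect_identical(suf$tau, "AAAA")
  # contract violations
  occ <- locate_occurrences("ATGCTA", 1L, a)
  rd <- list(id = "r", seq = "ATGCTA")
  expect_error(add_prefix_edge(toy_graph(), rd, occ[1, ]), "after position 1")
  expect_error(add_suffix_edge(toy_graph(), rd, occ[4, ]), "before the read end")
  expect_error(add_internal_edge(toy_graph(), rd, occ[2, ], occ[1, ]), "increasing start order")
  expect_error(build_graph(read_set(character(0)), a), "empty")
})

test_that("single-rule operations agree with the bulk builder", {
  a <- toy_anchors()
  rd <- list(id = "read_2", seq = "GCTAGC")
  occ <- locate_occurrences(rd$seq, 2L, a)
  g <- vmusdbg:::.new_graph(a$words)
  g <- add_prefix_edge(g, rd, occ[1, ])
  for (i in seq_len(nrow(occ) - 1L)) g <- add_internal_edge(g, rd, occ[i, ], occ[i + 1L, ])
  g <- add_suffix_edge(g, rd, occ[nrow(occ), ])
  gb <- build_graph(read_set(rd$seq, rd$id), a)
  expect_identical(graph_sig(g), graph_sig(gb))
})

test_that("per-read instance counts and internal deltas telescope", {
  set.seed(91)
  for (i in 1:25) {
    r <- rand_dna(sample(10:80, 1))
    a <- extract_mus(r, uniqueness_config("genome"))
    occ <- locate_occurrences(r, 1L, a)
    p <- nrow(occ)
    g <- build_graph(read_set(r), a)
    expected_rows <- (p - 1L) + as.integer(occ$start[1L] > 1L) +
      as.integer(occ$end[p] < nchar(r))
    expect_identical(nrow(g$edges), expected_rows)
    internal <- g$edges[g$edges$from != node_start() & g$edges$to != node_end(), ]
    expect_identical(sum(internal$delta), occ$start[p] - occ$start[1L])
  }
})

test_that("the graph does not depend on read order", {
  set.seed(14)
  a <- toy_anchors()
  g0 <- graph_sig(build_graph(toy_reads(), a))
  for (i in 1:5) {
    perm <- sample(5L)
    rs <- read_set(toy_reads()$seq[perm], toy_reads()$id[perm])
    expect_identical(graph_sig(build_graph(rs, a)), g0)
  }
})

test_that("node metadata records the longest terminal flanks", {
  g <- toy_graph()
  expect_identical(g$props[[node_start()]]$max_prefix, list(seq = "G", len = 1L))
  expect_identical(g$props[["CT"]]$max_prefix, list(seq = "G", len = 1L))
  expect_identical(g$props[[node_end()]]$max_suffix, list(seq = "C", len = 1L))
  expect_identical(g$props[["TG"]]$max_suffix, list(seq = "C", len = 1L))
  expect_identical(g$props[["AT"]]$max_prefix, list(seq = "", len = 0L))
})

test_that("GFA export lists all segments and round-trips nodes and flows", {
  g <- toy_graph()
  lines <- export_gfa(g)
  s_lines <- grep("^S\t", lines, value = TRUE)
  expect_identical(length(s_lines), 9L)  # 7 anchors + 2 terminals
  expect_identical(sum(grepl("TN:i:1", s_lines)), 2L)
  back <- read_gfa(lines)
  expect_setequal(back$nodes, g$nodes)
  el <- graph_edges(g)
  rownames(el) <- rownames(back$edges) <- NULL
  expect_identical(back$edges, el)
  # an entirely empty graph is just the header
  empty <- vmusdbg:::.new_graph(character(0))
  empty$nodes <- character(0)
  expect_identical(export_gfa(empty), "H\tVN:Z:1.0")
})

test_that("graph JSON dumps are lossless", {
  g <- toy_graph()
  f <- tempfile(fileext = ".json")
  graph_to_json(g, f)
  g2 <- graph_from_json(f)
  expect_identical(g2$edges, g$edges)
  expect_identical(g2$nodes, g$nodes)
  expect_identical(g2$props, g$props)
  expect_identical(g2$skipped_reads, g$skipped_reads)
  expect_identical(g2$next_iid, g$next_iid)
})
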