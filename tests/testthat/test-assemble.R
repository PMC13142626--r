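test_that("degree summaries separate unique and total degrees", {
  g <- toy_graph()
  at <- degree_summary(g, "AT")
  expect_identical(at, list(unique_in = 1L, unique_out = 1L, total_in = 2L, total_out = 2L))
  tg <- degree_summary(g, "TG")
  expect_identical(tg$unique_out, 2L)  # CT and the sink
  expect_identical(degree_summary(g, node_start())$total_in, 0L)
  expect_identical(degree_summary(g, node_end())$total_out, 0L)
  expect_error(degree_summary(g, "GGGG"), "unknown node")
})

test_that("junctions are terminals or nodes with non-unit unique degree", {
  g <- toy_graph()
  expect_true(is_junction(g, node_start()))
  expect_true(is_junction(g, node_end()))
  expect_true(is_junction(g, "TG"))   # two distinct successors
  expect_true(is_junction(g, "CT"))   # predecessors TG and the source
  expect_false(is_junction(g, "TA"))  # 1-in-1-out interior node
  expect_false(is_junction(g, "AT"))  # parallel flow does not branch
})

test_that("best instance selection follows the weight/tag rules", {
  gi <- mk_graph(c("AAA", "TTT"), data.frame(
    from = "AAA", to = "TTT", delta = c(5L, 4L), tau = c("AA", "G"),
    stringsAsFactors = FALSE))
  b <- best_instance(gi, "AAA", "TTT")
  expect_identical(c(b$delta, b$tau), c("4", "G"))  # smallest weight wins
  gt <- mk_graph("AAA", data.frame(
    from = "AAA", to = node_end(), delta = c(1L, 3L), tau = c("C", "CAT"),
    stringsAsFactors = FALSE))
  b <- best_instance(gt, "AAA", node_end())
  expect_identical(b$tau, "CAT")  # terminal edges prefer the longest tag
  b <- best_instance(toy_graph(), "AT", "TG")
  expect_identical(c(b$delta, b$tau), c(1L, ""))
  expect_error(best_instance(toy_graph(), "AT", "GCA"), "no edge")
  # ties on (delta, |tau|) break lexicographically by tag
  gx <- mk_graph(c("AAA", "TTT"), data.frame(
    from = "AAA", to = "TTT", delta = 5L, tau = c("GA", "AG"),
    stringsAsFactors = FALSE))
  expect_identical(best_instance(gx, "AAA", "TTT")$tau, "AG")
})

test_that("MNBP extraction handles chains, forks and isolated cycles", {
  # chain: one path from source to sink
  gc <- build_graph(read_set("GCTAGC"), toy_anchors())
  pc <- extract_mnbps(gc)
  expect_length(pc, 1L)
  expect_identical(pc[[1]]$nodes, c(node_start(), "CT", "TA", "AG", node_end()))
  expect_length(pc[[1]]$iids, 4L)
  # fork: a junction with two distinct successors starts two paths
  gf <- mk_graph(c("AAA", "CCC", "GGG"), data.frame(
    from = c("AAA", "AAA"), to = c("CCC", "GGG"), delta = c(4L, 4L),
    tau = c("C", "G"), stringsAsFactors = FALSE))
  pf <- extract_mnbps(gf)
  expect_length(pf, 2L)
  expect_setequal(vapply(pf, function(p) p$nodes[2], ""), c("CCC", "GGG"))
  # pure cycle with no junction: one circular unitig from the smallest node
  gcy <- mk_graph(c("CCC", "AAA", "GGG"), data.frame(
    from = c("AAA", "CCC", "GGG"), to = c("CCC", "GGG", "AAA"),
    delta = c(4L, 4L, 4L), tau = c("T", "T", "T"), stringsAsFactors = FALSE))
  pcy <- extract_mnbps(gcy)
  expect_length(pcy, 1L)
  expect_true(pcy[[1]]$circular)
  expect_identical(pcy[[1]]$nodes[1], "AAA")
  expect_length(pcy[[1]]$iids, 3L)
  expect_length(attr(pcy, "unused_iids"), 0L)
  # empty graph
  expect_length(extract_mnbps(vmusdbg:::.new_graph(character(0))), 0L)
})

test_that("each edge instance is used at most once and interiors partition", {
  g <- toy_graph()
  paths <- extract_mnbps(g)
  all_iids <- unlist(lapply(paths, `[[`, "iids"))
  expect_false(any(duplicated(all_iids)))
  expect_identical(sort(c(all_iids, attr(paths, "unused_iids"))), sort(g$edges$iid))
  # every non-junction node is interior to exactly one path
  interior_counts <- table(unlist(lapply(paths, function(p) {
    p$nodes[-c(1L, length(p$nodes))]
  })))
  nonjunction <- Filter(function(n) !is_junction(g, n), g$nodes)
  for (n in nonjunction) expect_identical(as.integer(interior_counts[n]), 1L)
})

test_that("path spelling follows the overlap recursion", {
  a <- toy_anchors()
  # AT (1,e) TG (2,e) CT (1,e) TA: overlap, abutment, overlap
  expect_identical(spell_read("ATGCTA", a), "ATGCTA")
  # source tag base case and sink tag append
  expect_identical(spell_read("GCTAGC", a), "GCTAGC")
  # a path that is a single node spells its word
  single <- structure(list(nodes = "GCA", iids = integer(0), circular = FALSE),
                      class = "unitig_path")
  expect_identical(spell_path(single, toy_graph())$seq, "GCA")
  # gap case: phi < 0 appends the tag then the whole next word
  gg <- mk_graph(c("AT", "CT"), data.frame(from = "AT", to = "CT", delta = 5L,
                                           tau = "GGG", stringsAsFactors = FALSE))
  pg <- extract_mnbps(gg)
  expect_identical(spell_path(pg[[1]], gg)$seq, "ATGGGCT")
  # an overlap larger than the next anchor is a hard error naming the hop
  bad <- data.frame(from = "ATG", to = "C", delta = 0L, tau = "", iid = 1L,
                    stringsAsFactors = FALSE)
  expect_error(vmusdbg:::.spell_hops(bad), "impossible overlap at hop 1")
})

test_that("spelling a read's own occurrence path reproduces the read", {
  set.seed(5)
  for (i in 1:100) {
    r <- rand_dna(sample(15:80, 1))
    a <- extract_mus(r, uniqueness_config("genome"))
    expect_identical(spell_read(r, a), r)
  }
})

test_that("toy end-to-end assembly yields substrings of the doubled genome", {
  s <- simplify_graph(toy_graph())
  ct <- assemble_contigs(s$graph, s$records)
  dbl <- paste0(toy_genome(), toy_genome())
  expect_true(all(vapply(ct$seq, grepl, TRUE, x = dbl, fixed = TRUE)))
  expect_identical(ct$seq, c("AGCACATG", "CTAG", "TGCT", "AGC", "GCT", "TGC"))
  expect_identical(ct$id, paste0("contig_", 1:6))
  expect_identical(ct$length, nchar(ct$seq))
})

test_that("boundary-aligned circular reads recover one genome rotation", {
  # every read starts at an anchor start and ends at an anchor end, so no
  # terminal edges break the anchor cycle; after collapsing, the whole genome
  # survives as one circular unitig
  a <- toy_anchors()
  rs <- read_set(c("ATGCTA", "TAGCAC", "ACAT"))
  s <- simplify_graph(build_graph(rs, a))
  ct <- assemble_contigs(s$graph, s$records)
  expect_identical(nrow(ct), 1L)
  expect_true(ct$circular[1])
  expect_true(is_rotation_of(ct$seq[1], toy_genome()))
})

test_that("spelling is conserved under simplification", {
  g <- chain_graph()
  p0 <- extract_mnbps(g)
  expect_length(p0, 1L)
  before <- spell_path(p0[[1]], g)$seq
  s <- simplify_graph(g)
  p1 <- extract_mnbps(s$graph)
  expect_length(p1, 1L)
  expect_identical(spell_path(p1[[1]], s$graph, s$records)$seq, before)
  expect_identical(before, "GCAATACCCGTGGTTAG")
})

test_that("assembly statistics implement the N50 definition", {
  expect_identical(assembly_stats(c(10, 6, 4))$n50, 10L)
  expect_identical(assembly_stats(7)$largest, 7L)
  expect_identical(assembly_stats(7)$n50, 7L)
  empty <- assembly_stats(integer(0))
  expect_identical(empty, list(contigs = 0L, total_length = 0L, largest = 0L, n50 = 0L))
  expect_identical(assembly_stats(c(5, 5, 5, 5))$n50, 5L)
  expect_identical(assembly_stats(c(8, 4, 4), reference_length = 20)$reference_length, 20L)
})
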