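# vmusdbg

De novo genome assembly with a **variable-length minimum-unique-substring de
Bruijn graph**. Instead of breaking reads into fixed-length k-mers, the graph's
nodes are *minimum unique substrings* (MUSs): substrings that occur exactly
once in the assembly scope and cannot be shortened at either end without
losing uniqueness. MUS lengths adapt to local sequence context and MUSs sit at
the boundaries of maximal repeats, so the graph encodes repeat structure
without any global k parameter. The package is aimed at people studying
assembly-graph models: every stage — anchor extraction, graph construction,
simplification, traversal, contig spelling — is an exported, testable
function, and a synthetic-data module generates the circular genomes with
planted repeats needed to exercise them.

## The model

For a read set ℛ and an anchor set 𝒜 of MUSs, the assembly graph is a directed
multigraph whose nodes are the anchors plus a global source and sink. Per
read, anchor occurrences are sorted by start position and every consecutive
pair (u at [s_u, e_u], v at [s_v, e_v]) contributes one *edge instance* with

- weight δ(u, v) = s_v − s_u, and
- tag τ = R[e_u + 1 : s_v − 1] when δ > |u| (a gap, typically spanning a
  repeat), or τ = ε when the anchors overlap or abut.

A read whose first anchor starts after position 1 adds a source edge tagged
with the uncovered prefix; a read whose last anchor ends early adds a sink
edge tagged with the uncovered suffix. The flow f(u, v) counts instances.
Strictly linear nodes (1-in-1-out, flow 1) are collapsed into merged edges
(δ₁+δ₂, τ₁·v·τ₂); maximal non-branching paths between junctions become
unitigs; and a path P = v₀…v_k is spelled via the overlap
φᵢ = |v_i| − δᵢ:

    S(P) = seq(v0) · Π Δ(v_i, v_i+1),
    Δ = suffix(seq(v_i+1), |v_i+1| − φ) if φ > 0
        seq(v_i+1)                      if φ = 0
        τ · seq(v_i+1)                  if φ < 0

with the source tag prepended and the sink tag appended when present.

## Worked example

The bundled fixture is the 10 bp circular genome `ATGCTAGCAC` and five 6 bp
reads sampled with overlap from it:

```r
library(vmusdbg)
anchors <- extract_mus(toy_genome(), uniqueness_config("genome", circular = TRUE))
anchors$words
#> [1] "AC"  "AG"  "AT"  "CT"  "GCA" "TA"  "TG"

g <- build_graph(toy_reads(), anchors)
edge_flow(g, "AT", "TG")
#> [1] 2
edge_instances(g, "AT", "TG")[, c("delta", "tau", "read_id")]
#>    delta tau read_id
#> 1      1      read_1
#> 14     1      read_5

s <- simplify_graph(g)
assemble_contigs(s$graph, s$records)
#> contig_set: 6 contig(s), total 25 bp, largest 8 bp, N50 4 bp
```

The two `(1, ε)` instances of the edge AT→TG record that reads 1 and 5 both
saw TG start one position after AT with full overlap; the edge TG→CT carries
the single instance `(2, ε)`. The six contigs (`AGCACATG`, `CTAG`, `TGCT`,
`AGC`, `GCT`, `TGC`) are the maximal non-branching paths of the toy graph;
each is an exact substring of the doubled circular genome. When read
boundaries align with anchor boundaries the whole cycle instead survives
collapsing and is emitted as one circular contig equal to a rotation of the
genome:

```r
s <- simplify_graph(build_graph(read_set(c("ATGCTA", "TAGCAC", "ACAT")), anchors))
assemble_contigs(s$graph, s$records)$seq
#> [1] "TGCTAGCACA"
```

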