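---
title: "Assembly with a variable-length MUS de Bruijn graph: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assembly with a variable-length MUS de Bruijn graph: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vmusdbg)
```

## The problem and the model

Fixed-k de Bruijn assembly faces a structural trade-off: small k collapses
repeats, large k fragments low-coverage regions, and no single k is optimal
across a genome. This package implements an assembly graph whose nodes are
**minimum unique substrings (MUSs)** — substrings that occur exactly once in
the assembly scope and are *minimal*, meaning that dropping the first
character (left-minimality) or the last character (right-minimality) yields a
string that is no longer unique. MUS lengths adapt to local context: in
repetitive neighbourhoods they grow until they become distinctive, in unique
sequence they stay short. Because the proper prefix and suffix of every MUS
are repeats, MUSs sit exactly at the boundaries of **maximal repeats**
(substrings occurring twice or more that cannot be extended at all their
occurrences on either side while remaining repeats), so a graph over MUS
anchors has repeat boundaries built into its topology rather than imposed by
a parameter.

On the bundled example — the circular genome `ATGCTAGCAC` — the anchors are

```{r}
anchors <- extract_mus(toy_genome(), uniqueness_config("genome", circular = TRUE))
anchors$words
```

Two facts about this set are worth keeping in mind. First, no MUS is a
substring of another, so at most one anchor starts at any position and
per-read occurrence lists have a total order. Second, the set depends on
whether occurrences are counted linearly or around the circle: linearly, `CA`
occurs once (so `CA` is an anchor and `GCA` fails right-minimality), while on
the circle `CA` also occurs across the wrap, making `GCA` the anchor. The
fixture genome is circular, so the circular count is the correct one for it;
`circular = FALSE` remains the default for genome-scope extraction because
linearity is the safe assumption for arbitrary input.

```{r}
extract_mus(toy_genome(), uniqueness_config("genome"))$words  # linear: CA, not GCA
```

### Uniqueness scope

`uniqueness_config()` fixes the scope of "occurs exactly once":

* `scope = "genome"` counts occurrences in one string (optionally circular,
  optionally on both strands). This is the scope used by the fixture and by
  the simulation tests, where anchors are extracted from the known source
  genome and the graph is then built from reads.
* `scope = "reads"` counts occurrences pooled over every read (plus reverse
  complements when enabled). This honours the definition of uniqueness over a
  read set, but note its operational oddity: at meaningful coverage most
  genomic substrings appear in many reads, so read-scope MUSs are rare and
  long. The mode is provided as a best-effort reading and the two backends
  agree on it; the genome scope is what the worked example actually
  reproduces.

Reverse-complement counting defaults to off because the example anchor set is
forward-only; `use_reverse_complement = TRUE` enables canonical counting for
real double-stranded data.

### Extraction backends

Two independent mechanisms compute the same anchor set:

* `backend = "suffix_array"` (default): a prefix-doubling suffix array over an
  integer-coded corpus with per-segment unique sentinels, Kasai's LCP array,
  and nearest-countable-neighbour LCPs. The shortest unique substring at
  position i has length one plus the larger LCP with its suffix-array
  neighbours; a position yields a MUS when that candidate fits in its segment
  and the position one to its right cannot produce a shorter-or-equal unique
  substring (left-minimality). Circularity is handled by doubling the text
  and restricting countable starts to the first period; reverse complements
  and multiple reads are extra corpus segments whose positions count but
  never emit.
* `backend = "brute_force"`: per-length substring tabulation — enumerate all
  substrings of each length, count them, keep the unique ones whose
  length-(L−1) prefix and suffix both occur at least twice. It is O(n·L) in
  tabulation passes and serves as the oracle: the suite checks exact
  agreement on hundreds of random strings, and the acceptance checks repeat
  this at length up to 200.

A suffix-tree backend is not provided; the suffix array covers the same
contract with far smaller constants in R, and nothing downstream depends on
the index structure.

## Graph construction

For each read, occurrences are located and sorted by start; then three rules
fire (1-based closed coordinates everywhere):

* **prefix rule** — if the first anchor starts at s₁ > 1, add an edge from
  the global source with δ = s₁ − 1 and τ = the uncovered read prefix;
* **internal rule** — for each consecutive pair, add an edge with
  δ = s_{i+1} − s_i and τ = the intervening substring when δ > |u| (a gap,
  i.e. a repeat-spanning transition), else τ = ε (overlap/abutment);
* **suffix rule** — if the last anchor ends at e_p < |R|, add an edge into
  the global sink with δ = |R| − e_p and τ = the uncovered suffix.

Every rule application appends one *instance* (δ, τ, read id) to its edge;
the flow f(u, v) is the instance count. A read with p occurrences therefore
contributes exactly (p−1) internal instances plus its boundary instances — a
telescoping identity (the internal δs sum to s_p − s₁) that the test suite
checks on random reads. Reads with no occurrence contribute nothing and are
counted; a read that exactly spans one anchor contributes node presence only.
Self-loops (the same anchor twice in a row) are ordinary edges. Nodes also
carry the longest prefix/suffix ever observed at read boundaries around them
(`max_prefix`/`max_suffix`); these are reporting metadata updated by the
boundary rules and are not consulted by traversal.

```{r}
g <- build_graph(toy_reads(), anchors)
graph_edges(g)
```

## Simplification

A non-terminal node is **strictly linear** when its unique in- and out-degree
and its total in- and out-flow are all 1. Such a node v on u → v → w is
collapsed into a merged edge (u, w) with δ = δ₁ + δ₂ and τ = τ₁·v·τ₂.
Collapsing is confluent (the suite randomises the order), but candidates are
processed in lexicographic order so dumps are byte-stable. Nodes on
self-loops are never collapsed — the merge formula presumes three distinct
path nodes — and the literal flow-1 condition is implemented: chains with
parallel flow are left alone rather than collapsed with multiplicities.

One subtlety matters for correctness: when the collapsed hops overlap
(τ = ε, δ ≤ |u|), the merged tag τ₁·v·τ₂ contains v in full and therefore
double-counts the overlap; the merged label is not literally the spelled
interior. Each collapse therefore emits a **record** holding both source
instances, and contig spelling expands merged instances back to base-level
labels through these records before applying the spelling recursion. With
expansion, spelling any path in the simplified graph equals spelling the
corresponding pre-collapse path exactly (tested), and for gap-only chains the
merged tag does spell the interior verbatim.

## Traversal and spelling

Degrees come in two flavours: **unique** degrees count distinct neighbour
nodes; **total** degrees count instances (read support). A **junction** is a
terminal node or any node whose unique in- or out-degree differs from 1 —
including nodes whose extra neighbour is a terminal: a read boundary inside
otherwise-linear sequence makes that anchor a junction. Unitigs are **maximal
non-branching paths**: each starts and ends at a junction, has 1-in-1-out
interiors, and consumes one instance per hop, chosen best-first among unused
instances. The best instance of an internal edge is the one with the smallest
δ (tie: longest τ); for terminal edges it is the longest τ (tie: smallest δ);
remaining ties break lexicographically by τ then read id so that extraction
is deterministic. Across all paths each instance is used at most once;
instances not needed by any structural path are reported as unused rather
than spawning duplicate paths. Cycles consisting entirely of 1-in-1-out nodes
touch no junction and would otherwise be lost; they are emitted as circular
unitigs starting at their lexicographically smallest node and flagged
`circular` in output.

Spelling follows the overlap recursion: starting from the first anchor (or
source tag plus first anchor), each hop computes φ = |u| − δ and appends the
last |v| − φ characters of v when φ > 0, all of v when φ = 0, or τ followed
by v when φ < 0 (a gap); a sink hop appends its tag. φ > |v| cannot arise
from well-formed occurrence lists and is treated as a hard error naming the
hop, not clamped. For circular unitigs the closing hop is spelled and the
duplicated leading word trimmed, yielding one rotation of the cycle. The
fundamental identity — spelling a read's own occurrence path reproduces the
read — holds for every read by the telescoping of δ, and is tested on the
fixture reads and a thousand random reads.

## The synthetic-data generator

`make_genome()` draws a uniform random A/C/G/T background and plants exact
repeat copies (length × copy-number pairs) at non-overlapping uniform
positions, annotated in BED coordinates; `sample_reads()` samples error-free
reads of fixed or uniform-random length at uniform starts, wrapping across
the origin of circular genomes, with read count `round(coverage ·
genome_length / read_length)`. Both are byte-deterministic under a seed. The
defaults mirror the regime the model targets: a small circular genome read by
clean, long, overlapping reads. The generator deliberately omits sequencing
errors (a substitution-rate hook exists but defaults to 0 — single-base
errors break uniqueness and the model defers error correction), quality
modelling, coverage bias and chimeras. Passing simulation tests therefore
demonstrate the graph algebra on ideal data, not robustness to real-read
artefacts.

The simulation scale used throughout the tests is a 2 kb circular genome with
20× coverage of 200 bp reads (with and without a 50 bp × 2 planted repeat),
which keeps the whole suite in tens of seconds while giving ~1200 anchors and
~23000 edge instances — comfortably non-trivial topology.

## Behaviour on simulated data, and a structural limitation

On the 2 kb / 20× simulation the pipeline's contigs are exact substrings of
the doubled genome and cover it completely. They are, however, *many short*
contigs rather than one: with uniformly placed reads, nearly every anchor
that happens to start just after a read boundary receives a source edge (and
symmetrically a sink edge), its unique degree then differs from 1, and it
becomes a junction. The MNBP decomposition consequently fragments at read
boundaries even on a repeat-free genome. This is a direct consequence of the
junction definition counting terminal neighbours, and it is why single-contig
circular recovery under uniform sampling is not achieved by this model: a
lone circular contig appears exactly when every read boundary coincides with
an anchor boundary, as in the boundary-aligned example in the README. The
corresponding acceptance test records this expectation and its failure
honestly rather than weakening the junction definition, which the worked
example's degree facts (TG has unique out-degree 2: its successor CT and the
sink) pin down.

## Other design choices and limitations

* Maximal repeats require at least two occurrences (the two-occurrence `GC`
  example fixes the intended threshold), and maximality is the standard
  left/right-extension criterion with text boundaries counting as distinct
  context.
* Non-ACGT input: reads are uppercased and split at non-ACGT runs into
  sub-reads before any extraction; a single ambiguous base would otherwise
  manufacture spurious unique substrings. Genome-scope extraction rejects
  non-ACGT text outright.
* Merged edges inherit the concatenated read-id provenance of their source
  instances, so collapse records remain traceable.
* The pipeline is single-process and deterministic; manifests record
  parameters and input checksums, never timestamps, so reruns are
  byte-identical.
* Memory/performance: all indexing is pure R (prefix doubling is
  O(n log² n)); the intended operating range is desk-scale experimentation
  up to tens of kilobases, not production assembly of real sequencing runs.
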