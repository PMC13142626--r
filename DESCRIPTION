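Package: vmusdbg
Title: De Novo Assembly with a Variable-Length Minimum-Unique-Substring de Bruijn Graph
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds assembly graphs whose nodes are minimum unique substrings
    (MUSs) instead of fixed-length k-mers. Provides suffix-array and brute-force
    MUS extraction from genomes or read sets, maximal-repeat detection,
    construction of a directed multigraph whose edges carry read-supported
    positional weights and repeat tags, strictly-linear-node collapsing,
    maximal non-branching path extraction with best-instance selection, contig
    spelling, assembly statistics, an error-free read simulator for circular
    genomes with planted repeats, and FASTA/FASTQ/GFA/TSV/JSON input and output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
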