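#' Run the full assembly pipeline
#'
#' Executes extraction, graph construction, simplification, traversal and
#' statistics in order and writes all outputs plus a manifest into
#' `output_dir`. Outputs are only written after every stage has succeeded, so
#' a failed run leaves no partial files; stage errors are re-raised with the
#' stage name. Given identical inputs and parameters the outputs are
#' byte-identical across runs (the manifest records parameters and input
#' checksums, never timestamps).
#'
#' Files written: `anchors.tsv`, `graph.gfa`, `graph.json`,
#' `graph_simplified.json`, `collapses.tsv`, `contigs.fa`, `stats.json`,
#' `manifest.json`.
#'
#' @param input A FASTA/FASTQ path (plain or gzipped) or a [read_set()].
#' @param output_dir Output directory (created if needed).
#' @param genome Genome string or FASTA path; required when
#'   `scope = "genome"` (anchors are extracted from the genome, uniqueness at
#'   genome scope).
#' @param scope,circular,use_reverse_complement,backend Passed to
#'   [uniqueness_config()].
#' @param seed Recorded in the manifest and set before running; the pipeline
#'   itself is deterministic.
#' @param verbose Print per-stage node/edge/anchor counts.
#' @return Invisibly, a list with `anchors`, `graph`, `simplified`, `records`,
#'   `contigs`, `stats`, `manifest`.
#' @examples
#' out <- run_pipeline(toy_reads(), tempfile("toyasm"), genome = toy_genome(),
#'                     circular = TRUE, verbose = FALSE)
#' out$stats$n50
#' @export
run_pipeline <- function(input, output_dir, genome = NULL,
                         scope = c("genome", "reads"), circular = FALSE,
                         use_reverse_complement = FALSE,
                         backend = "suffix_array", seed = NULL,
                         verbose = TRUE) {
  scope <- match.arg(scope)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)), call. = FALSE)
    })
  }
  say <- function(...) if (verbose) message(sprintf(...))
  if (!is.null(seed)) set.seed(seed)

  input_path <- NULL
  reads <- stage("input", {
    if (inherits(input, "read_set")) input
    else {
      input_path <- input
      read_fastx(input)
    }
  })
  if (nrow(reads) == 0L) stop("stage 'input' failed: no reads", call. = FALSE)
  say("input: %d read(s), %d bp", nrow(reads), sum(nchar(reads$seq)))

  cfg <- uniqueness_config(scope, use_reverse_complement, circular, backend)
  anchors <- stage("extract", {
    if (scope == "genome") {
      if (is.null(genome)) stop("scope 'genome' requires a genome sequence or FASTA path")
      if (file.exists(genome)) genome <- read_fastx(genome)$seq[1L]
      extract_mus(genome, cfg)
    } else {
      extract_mus(reads, cfg)
    }
  })
  say("extract: %d anchor(s), lengths %d-%d", length(anchors$words),
      min(nchar(anchors$words)), max(nchar(anchors$words)))

  graph <- stage("build", build_graph(reads, anchors))
  say("build: %d node(s), %d edge instance(s), %d read(s) skipped",
      length(graph$nodes), nrow(graph$edges), graph$skipped_reads)

  simp <- stage("simplify", simplify_graph(graph))
  say("simplify: %d node(s) collapsed, %d remaining", nrow(simp$records),
      length(simp$graph$nodes))

  contigs <- stage("assemble", assemble_contigs(simp$graph, simp$records))
  ref_len <- if (scope == "genome") nchar(genome) else NULL
  stats <- stage("stats", assembly_stats(contigs, reference_length = ref_len))
  say("assemble: %d contig(s), total %d bp, N50 %d bp", stats$contigs,
      stats$total_length, stats$n50)

  manifest <- list(
    package = "vmusdbg",
    version = as.character(utils::packageVersion("vmusdbg")),
    parameters = list(scope = scope, circular = circular,
                      use_reverse_complement = use_reverse_complement,
                      backend = backend, seed = seed),
    input = list(path = input_path,
                 md5 = if (!is.null(input_path)) unname(tools::md5sum(input_path)) else NULL,
                 reads = nrow(reads), bases = sum(nchar(reads$seq))),
    anchors = length(anchors$words),
    graph = list(nodes = length(graph$nodes), instances = nrow(graph$edges),
                 skipped_reads = graph$skipped_reads),
    simplified = list(nodes = length(simp$graph$nodes), collapses = nrow(simp$records)),
    stats = stats
  )

  stage("output", {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    write_anchors(anchors, file.path(output_dir, "anchors.tsv"))
    export_gfa(graph, file.path(output_dir, "graph.gfa"))
    graph_to_json(graph, file.path(output_dir, "graph.json"))
    graph_to_json(simp$graph, file.path(output_dir, "graph_simplified.json"))
    write_collapses(simp$records, file.path(output_dir, "collapses.tsv"))
    write_fasta(contigs, file.path(output_dir, "contigs.fa"))
    jsonlite::write_json(stats, file.path(output_dir, "stats.json"),
                         auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE)
  })

  invisible(list(anchors = anchors, graph = graph, simplified = simp$graph,
                 records = simp$records, contigs = contigs, stats = stats,
                 manifest = manifest, output_dir = output_dir))
}
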