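#' Generate a random genome with planted exact repeats
#'
#' Draws a uniform random A/C/G/T background and plants exact repeat copies at
#' non-overlapping random positions. The generator emulates the regime the
#' assembler targets: a small (by default circular) genome whose only
#' structured feature is exact repeated sequence, so that repeat-aware graph
#' behaviour can be tested without external data.
#'
#' @param length Genome length in bp.
#' @param circular Logical; the genome is treated as circular downstream.
#' @param repeats A list of `c(unit_length, copy_number)` pairs; each entry
#'   plants `copy_number` exact copies of one random unit. Copies never
#'   overlap each other.
#' @param seed Integer seed; with a fixed seed the output is byte-identical
#'   across runs.
#' @param toy If `TRUE`, return the worked-example fixture: the 10 bp circular
#'   genome `ATGCTAGCAC` with no annotation.
#' @return A list with `seq` (string), `circular`, and `repeats`, a BED-style
#'   data frame (`chrom`, `start`, `end` 0-based half-open, `name`) of planted
#'   repeat intervals.
#' @examples
#' g <- make_genome(500, repeats = list(c(40, 2)), seed = 1)
#' g$repeats
#' @export
make_genome <- function(length = 1000L, circular = TRUE, repeats = list(),
                        seed = NULL, toy = FALSE) {
  if (isTRUE(toy)) {
    return(list(seq = toy_genome(), circular = TRUE,
                repeats = data.frame(chrom = character(0), start = integer(0),
                                     end = integer(0), name = character(0))))
  }
  if (!is.null(seed)) set.seed(seed)
  length <- as.integer(length)
  planted <- sum(vapply(repeats, function(r) as.integer(r[1]) * as.integer(r[2]), integer(1)))
  if (length < planted + 1L) stop("genome length must exceed total planted repeat content")
  bases <- c("A", "C", "G", "T")
  gseq <- sample(bases, length, replace = TRUE)
  bed <- list()
  occupied <- rep.int(FALSE, length)
  for (ri in seq_along(repeats)) {
    L <- as.integer(repeats[[ri]][1])
    copies <- as.integer(repeats[[ri]][2])
    unit <- sample(bases, L, replace = TRUE)
    for (ci in seq_len(copies)) {
      placed <- FALSE
      for (try in seq_len(1000L)) {
        st <- sample.int(length - L + 1L, 1L)
        span <- st:(st + L - 1L)
        if (!any(occupied[span])) {
          gseq[span] <- unit
          occupied[span] <- TRUE
          bed[[length(bed) + 1L]] <- data.frame(
            chrom = "genome", start = st - 1L, end = st + L - 1L,
            name = sprintf("repeat%d_copy%d", ri, ci), stringsAsFactors = FALSE)
          placed <- TRUE
          break
        }
      }
      if (!placed) stop("could not place planted repeat after bounded retries")
    }
  }
  bed <- if (length(bed)) do.call(rbind, bed) else
    data.frame(chrom = character(0), start = integer(0), end = integer(0),
               name = character(0), stringsAsFactors = FALSE)
  list(seq = paste(gseq, collapse = ""), circular = isTRUE(circular), repeats = bed)
}

#' Sample error-free reads from a genome
#'
#' Reads are exact substrings with uniform random start positions; on a
#' circular genome starts wrap across the origin. The number of reads is
#' `round(coverage * genome_length / mean(read_length))`. A substitution-rate
#' hook exists but defaults to 0: the model assumes clean long reads and
#' defers error handling.
#'
#' @param genome A genome string or the list returned by [make_genome()].
#' @param coverage Requested mean coverage; 0 yields an empty read set.
#' @param read_length A single length, or `c(min, max)` for uniform lengths.
#' @param circular Overrides the genome's circular flag if given.
#' @param error_rate Per-base substitution probability (default 0).
#' @param seed Integer seed for reproducible sampling.
#' @param toy If `TRUE`, return the worked-example fixture reads
#'   `{ATGCTA, GCTAGC, TAGCAC, GCACAT, ACATGC}`.
#' @return A [read_set()].
#' @examples
#' g <- make_genome(500, seed = 1)
#' sample_reads(g, coverage = 5, read_length = 50, seed = 2)
#' @export
sample_reads <- function(genome, coverage, read_length, circular = NULL,
                         error_rate = 0, seed = NULL, toy = FALSE) {
  if (isTRUE(toy)) return(toy_reads())
  if (is.list(genome)) {
    if (is.null(circular)) circular <- genome$circular
    genome <- genome$seq
  }
  if (is.null(circular)) circular <- FALSE
  if (!is.null(seed)) set.seed(seed)
  n <- nchar(genome)
  rl <- as.integer(read_length)
  if (any(rl > n)) stop("read length may not exceed genome length")
  n_reads <- as.integer(round(coverage * n / mean(rl)))
  if (n_reads <= 0L) return(read_set(character(0)))
  lens <- if (length(rl) == 2L) sample(rl[1]:rl[2], n_reads, replace = TRUE) else
    rep.int(rl[1L], n_reads)
  if (circular) {
    starts <- sample.int(n, n_reads, replace = TRUE)
    g2 <- paste0(genome, genome)
    seqs <- substring(g2, starts, starts + lens - 1L)
  } else {
    starts <- vapply(lens, function(L) sample.int(n - L + 1L, 1L), integer(1))
    seqs <- substring(genome, starts, starts + lens - 1L)
  }
  if (error_rate > 0) {
    bases <- c("A", "C", "G", "T")
    seqs <- vapply(seqs, function(s) {
      ch <- strsplit(s, "", fixed = TRUE)[[1]]
      hit <- which(stats::runif(length(ch)) < error_rate)
      for (i in hit) ch[i] <- sample(setdiff(bases, ch[i]), 1L)
      paste(ch, collapse = "")
    }, character(1), USE.NAMES = FALSE)
  }
  read_set(seqs, sprintf("read_%04d", seq_len(n_reads)))
}
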