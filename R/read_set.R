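#' Create a set of DNA reads
#'
#' A read set is the basic input container: an ordered collection of named DNA
#' sequences over the alphabet A/C/G/T. Coordinates into reads are 1-based and
#' closed throughout the package.
#'
#' @param seq Character vector of DNA sequences (uppercase A/C/G/T only).
#' @param id Character vector of unique read identifiers. Defaults to
#'   `read_1 .. read_n`.
#' @return A `read_set`: a data frame with columns `id` and `seq`.
#' @examples
#' rs <- read_set(c("ATGCTA", "GCTAGC"))
#' nrow(rs)
#' @export
read_set <- function(seq, id = NULL) {
  seq <- as.character(seq)
  if (is.null(id)) id <- if (length(seq)) paste0("read_", seq_along(seq)) else character(0)
  id <- as.character(id)
  if (length(id) != length(seq)) stop("'id' and 'seq' must have the same length")
  if (anyDuplicated(id)) stop("read ids must be unique")
  if (length(seq) && any(nchar(seq) == 0)) stop("reads must be non-empty")
  if (length(seq) && any(grepl("[^ACGT]", seq))) {
    stop("reads may only contain A/C/G/T; use sanitize_reads() first")
  }
  structure(
    data.frame(id = id, seq = seq, stringsAsFactors = FALSE),
    class = c("read_set", "data.frame")
  )
}

#' @export
print.read_set <- function(x, ...) {
  cat(sprintf("read_set with %d read(s), total %d bp\n", nrow(x), sum(nchar(x$seq))))
  if (nrow(x)) {
    show <- utils::head(x, 6L)
    for (i in seq_len(nrow(show))) {
      s <- show$seq[i]
      if (nchar(s) > 60) s <- paste0(substr(s, 1, 57), "...")
      cat(sprintf("  %s  %s (%d bp)\n", show$id[i], s, nchar(show$seq[i])))
    }
    if (nrow(x) > 6L) cat(sprintf("  ... and %d more\n", nrow(x) - 6L))
  }
  invisible(x)
}

#' Sanitize raw sequences into a valid read set
#'
#' Uppercases sequences and splits each read at runs of non-ACGT characters
#' (including N) into sub-reads; a single ambiguous base would otherwise create
#' spurious unique substrings. Sub-reads arising from a split get `/1`, `/2`,
#' ... suffixes on the original id. Empty fragments are dropped.
#'
#' @param seq Character vector of raw sequences.
#' @param id Optional identifiers (defaults as in [read_set()]).
#' @return A `read_set`.
#' @examples
#' sanitize_reads(c("acgtNNgga"), "r1")  # splits into r1/1, r1/2
#' @export
sanitize_reads <- function(seq, id = NULL) {
  seq <- toupper(as.character(seq))
  if (is.null(id)) id <- if (length(seq)) paste0("read_", seq_along(seq)) else character(0)
  out_seq <- character(0)
  out_id <- character(0)
  for (i in seq_along(seq)) {
    parts <- strsplit(seq[i], "[^ACGT]+")[[1]]
    parts <- parts[nzchar(parts)]
    if (length(parts) == 0L) next
    ids <- if (length(parts) == 1L) id[i] else paste0(id[i], "/", seq_along(parts))
    out_seq <- c(out_seq, parts)
    out_id <- c(out_id, ids)
  }
  read_set(out_seq, out_id)
}

#' Reverse complement of DNA strings
#'
#' @param x Character vector of A/C/G/T strings.
#' @return Character vector of reverse complements.
#' @examples
#' revcomp("ATGC")
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' The worked-example fixture: a 10 bp circular genome and its five reads
#'
#' `toy_genome()` returns the circular genome `ATGCTAGCAC`; `toy_reads()`
#' returns the five 6 bp reads sampled with overlap from it. Together they
#' exercise every stage of the assembler at desk scale.
#'
#' @return `toy_genome()`: a string; `toy_reads()`: a `read_set` of five reads.
#' @examples
#' toy_genome()
#' toy_reads()
#' @export
toy_genome <- function() "ATGCTAGCAC"

#' @rdname toy_genome
#' @export
toy_reads <- function() {
  read_set(c("ATGCTA", "GCTAGC", "TAGCAC", "GCACAT", "ACATGC"))
}
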