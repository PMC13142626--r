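#' Read sequences from FASTA or FASTQ
#'
#' Format is chosen from the file extension (`.fq`/`.fastq`, optionally
#' `.gz`-compressed, are FASTQ; anything else FASTA); quality strings are
#' ignored. Sequences are uppercased and split at non-ACGT runs via
#' [sanitize_reads()].
#'
#' @param path Input file (plain or gzipped).
#' @return A [read_set()].
#' @export
read_fastx <- function(path) {
  if (!file.exists(path)) stop(sprintf("input file '%s' does not exist", path))
  base <- sub("\\.gz$", "", path)
  fmt <- if (grepl("\\.(fq|fastq)$", base, ignore.case = TRUE)) "fastq" else "fasta"
  dss <- tryCatch(Biostrings::readDNAStringSet(path, format = fmt),
                  error = function(e) stop(sprintf("malformed %s in '%s': %s",
                                                   fmt, path, conditionMessage(e))))
  ids <- sub("\\s.*$", "", names(dss))
  sanitize_reads(as.character(dss), ids)
}

#' Write sequences to FASTA
#'
#' Contig sets get headers of the form `contig_1 length=10 circular=true`;
#' read sets and named character vectors use their ids. Sequence lines wrap at
#' 80 columns.
#'
#' @param x A `contig_set`, [read_set()], or named character vector.
#' @param path Output file.
#' @export
write_fasta <- function(x, path) {
  if (inherits(x, "contig_set")) {
    nm <- sprintf("%s length=%d circular=%s", x$id, x$length, tolower(x$circular))
    seqs <- x$seq
  } else if (inherits(x, "read_set")) {
    nm <- x$id
    seqs <- x$seq
  } else {
    nm <- names(x)
    seqs <- as.character(x)
  }
  dss <- Biostrings::DNAStringSet(stats::setNames(seqs, nm))
  Biostrings::writeXStringSet(dss, path, width = 80L)
  invisible(path)
}

#' Write reads as FASTQ with constant qualities
#'
#' @param reads A [read_set()].
#' @param path Output file; a `.gz` suffix triggers gzip compression.
#' @export
write_fastq <- function(reads, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(reads))) {
    writeLines(c(paste0("@", reads$id[i]), reads$seq[i], "+",
                 strrep("I", nchar(reads$seq[i]))), con)
  }
  invisible(path)
}

#' Anchor and occurrence tables
#'
#' `write_anchors()`/`read_anchors()` serialise an anchor set as TSV with
#' columns `anchor_id`, `word`, `length`. `occurrence_table()` locates all
#' anchor occurrences across a read set (columns `read_id`, `word`, `start`,
#' `end`; 1-based closed).
#'
#' @param anchors An [anchor_set()].
#' @param reads A [read_set()].
#' @param path TSV file.
#' @return `read_anchors()` returns an `anchor_set`; `occurrence_table()` a
#'   data frame.
#' @export
write_anchors <- function(anchors, path) {
  df <- data.frame(anchor_id = paste0("anchor_", seq_along(anchors$words)),
                   word = anchors$words, length = nchar(anchors$words),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_anchors
#' @export
read_anchors <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, colClasses = "character")
  anchor_set(df$word)
}

#' @rdname write_anchors
#' @export
occurrence_table <- function(reads, anchors) {
  out <- list()
  for (k in seq_len(nrow(reads))) {
    occ <- locate_occurrences(reads$seq[k], k, anchors)
    if (nrow(occ)) {
      out[[length(out) + 1L]] <- data.frame(read_id = reads$id[k], word = occ$word,
                                            start = occ$start, end = occ$end,
                                            stringsAsFactors = FALSE)
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(read_id = character(0), word = character(0),
               start = integer(0), end = integer(0), stringsAsFactors = FALSE)
}

#' Serialise collapse records
#'
#' @param records Collapse records from [simplify_graph()].
#' @param path TSV file.
#' @export
write_collapses <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = TRUE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_collapses
#' @export
read_collapses <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = c(iid = "integer", node = "character",
                                         from = "character", to = "character",
                                         delta = "integer", tau = "character",
                                         read_id = "character",
                                         left_iid = "integer", left_delta = "integer",
                                         left_tau = "character",
                                         right_iid = "integer", right_delta = "integer",
                                         right_tau = "character"),
                          na.strings = NULL)
  df
}
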