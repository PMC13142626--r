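#' Configure the uniqueness scope for MUS extraction
#'
#' A minimum unique substring (MUS) is defined relative to a scope text: either
#' a single genome string (optionally treated as circular) or the whole read
#' set. Occurrence counting may optionally include reverse complements.
#'
#' @param scope `"genome"` (uniqueness over one string) or `"reads"`
#'   (uniqueness over the pooled read sequences).
#' @param use_reverse_complement Count occurrences on both strands. Default
#'   `FALSE`: the worked example is forward-only.
#' @param circular Treat a genome-scope text as circular: occurrences are
#'   counted over all rotations (implemented by doubling the text and counting
#'   start positions modulo its length). Ignored for reads scope.
#' @param backend `"suffix_array"` (default; prefix-doubling suffix array with
#'   LCP neighbours) or `"brute_force"` (per-length substring tabulation, an
#'   independent mechanism kept as an oracle). `"suffix_tree"` is not
#'   implemented; suffix arrays supersede it here.
#' @return A `uniqueness_config` list.
#' @export
uniqueness_config <- function(scope = c("genome", "reads"),
                              use_reverse_complement = FALSE,
                              circular = FALSE,
                              backend = c("suffix_array", "brute_force", "suffix_tree")) {
  scope <- match.arg(scope)
  backend <- match.arg(backend)
  if (backend == "suffix_tree") {
    stop("backend 'suffix_tree' is not implemented; use 'suffix_array' (equivalent output)")
  }
  structure(
    list(scope = scope,
         use_reverse_complement = isTRUE(use_reverse_complement),
         circular = isTRUE(circular),
         backend = backend),
    class = "uniqueness_config"
  )
}

#' Construct an anchor set
#'
#' An anchor set is the operational MUS collection used as graph nodes. The
#' constructor checks the anti-nesting invariant: no anchor may be a substring
#' of another (which also guarantees at most one anchor starts at any position
#' of the scope text).
#'
#' @param words Character vector of anchor words (A/C/G/T).
#' @param scope Optional `uniqueness_config` the set was extracted under.
#' @return An `anchor_set`.
#' @export
anchor_set <- function(words, scope = NULL) {
  words <- sort(unique(as.character(words)), method = "radix")
  if (length(words) == 0L) stop("anchor set must be non-empty")
  if (any(grepl("[^ACGT]", words))) stop("anchor words may only contain A/C/G/T")
  for (w in words) {
    host <- words[nchar(words) > nchar(w)]
    if (length(host) && any(grepl(w, host, fixed = TRUE))) {
      stop(sprintf("anchor '%s' is nested inside another anchor", w))
    }
  }
  structure(list(words = words, scope = scope), class = "anchor_set")
}

#' @export
print.anchor_set <- function(x, ...) {
  cat(sprintf("anchor_set with %d MUS anchor(s), lengths %d-%d\n",
              length(x$words), min(nchar(x$words)), max(nchar(x$words))))
  if (length(x$words) <= 20L) cat(" ", paste(x$words, collapse = ", "), "\n")
  invisible(x)
}

# ---------------------------------------------------------------------------
# Corpus: a flat character vector with unique sentinel codes between segments.
# 'countable' marks positions where occurrences are counted (forward text plus
# reverse complements if enabled); 'emittable' marks positions anchors may be
# reported from (forward text only); 'cap' bounds the reported word length;
# 'room' is the maximal match length before the segment ends; 'next_pos' is
# where the word minus its first character starts (for left-minimality).
# ---------------------------------------------------------------------------
.mus_corpus <- function(x, config) {
  segs <- list()
  add_seg <- function(text, countable_n, emittable, cap, next_pos) {
    segs[[length(segs) + 1L]] <<- list(text = text, countable_n = countable_n,
                                       emittable = emittable, cap = cap,
                                       next_pos = next_pos)
  }
  if (config$scope == "genome") {
    text <- x
    n <- nchar(text)
    if (config$circular) {
      cap <- rep.int(n, n)
      np <- (seq_len(n) %% n) + 1L
      add_seg(paste0(text, text), n, TRUE, cap, np)
      if (config$use_reverse_complement) {
        rc <- revcomp(text)
        add_seg(paste0(rc, rc), n, FALSE, NULL, NULL)
      }
    } else {
      cap <- n - seq_len(n) + 1L
      np <- c(seq_len(n)[-1L], NA_integer_)
      add_seg(text, n, TRUE, cap, np)
      if (config$use_reverse_complement) add_seg(revcomp(text), n, FALSE, NULL, NULL)
    }
    maxL <- n
  } else {
    reads <- x$seq
    for (s in reads) {
      len <- nchar(s)
      add_seg(s, len, TRUE, len - seq_len(len) + 1L, c(seq_len(len)[-1L], NA_integer_))
    }
    if (config$use_reverse_complement) {
      for (s in revcomp(reads)) add_seg(s, nchar(s), FALSE, NULL, NULL)
    }
    maxL <- max(nchar(reads))
  }

  chars <- character(0)
  countable <- logical(0)
  emittable <- logical(0)
  cap <- integer(0)
  room <- integer(0)
  next_pos <- integer(0)
  for (sg in segs) {
    off <- length(chars)
    sc <- strsplit(sg$text, "", fixed = TRUE)[[1]]
    slen <- length(sc)
    cnt <- c(rep(TRUE, sg$countable_n), rep(FALSE, slen - sg$countable_n))
    emt <- if (isTRUE(sg$emittable)) cnt else rep(FALSE, slen)
    cp <- rep.int(NA_integer_, slen)
    np <- rep.int(NA_integer_, slen)
    if (isTRUE(sg$emittable)) {
      cp[seq_len(sg$countable_n)] <- sg$cap
      np[seq_len(sg$countable_n)] <- sg$next_pos + off
    }
    rm_ <- slen - seq_len(slen) + 1L
    # sentinel after the segment
    chars <- c(chars, sc, "#")
    countable <- c(countable, cnt, FALSE)
    emittable <- c(emittable, emt, FALSE)
    cap <- c(cap, cp, NA_integer_)
    room <- c(room, rm_, 0L)
    next_pos <- c(next_pos, np, NA_integer_)
  }
  codes <- match(chars, c("A", "C", "G", "T"))
  sent <- which(is.na(codes))
  codes[sent] <- 4L + seq_along(sent)
  list(chars = chars, flat = paste(chars, collapse = ""), codes = codes,
       countable = countable, emittable = emittable, cap = cap, room = room,
       next_pos = next_pos, maxL = maxL)
}

.mus_backend_sa <- function(corpus) {
  su <- .sa_shortest_unique(corpus$codes, corpus$countable)
  cand <- which(corpus$emittable & !is.na(su) & su <= corpus$cap)
  if (!length(cand)) return(character(0))
  keep <- vapply(cand, function(i) {
    L <- su[i]
    if (L == 1L) return(TRUE)
    j <- corpus$next_pos[i]
    if (is.na(j)) return(FALSE)
    sj <- su[j]
    is.na(sj) || sj > L - 1L
  }, logical(1))
  cand <- cand[keep]
  substring(corpus$flat, cand, cand + su[cand] - 1L)
}

.mus_backend_bf <- function(corpus) {
  cidx <- which(corpus$countable)
  res <- character(0)
  prev_tab <- NULL
  for (L in seq_len(corpus$maxL)) {
    idx <- cidx[corpus$room[cidx] >= L]
    if (!length(idx)) break
    subs <- substring(corpus$flat, idx, idx + L - 1L)
    tab <- table(subs)
    uni <- names(tab)[tab == 1L]
    if (length(uni)) {
      pos <- idx[match(uni, subs)]
      ok <- corpus$emittable[pos] & !is.na(corpus$cap[pos]) & L <= corpus$cap[pos]
      if (L > 1L) {
        pre <- substr(uni, 1L, L - 1L)
        suf <- substr(uni, 2L, L)
        pc <- as.integer(prev_tab[pre])
        sc <- as.integer(prev_tab[suf])
        ok <- ok & !is.na(pc) & pc >= 2L & !is.na(sc) & sc >= 2L
      }
      res <- c(res, uni[ok])
    }
    if (!any(tab >= 2L)) break
    prev_tab <- tab
  }
  res
}

#' Extract minimum unique substrings (MUS anchors)
#'
#' A MUS is a substring that occurs exactly once in the uniqueness scope and is
#' minimal: removing its first character (left-minimality) or its last
#' character (right-minimality) yields a string that is no longer unique. MUSs
#' sit at the boundaries of maximal repeats, so the anchor set encodes repeat
#' structure without any fixed k-mer length.
#'
#' @param x A genome string (scope `"genome"`) or a [read_set()] (scope
#'   `"reads"`).
#' @param config A [uniqueness_config()].
#' @return An [anchor_set()] with words in lexicographic order.
#' @examples
#' # The 10 bp circular example genome:
#' extract_mus(toy_genome(), uniqueness_config("genome", circular = TRUE))$words
#' @export
extract_mus <- function(x, config = uniqueness_config()) {
  stopifnot(inherits(config, "uniqueness_config"))
  if (config$scope == "genome") {
    if (inherits(x, "read_set")) {
      stop("scope 'genome' expects a single string; pass the genome sequence")
    }
    x <- toupper(as.character(x))
    if (length(x) != 1L || is.na(x) || !nzchar(x)) stop("input text must be a non-empty string")
    if (grepl("[^ACGT]", x)) stop("input contains non-ACGT characters after sanitization")
  } else {
    if (is.character(x)) x <- sanitize_reads(x)
    if (!inherits(x, "read_set")) stop("scope 'reads' expects a read_set")
    if (nrow(x) == 0L) stop("read set is empty")
  }
  corpus <- .mus_corpus(x, config)
  words <- switch(config$backend,
    suffix_array = .mus_backend_sa(corpus),
    brute_force = .mus_backend_bf(corpus)
  )
  if (!length(words)) stop("no minimum unique substring exists in this scope")
  anchor_set(words, scope = config)
}

#' Count occurrences of a word in a text
#'
#' Counts distinct start positions where `word` matches `text`, including
#' overlapping matches. With `circular = TRUE` matches spanning the wrap point
#' are counted (start positions are taken modulo the text length). With
#' `use_rc = TRUE` occurrences of the reverse complement are added.
#'
#' @param text,word A/C/G/T strings.
#' @param circular Treat `text` as circular.
#' @param use_rc Also count the reverse complement of `word`.
#' @return Integer count. A word longer than a linear text yields 0.
#' @examples
#' count_occurrences("ATGCTAGCAC", "GC")  # 2
#' @export
count_occurrences <- function(text, word, circular = FALSE, use_rc = FALSE) {
  stopifnot(nchar(word) >= 1L)
  n <- nchar(text)
  L <- nchar(word)
  one <- function(w) {
    if (circular) {
      if (L > n) return(0L)
      t2 <- paste0(text, text)
      st <- seq_len(n)
      sum(substring(t2, st, st + L - 1L) == w)
    } else {
      if (L > n) return(0L)
      st <- seq_len(n - L + 1L)
      sum(substring(text, st, st + L - 1L) == w)
    }
  }
  cnt <- one(word)
  if (use_rc) cnt <- cnt + one(revcomp(word))
  as.integer(cnt)
}

#' Extract maximal repeats from a string
#'
#' A maximal repeat occurs at least twice and cannot be extended on either
#' side at all of its occurrences while remaining a repeat: its occurrences
#' are preceded by at least two distinct symbols (or a text boundary) and
#' followed by at least two distinct symbols (or a boundary).
#'
#' @param text A non-empty string over uppercase letters (DNA in practice;
#'   arbitrary letters are accepted for toy alphabets).
#' @return A data frame with columns `word`, `count` and a list column
#'   `positions` (1-based starts), sorted by decreasing length then word.
#' @examples
#' extract_maximal_repeats("ATGCTAGCAC")  # contains GC at positions 3 and 7
#' @export
extract_maximal_repeats <- function(text) {
  text <- toupper(as.character(text))
  if (length(text) != 1L || is.na(text) || !nzchar(text)) stop("input text must be a non-empty string")
  if (grepl("[^A-Z]", text)) stop("input contains non-letter characters")
  n <- nchar(text)
  out_word <- character(0)
  out_count <- integer(0)
  out_pos <- list()
  if (n >= 2L) {
    for (L in seq_len(n - 1L)) {
      starts <- seq_len(n - L + 1L)
      subs <- substring(text, starts, starts + L - 1L)
      tab <- table(subs)
      reps <- names(tab)[tab >= 2L]
      if (!length(reps)) break
      for (w in reps) {
        ps <- starts[subs == w]
        left <- ifelse(ps == 1L, "^", substring(text, ps - 1L, ps - 1L))
        right <- ifelse(ps + L - 1L == n, "$", substring(text, ps + L, ps + L))
        if (length(unique(left)) >= 2L && length(unique(right)) >= 2L) {
          out_word <- c(out_word, w)
          out_count <- c(out_count, length(ps))
          out_pos[[length(out_pos) + 1L]] <- ps
        }
      }
    }
  }
  ord <- order(-nchar(out_word), out_word, method = "radix")
  res <- data.frame(word = out_word[ord], count = out_count[ord],
                    stringsAsFactors = FALSE)
  res$positions <- out_pos[ord]
  res
}

#' Locate sorted anchor occurrences in one read
#'
#' Reports every exact match of every anchor in the read, sorted by start
#' position. Because no anchor nests inside another, at most one anchor starts
#' at any position, so the start order is total.
#'
#' @param read The read sequence (a string), or a list/one-row data frame with
#'   fields `id` and `seq`.
#' @param k Read index recorded in the output.
#' @param anchors An [anchor_set()].
#' @return A data frame with columns `word`, `read_index`, `start`, `end`
#'   (1-based, closed), sorted by `start`.
#' @examples
#' a <- extract_mus(toy_genome(), uniqueness_config("genome", circular = TRUE))
#' locate_occurrences("ATGCTA", 1, a)
#' @export
locate_occurrences <- function(read, k, anchors) {
  stopifnot(inherits(anchors, "anchor_set"), length(anchors$words) > 0L)
  seqc <- if (is.character(read)) read else read$seq
  seqc <- as.character(seqc)[1L]
  n <- nchar(seqc)
  words <- anchors$words
  res_word <- character(0)
  res_start <- integer(0)
  for (L in sort(unique(nchar(words)))) {
    if (L > n) next
    wl <- words[nchar(words) == L]
    st <- seq_len(n - L + 1L)
    subs <- substring(seqc, st, st + L - 1L)
    hit <- subs %in% wl
    res_word <- c(res_word, subs[hit])
    res_start <- c(res_start, st[hit])
  }
  ord <- order(res_start, method = "radix")
  data.frame(word = res_word[ord],
             read_index = rep.int(as.integer(k), length(res_word)),
             start = res_start[ord],
             end = res_start[ord] + nchar(res_word[ord]) - 1L,
             stringsAsFactors = FALSE)
}
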