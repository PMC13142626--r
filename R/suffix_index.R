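# Suffix-array machinery for minimum-unique-substring extraction.
#
# The index works on integer code vectors rather than characters so that
# per-segment sentinel symbols can be given unique codes: two suffixes then
# never match across a sentinel, which is what restricts candidate substrings
# to a single segment of a multi-segment corpus.

# Suffix array by prefix doubling: O(n log^2 n), pure R. The caller must make
# the last element a globally unique code so that all suffixes are distinct.
.sa_build <- function(codes) {
  n <- length(codes)
  if (n == 1L) return(1L)
  rank <- match(codes, sort(unique(codes)))
  k <- 1L
  repeat {
    key2 <- c(rank[-seq_len(min(k, n))], rep.int(0L, min(k, n)))
    ord <- order(rank, key2, method = "radix")
    r1 <- rank[ord]
    r2 <- key2[ord]
    newr <- cumsum(c(1L, as.integer(r1[-1L] != r1[-n] | r2[-1L] != r2[-n])))
    rank[ord] <- newr
    if (newr[n] == n) break
    k <- 2L * k
    if (k > 2L * n) stop("suffix sort failed to converge; corpus lacks a unique terminator")
  }
  order(rank, method = "radix")
}

# Kasai's algorithm: lcp[r] = longest common prefix of suffixes sa[r], sa[r+1].
.sa_lcp <- function(codes, sa) {
  n <- length(codes)
  if (n == 1L) return(integer(0))
  rank <- integer(n)
  rank[sa] <- seq_len(n)
  lcp <- integer(n - 1L)
  h <- 0L
  for (i in seq_len(n)) {
    r <- rank[i]
    if (r > 1L) {
      j <- sa[r - 1L]
      while (i + h <= n && j + h <= n && codes[i + h] == codes[j + h]) h <- h + 1L
      lcp[r - 1L] <- h
      if (h > 0L) h <- h - 1L
    } else {
      h <- 0L
    }
  }
  lcp
}

# Shortest unique-prefix length at every countable corpus position: the
# minimal L such that the length-L substring starting there occurs at exactly
# one countable start. Computed as 1 + the larger LCP with the nearest
# countable neighbours in suffix-array order (neighbour LCP = min over the
# LCP array between them).
.sa_shortest_unique <- function(codes, countable) {
  n <- length(codes)
  sa <- .sa_build(codes)
  lcp <- .sa_lcp(codes, sa)
  su <- rep.int(NA_integer_, n)
  prev_pos <- NA_integer_
  prev_lcp <- Inf   # running min of lcp since the last countable suffix
  best <- numeric(n) # max neighbour lcp per countable position
  for (r in seq_len(n)) {
    p <- sa[r]
    if (countable[p]) {
      if (!is.na(prev_pos)) {
        best[p] <- max(best[p], prev_lcp)
        best[prev_pos] <- max(best[prev_pos], prev_lcp)
      }
      prev_pos <- p
      prev_lcp <- Inf
    }
    if (r < n) prev_lcp <- min(prev_lcp, lcp[r])
  }
  idx <- which(countable)
  if (length(idx) == 1L) {
    su[idx] <- 1L
  } else {
    su[idx] <- as.integer(best[idx]) + 1L
  }
  su
}
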