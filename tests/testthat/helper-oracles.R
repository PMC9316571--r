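# Independent brute-force oracles and fixture builders. These deliberately
# take a different route than the package (grepl-based double loops over
# explicit substring enumeration) so agreement is meaningful.

# random RNA sequence set as a named character vector
randomSeqSet <- function(n, minLen = 17, maxLen = 27, prefix = "rnd-mir-") {
  lens <- sample(minLen:maxLen, n, replace = TRUE)
  seqs <- vapply(lens, function(L)
    paste(sample(c("A", "C", "G", "U"), L, replace = TRUE), collapse = ""),
    "")
  names(seqs) <- sprintf("%s%03d", prefix, seq_len(n))
  seqs
}

# does sequence s contain motif m? (single source of truth for oracles)
oracleHas <- function(s, m) grepl(m, s, fixed = TRUE)

# presence count of one motif across a set
oraclePresence <- function(seqs, m) {
  sum(vapply(seqs, oracleHas, logical(1), m = m))
}

# naive double-loop presence table of all k-mers
oracleMotifCounts <- function(seqs, k) {
  cand <- character(0)
  for (s in seqs) {
    n <- nchar(s)
    if (n >= k)
      for (i in seq_len(n - k + 1L))
        cand <- c(cand, substr(s, i, i + k - 1L))
  }
  cand <- unique(cand)
  counts <- vapply(cand, function(m) oraclePresence(seqs, m), 0L)
  counts[order(names(counts), method = "radix")]
}

# all substrings of all lengths >= kmin with presence >= m, plus maximality
# by direct extension recount
oracleMaximal <- function(seqs, m, kmin) {
  cand <- character(0)
  for (s in seqs) {
    n <- nchar(s)
    for (k in kmin:n)
      if (n >= k)
        for (i in seq_len(n - k + 1L))
          cand <- c(cand, substr(s, i, i + k - 1L))
  }
  cand <- unique(cand)
  counts <- vapply(cand, function(x) oraclePresence(seqs, x), 0L)
  keep <- counts >= m
  cand <- cand[keep]
  counts <- counts[keep]
  maximal <- vapply(cand, function(x) {
    ext <- c(paste0(c("A", "C", "G", "U"), x),
             paste0(x, c("A", "C", "G", "U")))
    all(vapply(ext, function(e) oraclePresence(seqs, e), 0L) < m)
  }, logical(1))
  data.frame(motif = cand, count = unname(counts),
             maximal = unname(maximal), row.names = NULL)
}

# build a synthetic family: each sequence contains `anchor` as a substring,
# padded with random flanks up to `len`
plantedFamily <- function(nMembers, anchor, len = 22, prefix = "fam-mir-") {
  k <- nchar(anchor)
  stopifnot(len >= k)
  seqs <- vapply(seq_len(nMembers), function(i) {
    pad <- len - k
    left <- sample(0:pad, 1L)
    paste0(
      paste(sample(c("A", "C", "G", "U"), left, replace = TRUE),
            collapse = ""),
      anchor,
      paste(sample(c("A", "C", "G", "U"), pad - left, replace = TRUE),
            collapse = "")
    )
  }, "")
  names(seqs) <- sprintf("%s%02d", prefix, seq_len(nMembers))
  seqs
}
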