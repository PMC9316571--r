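#' Length-distribution statistics of a miRNA sequence set
#'
#' Histogram of sequence lengths with mean, variance, median, all modal
#' lengths and the range. Mature miRNAs run 17-27 nt with a strong mode at
#' 22; these statistics summarise where a given set sits in that range.
#'
#' @param set named RNAStringSet or named character vector.
#' @param varianceMode `"population"` (default, divisor n) or `"sample"`
#'   (divisor n-1). A single-sequence set has variance 0 under both.
#' @return a [LengthStats-class]
#' @examples
#' lengthStats(c(a = "ACGUACGUACGUACGUACGUAC", b = "ACGUACGUACGUACGUACGUA"))
#' @export
lengthStats <- function(set, varianceMode = c("population", "sample")) {
  varianceMode <- match.arg(varianceMode)
  seqs <- .asSeqChar(set)
  len <- nchar(seqs)
  n <- length(len)
  tab <- table(len)
  lengths <- as.integer(names(tab))
  counts <- as.integer(tab)
  m <- mean(len)
  v <- sum((len - m)^2) / if (varianceMode == "population") n else max(n - 1L, 1L)
  new("LengthStats",
    histogram = data.frame(length = lengths, count = counts,
                           percentage = 100 * counts / n),
    mean = m, variance = v, median = median(len),
    modes = lengths[counts == max(counts)],
    min = min(len), max = max(len),
    varianceMode = varianceMode, setSize = n
  )
}

#' Per-position nucleotide composition (5' to 3')
#'
#' Tallies, for each position p = 1..Lmax, the p-th nucleotide of every
#' sequence with length >= p. With `denominator = "coverage"` (default)
#' percentages at position p are taken over the sequences that actually
#' reach p, so the 3' tail is not artificially deflated; with `"total"`
#' the full set size is the denominator at every position.
#'
#' @param set named RNAStringSet or named character vector.
#' @param denominator `"coverage"` or `"total"`.
#' @return a [PositionFrequencyMatrix-class]
#' @export
positionFrequency <- function(set, denominator = c("coverage", "total")) {
  denominator <- match.arg(denominator)
  seqs <- .asSeqChar(set)
  L <- max(nchar(seqs))
  counts <- matrix(0L, nrow = 4L, ncol = L,
                   dimnames = list(RNA_BASES, seq_len(L)))
  for (p in seq_len(L)) {
    nt <- substring(seqs[nchar(seqs) >= p], p, p)
    t <- table(factor(nt, levels = RNA_BASES))
    counts[, p] <- as.integer(t)
  }
  coverage <- colSums(counts)
  denom <- if (denominator == "coverage") coverage else
    rep(length(seqs), L)
  pct <- sweep(counts, 2L, denom, "/") * 100
  new("PositionFrequencyMatrix",
    counts = counts, percentages = pct,
    coverage = as.integer(coverage), denominator = denominator
  )
}

#' Overall nucleotide frequencies pooled across all positions
#'
#' @param set named RNAStringSet or named character vector.
#' @return named numeric (A, C, G, U) of percentages summing to 100.
#' @examples
#' globalNucleotideFrequency(c(x = "AU", y = "GC"))
#' @export
globalNucleotideFrequency <- function(set) {
  seqs <- .asSeqChar(set)
  nt <- unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE)
  t <- table(factor(nt, levels = RNA_BASES))
  setNames(100 * as.vector(t) / length(nt), RNA_BASES)
}

#' Per-miRNA purine/pyrimidine content profile
#'
#' Base counts and purine percentage 100*(A+G)/length for every sequence,
#' ranked by decreasing purine content (ties broken by id). Purine-rich and
#' purine-poor extremes are the biologically interesting tails.
#'
#' @param set named RNAStringSet or named character vector.
#' @return a [PurineProfile-class]; `as.data.frame()` gives the ranked
#'   table with raw (unrounded) percentages.
#' @examples
#' pp <- purineProfile(c("hsa-mir-765" = "UGGAGGAGAAGGAAGGUGAUG"))
#' as.data.frame(pp)$purinePercent  # 85.714...
#' @export
purineProfile <- function(set) {
  seqs <- .asSeqChar(set)
  cnt <- function(base) vapply(
    strsplit(seqs, "", fixed = TRUE),
    function(x) sum(x == base), 0L)
  A <- cnt("A"); G <- cnt("G"); C <- cnt("C"); U <- cnt("U")
  len <- nchar(seqs)
  pur <- 100 * (A + G) / len
  t <- data.frame(
    id = names(seqs), sequence = unname(seqs),
    A = A, G = G, C = C, U = U, length = len,
    purinePercent = pur, pyrimidinePercent = 100 - pur,
    row.names = NULL
  )
  t <- t[order(-t$purinePercent, t$id, method = "radix"), , drop = FALSE]
  rownames(t) <- NULL
  new("PurineProfile", table = t)
}
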