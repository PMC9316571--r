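## Exhaustive presence-based k-mer motif discovery.
##
## Presence semantics throughout: a sequence contributes at most 1 to a
## motif's count no matter how many (possibly overlapping) occurrences it
## holds. Motifs are literal 5'->3' substrings; no reverse complement.

# presence count of every k-mer observed in seqs (named integer vector)
.presenceCounts <- function(seqs, k) {
  uk <- lapply(seqs, function(s) unique(.kmers(s, k)))
  tab <- table(unlist(uk, use.names = FALSE))
  setNames(as.integer(tab), names(tab))
}

#' Count presence of all k-mers across a sequence set
#'
#' For a motif length `k`, lists every motif occurring in at least one
#' sequence with its presence count (number of distinct sequences
#' containing it at least once) and percentage of the set. Sequences
#' shorter than `k` contribute nothing. Rows are ordered by count
#' descending, then motif ascending (C locale).
#'
#' @param set named RNAStringSet or named character vector.
#' @param k motif length in nucleotides (>= 1).
#' @return a [MotifTable-class]
#' @examples
#' countMotifs(c(a = "CUGCUG", b = "ACUG"), k = 3)  # CUG counted once in a
#' @export
countMotifs <- function(set, k) {
  seqs <- .asSeqChar(set)
  k <- as.integer(k)
  if (is.na(k) || k < 1L) stop("k must be a positive integer")
  cnt <- .presenceCounts(seqs, k)
  if (length(cnt) == 0L) {
    tab <- data.frame(motif = character(0), count = integer(0),
                      percentage = numeric(0))
  } else {
    ord <- .orderCountMotif(cnt, names(cnt))
    tab <- data.frame(
      motif = names(cnt)[ord], count = unname(cnt[ord]),
      percentage = 100 * unname(cnt[ord]) / length(seqs),
      row.names = NULL
    )
  }
  new("MotifTable", k = k, table = tab, setSize = length(seqs))
}

#' Locate every occurrence of given motifs in a sequence set
#'
#' Records, per motif, each carrier sequence id with all (overlapping
#' included) 0-based start offsets. Presence counts derive from this index
#' but ignore multiplicity.
#'
#' @param set named RNAStringSet or named character vector.
#' @param motifList character vector of RNA motifs (any lengths).
#' @return a [MotifHitIndex-class]
#' @export
motifHitIndex <- function(set, motifList) {
  seqs <- .asSeqChar(set)
  if (length(motifList) == 0L) stop("motifList is empty")
  for (m in motifList) .validMotif(m)
  hits <- lapply(setNames(motifList, motifList), function(m) {
    occ <- lapply(seqs, .occurrences, motif = m)
    occ[lengths(occ) > 0L]
  })
  new("MotifHitIndex", hits = hits)
}

#' Motifs present in exactly one sequence
#'
#' @param table a [MotifTable-class]
#' @return lexicographically sorted character vector of singleton motifs
#' @export
uniqueMotifs <- function(table) {
  stopifnot(is(table, "MotifTable"))
  sort(table@table$motif[table@table$count == 1L], method = "radix")
}

#' Most- and least-detected strata of a motif table
#'
#' Splits a motif table into the "most detected" motifs (presence count
#' strictly greater than `minCount`) and the "least detected" ones (count
#' strictly less than `maxCount`). The bounds delimit disjoint strata, so
#' `minCount > maxCount` is the normal usage. Defaults follow the
#' conventional 4-mer cut at >70 / <10 sequences.
#'
#' @param table a [MotifTable-class]
#' @param minCount lower bound (exclusive) for the "most" stratum.
#' @param maxCount upper bound (exclusive) for the "least" stratum.
#' @return list with data.frames `most` and `least` (either may be empty),
#'   each ordered count descending then motif.
#' @export
thresholdReport <- function(table, minCount = 70, maxCount = 10) {
  stopifnot(is(table, "MotifTable"))
  t <- table@table
  list(most = t[t$count > minCount, , drop = FALSE],
       least = t[t$count < maxCount, , drop = FALSE])
}

#' Ids of sequences containing none of the given motifs
#'
#' Complements a motif list: which miRNAs escape all of them? Used to
#' quantify how much of a set the top motifs fail to cover.
#'
#' @param set named RNAStringSet or named character vector.
#' @param motifList non-empty character vector of RNA motifs.
#' @return character vector of record ids, in set order.
#' @export
sequencesWithoutMotifs <- function(set, motifList) {
  seqs <- .asSeqChar(set)
  if (length(motifList) == 0L) stop("motifList is empty")
  for (m in motifList) .validMotif(m)
  hit <- rep(FALSE, length(seqs))
  for (m in motifList) hit <- hit | grepl(m, seqs, fixed = TRUE)
  names(seqs)[!hit]
}

#' Maximal shared motifs at a support threshold
#'
#' Finds every motif (length >= `kmin`) present in at least `support`
#' sequences, and flags the maximal ones: motifs none of whose
#' single-nucleotide extensions (one base prepended or appended) still
#' reaches the support threshold. Computed by iterative k-deepening --
#' presence counts are anti-monotone under extension, so a (k+1)-mer can
#' reach support m only if both its k-length substrings do -- which makes
#' the search equivalent to exhaustive enumeration of all substrings.
#'
#' @param set named RNAStringSet or named character vector.
#' @param support support threshold m (>= 1; `support = 1` makes every full
#'   sequence maximal).
#' @param kmin smallest motif length to report (default 3).
#' @return a [MaximalMotifReport-class]; `motifs()` gives the maximal ones.
#' @examples
#' r <- maximalMotifs(c(a = "GAAAC", b = "UAAAG", c = "AAAUU"), support = 3)
#' motifs(r)  # "AAA"
#' @export
maximalMotifs <- function(set, support, kmin = 3) {
  seqs <- .asSeqChar(set)
  support <- as.integer(support)
  kmin <- as.integer(kmin)
  if (is.na(support) || support < 1L) stop("support must be >= 1")
  if (support > length(seqs))
    stop("support (", support, ") exceeds set size (", length(seqs), ")")
  if (is.na(kmin) || kmin < 1L) stop("kmin must be >= 1")
  levels <- list()
  k <- kmin
  repeat {
    cnt <- .presenceCounts(seqs, k)
    cnt <- cnt[cnt >= support]
    if (length(cnt) == 0L) break
    levels[[as.character(k)]] <- cnt
    k <- k + 1L
  }
  rows <- lapply(names(levels), function(kk) {
    k <- as.integer(kk)
    cnt <- levels[[kk]]
    nxt <- levels[[as.character(k + 1L)]]
    extended <- if (is.null(nxt)) character(0) else
      c(substring(names(nxt), 1L, k), substring(names(nxt), 2L, k + 1L))
    ord <- .orderCountMotif(cnt, names(cnt))
    data.frame(
      motif = names(cnt)[ord], k = k, count = unname(cnt[ord]),
      maximal = !(names(cnt)[ord] %in% extended),
      row.names = NULL
    )
  })
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(motif = character(0), k = integer(0), count = integer(0),
               maximal = logical(0))
  new("MaximalMotifReport",
      support = support, kmin = kmin, table = tab,
      setSize = length(seqs))
}
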