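#' @import methods
#' @importFrom stats median runif setNames
#' @importFrom utils head read.table write.csv packageVersion
NULL

RNA_BASES <- c("A", "C", "G", "U")

# round-half-up at d decimals (reporting convention; raw values kept internally)
.round2 <- function(x, d = 2) floor(x * 10^d + 0.5) / 10^d

.isRnaString <- function(x) {
  nzchar(x) & !grepl("[^ACGU]", x)
}

# Coerce a sequence set (named RNAStringSet or named character vector) to a
# validated named character vector over {A,C,G,U}. All analysis funnels
# through this check so downstream code can assume a clean alphabet.
.asSeqChar <- function(set, what = "sequence set") {
  if (is(set, "XStringSet")) {
    seqs <- as.character(set)
  } else if (is.character(set)) {
    seqs <- set
  } else {
    stop(what, " must be an RNAStringSet or a named character vector")
  }
  if (length(seqs) == 0L)
    stop(what, " is empty; analysis requires at least one sequence")
  ids <- names(seqs)
  if (is.null(ids) || any(!nzchar(ids)))
    stop(what, " must have non-empty names (miRNA identifiers)")
  if (anyDuplicated(ids))
    stop(
      "duplicate ids in ", what, ": ",
      paste(unique(ids[duplicated(ids)]), collapse = ", ")
    )
  bad <- !.isRnaString(seqs)
  if (any(bad))
    stop(
      "non-RNA symbols (outside A/C/G/U) in: ",
      paste(head(ids[bad], 5L), collapse = ", ")
    )
  seqs
}

# all k-mers (with multiplicity, in positional order) of one sequence
.kmers <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(character(0))
  st <- seq_len(n - k + 1L)
  substring(s, st, st + k - 1L)
}

# 0-based start offsets of every (possibly overlapping) occurrence
.occurrences <- function(s, motif) {
  k <- nchar(motif)
  n <- nchar(s)
  if (n < k) return(integer(0))
  st <- seq_len(n - k + 1L)
  st[substring(s, st, st + k - 1L) == motif] - 1L
}

# deterministic C-locale ordering: count descending, motif ascending
.orderCountMotif <- function(count, motif) {
  order(-count, motif, method = "radix")
}

.validMotif <- function(motif) {
  if (!is.character(motif) || length(motif) != 1L || !.isRnaString(motif))
    stop("motif must be a single non-empty string over A/C/G/U: ",
         deparse(motif))
  invisible(motif)
}
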