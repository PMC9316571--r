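#' Summarize the target genes shared by carriers of one motif
#'
#' Finds the miRNAs of `set` containing `motif` (presence semantics, as in
#' [countMotifs()]), restricts to those with annotations in `map`, and
#' tabulates how many of them target each gene. The percentage is taken
#' over the annotated carriers, so a gene targeted by every annotated
#' carrier reports exactly 100. Carriers absent from the map are excluded
#' from the denominator and returned in the `unannotated` slot.
#'
#' @param set named RNAStringSet or named character vector.
#' @param map a [TargetMap-class].
#' @param motif RNA motif string.
#' @param minPercentage rows below this percentage are omitted (default 30,
#'   the conventional reporting cut for 7-mer target overlap tables).
#' @return a [TargetSummary-class]; rows sorted by gene frequency
#'   descending then gene symbol.
#' @examples
#' set <- c(m1 = "AACUGAA", m2 = "GGCUGAG", m3 = "UUCUGAU")
#' map <- targetMap(list(m1 = c("G1", "G2"), m2 = "G1", m3 = "G1"))
#' as.data.frame(summarizeTargets(set, map, "CUGA", minPercentage = 0))
#' @export
summarizeTargets <- function(set, map, motif, minPercentage = 30) {
  seqs <- .asSeqChar(set)
  stopifnot(is(map, "TargetMap"))
  .validMotif(motif)
  carriers <- names(seqs)[grepl(motif, seqs, fixed = TRUE)]
  annotated <- intersect(carriers, names(map@entries))
  unannotated <- setdiff(carriers, annotated)
  mf <- length(annotated)
  if (mf == 0L) {
    tab <- data.frame(gene = character(0), count = integer(0),
                      percentage = numeric(0))
  } else {
    genes <- unlist(map@entries[annotated], use.names = FALSE)
    t <- table(genes)
    cnt <- as.integer(t)
    pct <- 100 * cnt / mf
    keep <- pct >= minPercentage
    ord <- .orderCountMotif(cnt[keep], names(t)[keep])
    tab <- data.frame(
      gene = names(t)[keep][ord], count = cnt[keep][ord],
      percentage = pct[keep][ord], row.names = NULL
    )
  }
  new("TargetSummary",
      motif = motif, motifFrequency = mf, table = tab,
      unannotated = unannotated)
}

#' Summarize target overlap for several motifs
#'
#' Element-wise [summarizeTargets()] in stable input order.
#'
#' @inheritParams summarizeTargets
#' @param motifList character vector of RNA motifs (may be empty).
#' @return list of [TargetSummary-class], named by motif.
#' @export
batchSummarizeTargets <- function(set, map, motifList, minPercentage = 30) {
  res <- lapply(motifList, function(m)
    summarizeTargets(set, map, m, minPercentage = minPercentage))
  names(res) <- motifList
  res
}
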