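#' Group miRNAs sharing long anchor motifs
#'
#' Derives consensus groups from [maximalMotifs()]: each maximal motif of
#' length >= `minAnchorLen` carried by >= `minMembers` sequences defines a
#' group of its carriers, anchored on that motif. For each group the
#' shorter motif layers (k = 3..7) list every k-mer shared by all members;
#' by substring closure these include all length-k windows of the anchor
#' itself. Groups with identical member sets are merged under their longest
#' anchor (ties broken lexicographically), so the construction is
#' idempotent.
#'
#' @param set named RNAStringSet or named character vector.
#' @param minAnchorLen minimum anchor length (>= 5; default 8, below which
#'   shared substrings stop being family-specific in 17-27 nt sequences).
#' @param minMembers minimum carriers per group (>= 2).
#' @return list of [ConsensusGroup-class], ordered by decreasing anchor
#'   length then anchor string; empty list when no anchor qualifies.
#' @examples
#' fam <- c(m1 = "AAUUUAGAGGAC", m2 = "CCUUUAGAGGAU", m3 = "GGUUUAGAGGAA")
#' g <- buildConsensusGroups(fam, minAnchorLen = 8)
#' anchorMotif(g[[1]])
#' @export
buildConsensusGroups <- function(set, minAnchorLen = 8, minMembers = 2) {
  seqs <- .asSeqChar(set)
  minAnchorLen <- as.integer(minAnchorLen)
  minMembers <- as.integer(minMembers)
  if (minAnchorLen < 5L) stop("minAnchorLen must be >= 5")
  if (minMembers < 2L) stop("minMembers must be >= 2")
  if (minMembers > length(seqs))
    stop("minMembers exceeds set size (", length(seqs), ")")
  rep <- maximalMotifs(seqs, support = minMembers, kmin = minAnchorLen)
  anch <- rep@table
  if (nrow(anch) == 0L) return(list())

  # one candidate group per supported long motif; merging identical member
  # sets under the longest anchor keeps, for every carrier set, exactly its
  # longest shared motif (chance one-base extensions shared by a subset
  # spawn their own, smaller group instead of shadowing this one)
  cand <- lapply(anch$motif, function(a) {
    members <- names(seqs)[grepl(a, seqs, fixed = TRUE)]
    list(anchor = a, members = sort(members, method = "radix"))
  })
  key <- vapply(cand, function(g) paste(g$members, collapse = "\r"), "")
  merged <- lapply(split(cand, key), function(grp) {
    anchors <- vapply(grp, `[[`, "", "anchor")
    ord <- order(-nchar(anchors), anchors, method = "radix")
    grp[[ord[1L]]]
  })

  groups <- lapply(merged, function(g) {
    mem <- seqs[g$members]
    perK <- lapply(setNames(3:7, as.character(3:7)), function(k) {
      shared <- Reduce(intersect, lapply(mem, function(s) unique(.kmers(s, k))))
      sort(shared, method = "radix")
    })
    starts <- vapply(mem, function(s) .occurrences(s, g$anchor)[1L], 0L)
    new("ConsensusGroup",
      memberIds = g$members, anchorMotif = g$anchor, perKMotifs = perK,
      anchorIntervals = data.frame(
        id = g$members, start = unname(starts),
        end = unname(starts) + nchar(g$anchor), row.names = NULL
      )
    )
  })
  anchors <- vapply(groups, anchorMotif, "")
  groups <- groups[order(-nchar(anchors), anchors, method = "radix")]
  names(groups) <- NULL
  groups
}

#' Flatten consensus groups to a report table
#'
#' One row per (group, k, motif) with the 1-based anchor start in each
#' member, matching the 1..27 position convention of printed miRNA tables.
#'
#' @param groups list of [ConsensusGroup-class] from [buildConsensusGroups()]
#' @return data.frame with columns `group`, `anchor`, `members`, `k`,
#'   `motif`, `memberStarts` (1-based anchor starts, comma-separated).
#' @export
consensusTable <- function(groups) {
  if (length(groups) == 0L)
    return(data.frame(group = integer(0), anchor = character(0),
                      members = character(0), k = integer(0),
                      motif = character(0), memberStarts = character(0)))
  do.call(rbind, lapply(seq_along(groups), function(i) {
    g <- groups[[i]]
    rows <- do.call(rbind, lapply(3:7, function(k) {
      mot <- sharedMotifs(g, k)
      if (length(mot) == 0L) return(NULL)
      data.frame(k = k, motif = mot)
    }))
    data.frame(
      group = i, anchor = anchorMotif(g),
      members = paste(memberIds(g), collapse = ";"),
      k = rows$k, motif = rows$motif,
      memberStarts = paste(g@anchorIntervals$start + 1L, collapse = ";"),
      row.names = NULL
    )
  }))
}
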