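#' Per-species motif profiles
#'
#' Runs [countMotifs()] per species and motif length, producing the
#' profiles that [conservationMatrix()] compares.
#'
#' @param sets named list of sequence sets (names are the species labels;
#'   labels must be unique and non-empty).
#' @param ks motif lengths to profile (default `c(5, 6)`, the lengths at
#'   which short-RNA motifs stay comparable across distant species).
#' @return list of [SpeciesMotifProfile-class], one per species, in input
#'   order.
#' @export
buildProfiles <- function(sets, ks = c(5L, 6L)) {
  if (length(sets) == 0L) stop("no sequence sets supplied")
  labels <- names(sets)
  if (is.null(labels) || any(!nzchar(labels)))
    stop("every set needs a species label (list names)")
  if (anyDuplicated(labels))
    stop("duplicate species labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  lapply(setNames(labels, labels), function(sp) {
    seqs <- .asSeqChar(sets[[sp]], what = paste0("set '", sp, "'"))
    tabs <- lapply(setNames(as.integer(ks), as.character(ks)),
                   function(k) countMotifs(seqs, k))
    new("SpeciesMotifProfile",
        species = sp, setSize = length(seqs), tables = tabs)
  })
}

#' Cross-species motif conservation matrix
#'
#' Takes each species' top-n motifs per length (presence count descending,
#' motif ascending as tie-break) and tabulates them against each other:
#' rows are motifs appearing in at least one top list, cells hold the
#' presence percentage (rounded to 1 decimal) only where the motif is in
#' that species' top list, and `shared` flags motifs in at least two
#' species' lists; species-exclusive rows are retained with the flag
#' FALSE. Column order follows the input profile order; row content is
#' independent of it.
#'
#' @param profiles list of [SpeciesMotifProfile-class] from
#'   [buildProfiles()].
#' @param topN size of the per-species top list (default 15).
#' @return a [ConservationMatrix-class]
#' @export
conservationMatrix <- function(profiles, topN = 15) {
  if (length(profiles) == 0L) stop("no profiles supplied")
  topN <- as.integer(topN)
  if (is.na(topN) || topN < 1L) stop("topN must be >= 1")
  species <- vapply(profiles, function(p) p@species, "")
  ks <- names(profiles[[1L]]@tables)

  # per (species, k): the top-n motif list plus full percentage lookup
  tops <- lapply(profiles, function(p) {
    lapply(setNames(ks, ks), function(kk) {
      t <- p@tables[[kk]]@table
      head(t, topN)
    })
  })
  rows <- unique(do.call(rbind, lapply(seq_along(profiles), function(i) {
    do.call(rbind, lapply(ks, function(kk) {
      if (nrow(tops[[i]][[kk]]) == 0L) return(NULL)
      data.frame(motif = tops[[i]][[kk]]$motif, k = as.integer(kk))
    }))
  })))
  if (is.null(rows) || nrow(rows) == 0L)
    return(new("ConservationMatrix",
               cells = matrix(numeric(0), 0L, length(species),
                              dimnames = list(NULL, species)),
               motifInfo = data.frame(motif = character(0), k = integer(0),
                                      nSpecies = integer(0),
                                      shared = logical(0)),
               topN = topN))

  cells <- matrix(NA_real_, nrow(rows), length(species),
                  dimnames = list(rows$motif, species))
  for (i in seq_along(profiles)) {
    for (kk in ks) {
      t <- tops[[i]][[kk]]
      hit <- match(t$motif, rows$motif)
      cells[hit, i] <- .round2(t$percentage, 1)
    }
  }
  nSpecies <- as.integer(rowSums(!is.na(cells)))
  ord <- order(rows$k, -nSpecies, rows$motif, method = "radix")
  info <- data.frame(motif = rows$motif, k = rows$k, nSpecies = nSpecies,
                     shared = nSpecies >= 2L)[ord, , drop = FALSE]
  rownames(info) <- NULL
  new("ConservationMatrix",
      cells = cells[ord, , drop = FALSE], motifInfo = info, topN = topN)
}
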