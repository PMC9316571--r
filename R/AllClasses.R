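#' @importFrom S4Vectors metadata metadata<-
NULL

## Result containers are lightweight S4 classes: a data.frame payload with
## the defining parameters alongside, validity checks enforcing the
## invariants stated in the class docs, and show()/as.data.frame() methods.

#' Length-distribution statistics for a miRNA sequence set
#'
#' Produced by [lengthStats()]. Holds the length histogram (counts and
#' percentages), the mean, the variance (population or sample, as
#' requested), the median, all modal lengths, and the range.
#'
#' @slot histogram data.frame with columns `length`, `count`, `percentage`.
#' @slot mean,variance,median numeric scalars on raw (unrounded) lengths.
#' @slot modes integer vector of all lengths attaining the maximum count.
#' @slot min,max integer range of observed lengths.
#' @slot varianceMode `"population"` or `"sample"`.
#' @slot setSize number of sequences summarised.
#' @aliases LengthStats-class
#' @exportClass LengthStats
setClass("LengthStats",
  representation(
    histogram = "data.frame", mean = "numeric", variance = "numeric",
    median = "numeric", modes = "integer", min = "integer", max = "integer",
    varianceMode = "character", setSize = "integer"
  )
)

setValidity("LengthStats", function(object) {
  h <- object@histogram
  if (!all(c("length", "count", "percentage") %in% names(h)))
    return("histogram must have columns length, count, percentage")
  if (abs(sum(h$percentage) - 100) > 1e-6)
    return("histogram percentages must sum to 100")
  if (sum(h$count) != object@setSize)
    return("histogram counts must sum to set size")
  if (object@min > object@median || object@median > object@max)
    return("min <= median <= max violated")
  if (!all(h$count[match(object@modes, h$length)] == max(h$count)))
    return("every mode must attain the maximum count")
  TRUE
})

#' Per-position nucleotide composition of a sequence set
#'
#' Produced by [positionFrequency()]. Position 1 is the 5' end. Each
#' position p tallies the p-th nucleotide of every sequence long enough to
#' have one; `coverage` records that per-position denominator.
#'
#' @slot counts 4 x Lmax integer matrix (rows A, C, G, U).
#' @slot percentages 4 x Lmax numeric matrix (raw, unrounded).
#' @slot coverage integer vector, non-increasing in position.
#' @slot denominator `"coverage"` (per-position) or `"total"` (set size).
#' @aliases PositionFrequencyMatrix-class
#' @exportClass PositionFrequencyMatrix
setClass("PositionFrequencyMatrix",
  representation(
    counts = "matrix", percentages = "matrix", coverage = "integer",
    denominator = "character"
  )
)

setValidity("PositionFrequencyMatrix", function(object) {
  if (!identical(rownames(object@counts), RNA_BASES))
    return("count rows must be A, C, G, U")
  if (any(diff(object@coverage) > 0L))
    return("coverage must be non-increasing in position")
  if (object@denominator == "coverage" &&
      any(abs(colSums(object@percentages) - 100) > 1e-6))
    return("percentages must sum to 100 at every covered position")
  TRUE
})

#' Per-miRNA purine/pyrimidine content profile
#'
#' Produced by [purineProfile()]. One row per sequence with base counts and
#' purine percentage 100*(A+G)/length, ranked by decreasing purine content
#' (ties broken by id).
#'
#' @slot table data.frame with columns `id`, `sequence`, `A`, `G`, `C`, `U`,
#'   `length`, `purinePercent`, `pyrimidinePercent` (raw, unrounded).
#' @aliases PurineProfile-class
#' @exportClass PurineProfile
setClass("PurineProfile", representation(table = "data.frame"))

setValidity("PurineProfile", function(object) {
  t <- object@table
  if (!all(t$A + t$G + t$C + t$U == t$length))
    return("A+G+C+U must equal sequence length")
  if (any(abs(t$purinePercent + t$pyrimidinePercent - 100) > 1e-9))
    return("purinePercent + pyrimidinePercent must equal 100")
  TRUE
})

#' Presence-based k-mer motif table
#'
#' Produced by [countMotifs()]. For a fixed motif length `k`, maps every
#' motif observed in the set to its presence count (number of sequences
#' containing at least one occurrence; each sequence counted once) and the
#' corresponding percentage of the set. Motifs absent from every sequence
#' are not listed. Rows are ordered by count descending, motif ascending.
#'
#' @slot k motif length in nucleotides.
#' @slot table data.frame with columns `motif`, `count`, `percentage`.
#' @slot setSize number of sequences the table was computed over.
#' @aliases MotifTable-class
#' @exportClass MotifTable
setClass("MotifTable",
  representation(k = "integer", table = "data.frame", setSize = "integer")
)

setValidity("MotifTable", function(object) {
  t <- object@table
  if (nrow(t) > 0) {
    if (any(nchar(t$motif) != object@k) || any(!.isRnaString(t$motif)))
      return("all motifs must be length-k RNA strings")
    if (any(t$count < 1L) || any(t$count > object@setSize))
      return("presence counts must lie in [1, set size]")
  }
  TRUE
})

#' Index of motif occurrence offsets per sequence
#'
#' Produced by [motifHitIndex()]. Maps each motif to the carrier sequence
#' ids and every (possibly overlapping) 0-based start offset within them.
#'
#' @slot hits named list: motif -> named list (id -> integer offsets).
#' @aliases MotifHitIndex-class
#' @exportClass MotifHitIndex
setClass("MotifHitIndex", representation(hits = "list"))

#' Maximal shared motif report
#'
#' Produced by [maximalMotifs()]. Lists every motif of length >= `kmin`
#' whose presence count meets the support threshold; the `maximal` flag
#' marks motifs none of whose single-nucleotide extensions (left or right)
#' still meets the threshold.
#'
#' @slot support the support threshold m.
#' @slot kmin smallest motif length examined.
#' @slot table data.frame with columns `motif`, `k`, `count`, `maximal`.
#' @slot setSize number of sequences examined.
#' @aliases MaximalMotifReport-class
#' @exportClass MaximalMotifReport
setClass("MaximalMotifReport",
  representation(
    support = "integer", kmin = "integer", table = "data.frame",
    setSize = "integer"
  )
)

setValidity("MaximalMotifReport", function(object) {
  t <- object@table
  if (nrow(t) > 0 && any(t$count < object@support))
    return("every reported motif must meet the support threshold")
  TRUE
})

#' Group of miRNAs sharing a long anchor motif
#'
#' Produced by [buildConsensusGroups()]. Members all contain the anchor
#' motif; `perKMotifs` lays out, for k = 3..7, every k-mer shared by all
#' members (which includes every length-k substring of the anchor).
#'
#' @slot memberIds ids of the member sequences (>= 2).
#' @slot anchorMotif the longest motif shared by all members.
#' @slot perKMotifs named list `"3"`..`"7"` of shared k-mer vectors.
#' @slot anchorIntervals data.frame `id`, `start`, `end`: 0-based half-open
#'   interval of the leftmost anchor occurrence in each member.
#' @aliases ConsensusGroup-class
#' @exportClass ConsensusGroup
setClass("ConsensusGroup",
  representation(
    memberIds = "character", anchorMotif = "character",
    perKMotifs = "list", anchorIntervals = "data.frame"
  )
)

setValidity("ConsensusGroup", function(object) {
  if (length(object@memberIds) < 2L)
    return("a consensus group needs at least 2 members")
  iv <- object@anchorIntervals
  if (!identical(sort(iv$id), sort(object@memberIds)))
    return("anchorIntervals must cover exactly the member ids")
  if (any(iv$end - iv$start != nchar(object@anchorMotif)))
    return("anchor intervals must span the anchor length")
  TRUE
})

#' Validated miRNA-to-target-gene map
#'
#' Read by [readTargetMap()] (miRTarBase-style two-column export) or built
#' by [generateTargetMap()]. Gene sets are deduplicated per miRNA id.
#'
#' @slot entries named list: miRNA id -> character vector of gene symbols.
#' @slot provenance free-form list (e.g. the gene/motif coupling table of a
#'   synthetic map).
#' @aliases TargetMap-class
#' @exportClass TargetMap
setClass("TargetMap",
  representation(entries = "list", provenance = "list"),
  prototype(provenance = list())
)

setValidity("TargetMap", function(object) {
  e <- object@entries
  if (length(e) == 0L) return("target map has no entries")
  if (is.null(names(e)) || any(!nzchar(names(e))))
    return("entries must be named by miRNA id")
  if (any(vapply(e, function(g) any(!nzchar(g)) || anyDuplicated(g) > 0L,
                 logical(1))))
    return("gene sets must be deduplicated, non-empty symbols")
  TRUE
})

#' Target-gene overlap summary for one motif
#'
#' Produced by [summarizeTargets()]. `motifFrequency` counts the miRNAs of
#' the set that carry the motif and have target annotations; each gene row
#' gives how many of those miRNAs target it and the percentage thereof.
#' Carriers without annotations are listed in `unannotated`.
#'
#' @slot motif the motif summarised.
#' @slot motifFrequency number of annotated carriers (the denominator).
#' @slot table data.frame `gene`, `count`, `percentage` (raw).
#' @slot unannotated ids of carriers absent from the target map.
#' @aliases TargetSummary-class
#' @exportClass TargetSummary
setClass("TargetSummary",
  representation(
    motif = "character", motifFrequency = "integer", table = "data.frame",
    unannotated = "character"
  )
)

setValidity("TargetSummary", function(object) {
  t <- object@table
  if (nrow(t) > 0 && (any(t$count < 0L) || any(t$count > object@motifFrequency)))
    return("gene frequencies must lie in [0, motifFrequency]")
  TRUE
})

#' Per-species motif profile
#'
#' Produced by [buildProfiles()]: one [MotifTable-class] per requested k
#' for one species' miRNA set.
#'
#' @slot species species label.
#' @slot setSize number of miRNAs in that species' set.
#' @slot tables named list (as.character(k) -> MotifTable).
#' @aliases SpeciesMotifProfile-class
#' @exportClass SpeciesMotifProfile
setClass("SpeciesMotifProfile",
  representation(species = "character", setSize = "integer", tables = "list")
)

#' Cross-species motif conservation matrix
#'
#' Produced by [conservationMatrix()]. Rows are motifs appearing in at
#' least one species' top-n list; a cell is filled (with the presence
#' percentage, rounded to 1 decimal) only where the motif is in that
#' species' top-n list, and `motifInfo$shared` flags motifs in >= 2 lists.
#'
#' @slot cells motifs x species numeric matrix, NA where not in top list.
#' @slot motifInfo data.frame `motif`, `k`, `nSpecies`, `shared`.
#' @slot topN size of the per-species top list used.
#' @aliases ConservationMatrix-class
#' @exportClass ConservationMatrix
setClass("ConservationMatrix",
  representation(cells = "matrix", motifInfo = "data.frame", topN = "integer")
)

setValidity("ConservationMatrix", function(object) {
  if (nrow(object@cells) > 0 && any(rowSums(!is.na(object@cells)) < 1L))
    return("every row must have at least one filled cell")
  TRUE
})

#' Configuration for the synthetic miRNA set generator
#'
#' Build with [generatorConfig()]; consumed by [generateSet()].
#'
#' @slot nSequences number of sequences to generate.
#' @slot lengthDistribution named numeric: length -> probability.
#' @slot positionBias 4 x Lmax matrix (rows A, C, G, U) of per-position
#'   nucleotide sampling weights; columns normalised to sum to 1.
#' @slot plantedMotifs list of `list(motif=, prevalence=, policy=)`.
#' @slot seed integer RNG seed.
#' @aliases GeneratorConfig-class
#' @exportClass GeneratorConfig
setClass("GeneratorConfig",
  representation(
    nSequences = "integer", lengthDistribution = "numeric",
    positionBias = "matrix", plantedMotifs = "list", seed = "integer"
  )
)

setValidity("GeneratorConfig", function(object) {
  ld <- object@lengthDistribution
  if (is.null(names(ld)) || any(is.na(as.integer(names(ld)))))
    return("lengthDistribution must be named by integer lengths")
  if (any(ld < 0) || abs(sum(ld) - 1) > 1e-6)
    return("length probabilities must be non-negative and sum to 1")
  if (object@nSequences < 1L) return("nSequences must be >= 1")
  if (!identical(rownames(object@positionBias), RNA_BASES))
    return("positionBias rows must be A, C, G, U")
  minLen <- min(as.integer(names(ld))[ld > 0])
  for (pm in object@plantedMotifs) {
    if (!all(c("motif", "prevalence", "policy") %in% names(pm)))
      return("each planted motif needs motif, prevalence, policy")
    if (!.isRnaString(pm$motif)) return("planted motifs must be RNA strings")
    if (pm$prevalence < 0 || pm$prevalence > 1)
      return("prevalence must lie in [0, 1]")
    if (nchar(pm$motif) > minLen)
      return("planted motif longer than the shortest generatable sequence")
    if (!pm$policy %in% c("uniform", "seed_region"))
      return("placement policy must be 'uniform' or 'seed_region'")
  }
  TRUE
})

#' Ground truth of a synthetic sequence set
#'
#' Returned by [generateSet()] beside the sequences: the exact carrier ids
#' and 0-based insertion offsets of every planted motif, so recovery can be
#' scored without re-deriving it.
#'
#' @slot ids all generated sequence ids.
#' @slot carriers named list: motif -> data.frame `id`, `offset`.
#' @aliases SyntheticTruth-class
#' @exportClass SyntheticTruth
setClass("SyntheticTruth",
  representation(ids = "character", carriers = "list")
)
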