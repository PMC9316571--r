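## Accessors, coercions and show() methods for the result classes.

#' @describeIn MotifTable-class number of sequences counted over
#' @param x,object a MotifTable
#' @export
setMethod("setSize", "MotifTable", function(x) x@setSize)

#' @describeIn MotifTable-class motif strings, table order
#' @export
setMethod("motifs", "MotifTable", function(x) x@table$motif)

#' @describeIn MotifTable-class presence counts, table order
#' @export
setMethod("presenceCounts", "MotifTable", function(x) x@table$count)

#' @describeIn MotifTable-class rows as a data.frame (`motif`, `count`,
#'   `percentage`; percentages raw)
#' @param row.names,optional,... passed on conventionally, unused
#' @export
setMethod("as.data.frame", "MotifTable",
  function(x, row.names = NULL, optional = FALSE, ...) x@table)

setMethod("show", "MotifTable", function(object) {
  cat(sprintf("MotifTable: %d distinct %d-mers over %d sequences\n",
              nrow(object@table), object@k, object@setSize))
  if (nrow(object@table) > 0) {
    top <- head(object@table, 5L)
    top$percentage <- .round2(top$percentage)
    print(top, row.names = FALSE)
    if (nrow(object@table) > 5L) cat("...\n")
  }
})

#' @describeIn MaximalMotifReport-class number of sequences examined
#' @param x,object a MaximalMotifReport
#' @export
setMethod("setSize", "MaximalMotifReport", function(x) x@setSize)

#' @describeIn MaximalMotifReport-class motifs flagged maximal
#' @export
setMethod("motifs", "MaximalMotifReport",
  function(x) x@table$motif[x@table$maximal])

#' @describeIn MaximalMotifReport-class counts of the maximal motifs
#' @export
setMethod("presenceCounts", "MaximalMotifReport",
  function(x) x@table$count[x@table$maximal])

#' @describeIn MaximalMotifReport-class all supported rows (`motif`, `k`,
#'   `count`, `maximal`)
#' @param row.names,optional,... passed on conventionally, unused
#' @export
setMethod("as.data.frame", "MaximalMotifReport",
  function(x, row.names = NULL, optional = FALSE, ...) x@table)

setMethod("show", "MaximalMotifReport", function(object) {
  cat(sprintf(
    "MaximalMotifReport: support >= %d, k >= %d; %d supported motifs (%d maximal) over %d sequences\n",
    object@support, object@kmin, nrow(object@table),
    sum(object@table$maximal), object@setSize))
})

#' @describeIn LengthStats-class number of sequences summarised
#' @param x,object a LengthStats
#' @export
setMethod("setSize", "LengthStats", function(x) x@setSize)

#' @describeIn LengthStats-class the length histogram as a data.frame
#' @param row.names,optional,... passed on conventionally, unused
#' @export
setMethod("as.data.frame", "LengthStats",
  function(x, row.names = NULL, optional = FALSE, ...) x@histogram)

setMethod("show", "LengthStats", function(object) {
  cat(sprintf(
    "LengthStats over %d sequences: mean %.2f, %s variance %.2f, median %g, mode%s %s, range %d-%d\n",
    object@setSize, object@mean, object@varianceMode, object@variance,
    object@median, if (length(object@modes) > 1) "s" else "",
    paste(object@modes, collapse = ","), object@min, object@max))
})

#' @describeIn PositionFrequencyMatrix-class long-format data.frame with
#'   columns `position`, `base`, `count`, `percentage`, `coverage`
#' @param x,row.names,optional,... a PositionFrequencyMatrix; rest unused
#' @export
setMethod("as.data.frame", "PositionFrequencyMatrix",
  function(x, row.names = NULL, optional = FALSE, ...) {
    L <- ncol(x@counts)
    data.frame(
      position = rep(seq_len(L), each = 4L),
      base = rep(RNA_BASES, L),
      count = as.vector(x@counts),
      percentage = as.vector(x@percentages),
      coverage = rep(x@coverage, each = 4L)
    )
  })

setMethod("show", "PositionFrequencyMatrix", function(object) {
  cat(sprintf(
    "PositionFrequencyMatrix: positions 1-%d (5'->3'), denominator = %s\n",
    ncol(object@counts), object@denominator))
})

#' @describeIn PurineProfile-class the ranked per-miRNA table
#' @param x,object,row.names,optional,... a PurineProfile; rest unused
#' @export
setMethod("as.data.frame", "PurineProfile",
  function(x, row.names = NULL, optional = FALSE, ...) x@table)

setMethod("show", "PurineProfile", function(object) {
  cat(sprintf("PurineProfile: %d miRNAs ranked by purine content (%%A+G)\n",
              nrow(object@table)))
  if (nrow(object@table) > 0) {
    t <- head(object@table[, c("id", "A", "G", "C", "U", "purinePercent")], 3L)
    t$purinePercent <- .round2(t$purinePercent)
    print(t, row.names = FALSE)
  }
})

#' @describeIn TargetMap-class miRNA ids with annotations
#' @param x,object a TargetMap
#' @export
setMethod("names", "TargetMap", function(x) names(x@entries))

#' @describeIn TargetMap-class number of annotated miRNA ids
#' @export
setMethod("length", "TargetMap", function(x) length(x@entries))

#' @describeIn TargetMap-class gene symbols annotated for `id`
#' @param id miRNA identifier
#' @export
setMethod("targetGenes", "TargetMap", function(x, id) {
  g <- x@entries[[id]]
  if (is.null(g)) character(0) else g
})

setMethod("show", "TargetMap", function(object) {
  cat(sprintf("TargetMap: %d miRNA ids, %d (id, gene) pairs\n",
              length(object@entries), sum(lengths(object@entries))))
})

#' @describeIn TargetSummary-class gene rows (`gene`, `count`, `percentage`)
#' @param x,object,row.names,optional,... a TargetSummary; rest unused
#' @export
setMethod("as.data.frame", "TargetSummary",
  function(x, row.names = NULL, optional = FALSE, ...) x@table)

setMethod("show", "TargetSummary", function(object) {
  cat(sprintf("TargetSummary for motif %s: %d annotated carriers, %d genes reported",
              object@motif, object@motifFrequency, nrow(object@table)))
  if (length(object@unannotated))
    cat(sprintf(" (%d carriers unannotated)", length(object@unannotated)))
  cat("\n")
})

#' @describeIn ConsensusGroup-class member ids
#' @param x,object a ConsensusGroup
#' @export
setMethod("memberIds", "ConsensusGroup", function(x) x@memberIds)

#' @describeIn ConsensusGroup-class the anchor motif
#' @export
setMethod("anchorMotif", "ConsensusGroup", function(x) x@anchorMotif)

#' @describeIn ConsensusGroup-class k-mers shared by all members
#' @param k motif length, 3..7
#' @export
setMethod("sharedMotifs", "ConsensusGroup", function(x, k) {
  stopifnot(k %in% 3:7)
  x@perKMotifs[[as.character(k)]]
})

setMethod("show", "ConsensusGroup", function(object) {
  cat(sprintf("ConsensusGroup: anchor %s (%d nt) shared by %d miRNAs: %s\n",
              object@anchorMotif, nchar(object@anchorMotif),
              length(object@memberIds),
              paste(object@memberIds, collapse = ", ")))
})

#' @describeIn SpeciesMotifProfile-class number of miRNAs in the species set
#' @param x,object a SpeciesMotifProfile
#' @export
setMethod("setSize", "SpeciesMotifProfile", function(x) x@setSize)

setMethod("show", "SpeciesMotifProfile", function(object) {
  cat(sprintf("SpeciesMotifProfile: %s (%d miRNAs), k = %s\n",
              object@species, object@setSize,
              paste(names(object@tables), collapse = ",")))
})

#' @describeIn ConservationMatrix-class motifs x species matrix plus the
#'   per-motif annotation columns `motif`, `k`, `nSpecies`, `shared`
#' @param x,object,row.names,optional,... a ConservationMatrix; rest unused
#' @export
setMethod("as.data.frame", "ConservationMatrix",
  function(x, row.names = NULL, optional = FALSE, ...) {
    cbind(x@motifInfo, as.data.frame(x@cells, check.names = FALSE))
  })

setMethod("show", "ConservationMatrix", function(object) {
  cat(sprintf(
    "ConservationMatrix: %d motifs x %d species (top-%d lists); %d motifs shared by >= 2 species\n",
    nrow(object@cells), ncol(object@cells), object@topN,
    sum(object@motifInfo$shared)))
})

setMethod("show", "GeneratorConfig", function(object) {
  cat(sprintf(
    "GeneratorConfig: %d sequences, lengths %s-%s, %d planted motif(s), seed %d\n",
    object@nSequences, min(names(object@lengthDistribution)),
    max(names(object@lengthDistribution)), length(object@plantedMotifs),
    object@seed))
})

setMethod("show", "SyntheticTruth", function(object) {
  cat(sprintf("SyntheticTruth: %d sequences; carriers per motif: %s\n",
              length(object@ids),
              if (length(object@carriers))
                paste(sprintf("%s=%d", names(object@carriers),
                              vapply(object@carriers, nrow, 0L)),
                      collapse = ", ")
              else "none"))
})
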