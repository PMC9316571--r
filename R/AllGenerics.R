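#' Number of sequences a result was computed over
#' @param x a result object
#' @return integer scalar
#' @export
setGeneric("setSize", function(x) standardGeneric("setSize"))

#' Motif strings listed in a result table
#' @param x a [MotifTable-class] or [MaximalMotifReport-class]
#' @return character vector in table order
#' @export
setGeneric("motifs", function(x) standardGeneric("motifs"))

#' Presence counts listed in a result table
#' @param x a [MotifTable-class] or [MaximalMotifReport-class]
#' @return integer vector parallel to [motifs()]
#' @export
setGeneric("presenceCounts", function(x) standardGeneric("presenceCounts"))

#' Member ids of a consensus group
#' @param x a [ConsensusGroup-class]
#' @return character vector
#' @export
setGeneric("memberIds", function(x) standardGeneric("memberIds"))

#' Anchor motif of a consensus group
#' @param x a [ConsensusGroup-class]
#' @return single string
#' @export
setGeneric("anchorMotif", function(x) standardGeneric("anchorMotif"))

#' Motifs of one length shared by all members of a consensus group
#' @param x a [ConsensusGroup-class]
#' @param k motif length, 3..7
#' @return character vector (sorted)
#' @export
setGeneric("sharedMotifs", function(x, k) standardGeneric("sharedMotifs"))

#' Target genes annotated for one miRNA id
#' @param x a [TargetMap-class]
#' @param id miRNA identifier
#' @return character vector of gene symbols (empty if id unannotated)
#' @export
setGeneric("targetGenes", function(x, id) standardGeneric("targetGenes"))
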