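#' Run the full structural-analysis pipeline and write CSV reports
#'
#' Binds all stages over one sequence set: composition (length histogram,
#' per-position composition, pooled nucleotide frequencies, purine
#' profile), presence-based motif tables for each requested k with
#' most/least-detected strata, maximal shared motifs, consensus groups,
#' and (when a target map is supplied) per-motif target overlap
#' summaries. Every table is written as CSV under `outputDir` together
#' with a `manifest.json` recording inputs, parameters and package
#' version; deterministic stages produce byte-identical outputs across
#' runs.
#'
#' @param input path to a FASTA file, or a named RNAStringSet / character
#'   vector.
#' @param outputDir directory for the reports (created if needed).
#' @param targetMap optional path to a two-column target-map file, or a
#'   [TargetMap-class].
#' @param targetMotifs motifs to summarise against the target map;
#'   default: the most-detected motif of each k in `ks`.
#' @param ks motif lengths to tabulate (default 3:7).
#' @param minCount,maxCount strata bounds for [thresholdReport()]
#'   (defaults 70 / 10).
#' @param support,kminMaximal support threshold and smallest length for
#'   [maximalMotifs()] (defaults 2 / 3).
#' @param minAnchorLen,minMembers consensus-group thresholds (defaults
#'   8 / 2).
#' @param minPercentage reporting cut for target summaries (default 30).
#' @param denominator positional denominator, `"coverage"` or `"total"`.
#' @param varianceMode `"population"` or `"sample"`.
#' @param raw write raw (unrounded) percentages instead of the 2-decimal
#'   reporting convention.
#' @param alphabetPolicy passed to [readMiRNAFasta()] when `input` is a
#'   path.
#' @param verbose log stage progress and input sizes via `message()`.
#' @return invisibly, a named character vector of written file paths.
#' @export
runPipeline <- function(input, outputDir,
                        targetMap = NULL, targetMotifs = NULL,
                        ks = 3:7, minCount = 70, maxCount = 10,
                        support = 2, kminMaximal = 3,
                        minAnchorLen = 8, minMembers = 2,
                        minPercentage = 30,
                        denominator = "coverage",
                        varianceMode = "population",
                        raw = FALSE,
                        alphabetPolicy = "coerce_dna",
                        verbose = TRUE) {
  say <- if (verbose) message else function(...) invisible(NULL)
  inputLabel <- if (is.character(input) && length(input) == 1L &&
                    file.exists(input)) {
    set <- readMiRNAFasta(input, alphabetPolicy = alphabetPolicy)
    basename(input)
  } else {
    set <- input
    "<in-memory>"
  }
  seqs <- .asSeqChar(set)
  if (!dir.exists(outputDir)) dir.create(outputDir, recursive = TRUE)
  fmt <- function(x, d = 2) if (raw) x else .round2(x, d)
  out <- character(0)
  emit <- function(df, name) {
    p <- file.path(outputDir, name)
    write.csv(df, p, row.names = FALSE, quote = FALSE)
    out[[name]] <<- p
  }
  say("compose: ", length(seqs), " sequences")
  ls <- lengthStats(seqs, varianceMode = varianceMode)
  h <- as.data.frame(ls)
  h$percentage <- fmt(h$percentage)
  emit(h, "lengths.csv")
  pf <- as.data.frame(positionFrequency(seqs, denominator = denominator))
  pf$percentage <- fmt(pf$percentage)
  emit(pf, "positions.csv")
  gf <- globalNucleotideFrequency(seqs)
  emit(data.frame(base = names(gf), percentage = fmt(unname(gf))),
       "nucleotide_frequency.csv")
  pp <- as.data.frame(purineProfile(seqs))
  pp$purinePercent <- fmt(pp$purinePercent)
  pp$pyrimidinePercent <- fmt(pp$pyrimidinePercent)
  emit(pp, "purine.csv")

  tables <- list()
  for (k in ks) {
    say("motifs: k = ", k)
    mt <- countMotifs(seqs, k)
    tables[[as.character(k)]] <- mt
    t <- as.data.frame(mt)
    t$percentage <- fmt(t$percentage)
    emit(t, sprintf("motifs_k%d.csv", k))
    strata <- thresholdReport(mt, minCount = minCount, maxCount = maxCount)
    s <- rbind(
      if (nrow(strata$most)) cbind(stratum = "most", strata$most),
      if (nrow(strata$least)) cbind(stratum = "least", strata$least)
    )
    if (!is.null(s)) {
      s$percentage <- fmt(s$percentage)
      emit(s, sprintf("motifs_k%d_strata.csv", k))
    }
  }

  say("maximal: support >= ", support)
  mm <- maximalMotifs(seqs, support = support, kmin = kminMaximal)
  emit(as.data.frame(mm), "maximal.csv")

  say("consensus: anchors >= ", minAnchorLen, " nt")
  groups <- buildConsensusGroups(seqs, minAnchorLen = minAnchorLen,
                                 minMembers = minMembers)
  emit(consensusTable(groups), "consensus.csv")

  if (!is.null(targetMap)) {
    map <- if (is(targetMap, "TargetMap")) targetMap else
      readTargetMap(targetMap)
    if (is.null(targetMotifs))
      targetMotifs <- unlist(lapply(tables, function(mt)
        head(motifs(mt), 1L)), use.names = FALSE)
    say("targets: ", length(targetMotifs), " motif(s)")
    sums <- batchSummarizeTargets(seqs, map, targetMotifs,
                                  minPercentage = minPercentage)
    rows <- do.call(rbind, lapply(sums, function(s) {
      t <- as.data.frame(s)
      if (nrow(t) == 0L) return(NULL)
      data.frame(motif = s@motif, motifFrequency = s@motifFrequency,
                 gene = t$gene, geneFrequency = t$count,
                 percentage = fmt(t$percentage))
    }))
    if (is.null(rows))
      rows <- data.frame(motif = character(0), motifFrequency = integer(0),
                         gene = character(0), geneFrequency = integer(0),
                         percentage = numeric(0))
    emit(rows, "targets.csv")
  }

  manifest <- list(
    package = "mirmotifs",
    version = as.character(packageVersion("mirmotifs")),
    input = inputLabel,
    nSequences = length(seqs),
    parameters = list(
      ks = as.integer(ks), minCount = minCount, maxCount = maxCount,
      support = support, kminMaximal = kminMaximal,
      minAnchorLen = minAnchorLen, minMembers = minMembers,
      minPercentage = minPercentage, denominator = denominator,
      varianceMode = varianceMode, raw = raw
    ),
    outputs = names(out)
  )
  mp <- file.path(outputDir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  out[["manifest.json"]] <- mp
  invisible(out)
}
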