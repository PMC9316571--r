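## Seeded generator of miRNA-like sequence sets, target maps and species
## panels, carrying the statistical structure the analysis stages assume:
## a length histogram concentrated at 21-23 nt, 5' adenine / 3' uracil
## positional bias, planted motifs at configurable prevalence, and target
## maps in which motif-sharing miRNAs share genes.

#' Default length distribution of the generator
#'
#' Concentrated at 21/22/23 nt with probabilities 0.198/0.498/0.135 (the
#' dominant bins of mature miRNA length histograms in myeloid-cancer
#' sets); the remaining mass tapers over 17-20 and 24-27 nt.
#'
#' @return named numeric vector of probabilities summing to 1.
#' @export
defaultLengthDistribution <- function() {
  c(`17` = 0.014, `18` = 0.020, `19` = 0.035, `20` = 0.075,
    `21` = 0.198, `22` = 0.498, `23` = 0.135,
    `24` = 0.015, `25` = 0.006, `26` = 0.002, `27` = 0.002)
}

#' Default per-position nucleotide bias of the generator
#'
#' Baseline frequencies follow the pooled composition of myeloid-cancer
#' miRNA sets (U most frequent at 27.8%, A least at 22.6%); adenine is
#' up-weighted at positions 1-3 (5' end) and uracil at positions >= 20
#' (3' tail).
#'
#' @param maxLen number of positions (columns), default 27.
#' @return 4 x `maxLen` matrix of sampling probabilities, rows A, C, G, U.
#' @export
defaultPositionBias <- function(maxLen = 27L) {
  base <- c(A = 0.226, C = 0.248, G = 0.248, U = 0.278)
  m <- matrix(rep(base, maxLen), nrow = 4L,
              dimnames = list(RNA_BASES, seq_len(maxLen)))
  m[, 1:3] <- c(A = 0.35, C = 0.20, G = 0.20, U = 0.25)
  if (maxLen >= 20L)
    m[, 20:maxLen] <- c(A = 0.18, C = 0.21, G = 0.21, U = 0.40)
  m
}

#' Build a generator configuration
#'
#' @param nSequences number of sequences (default 587, a typical
#'   disease-set size).
#' @param lengthDistribution named numeric, length -> probability
#'   (default [defaultLengthDistribution()]).
#' @param positionBias 4 x Lmax probability matrix, rows A/C/G/U (default
#'   [defaultPositionBias()] over the distribution's maximum length);
#'   columns are renormalised.
#' @param plantedMotifs list of `list(motif=, prevalence=, policy=)`;
#'   `policy` is `"uniform"` (any feasible offset) or `"seed_region"`
#'   (0-based offsets 1-7, the seed positions 2-8 of the mature miRNA).
#' @param seed integer RNG seed.
#' @return a validated [GeneratorConfig-class]
#' @export
generatorConfig <- function(nSequences = 587,
                            lengthDistribution = defaultLengthDistribution(),
                            positionBias = NULL,
                            plantedMotifs = list(),
                            seed = 1L) {
  maxLen <- max(as.integer(names(lengthDistribution)))
  if (is.null(positionBias)) positionBias <- defaultPositionBias(maxLen)
  if (ncol(positionBias) < maxLen)
    stop("positionBias must cover ", maxLen, " positions")
  positionBias <- sweep(positionBias, 2L, colSums(positionBias), "/")
  plantedMotifs <- lapply(plantedMotifs, function(pm) {
    if (is.null(pm$policy)) pm$policy <- "uniform"
    pm
  })
  new("GeneratorConfig",
      nSequences = as.integer(nSequences),
      lengthDistribution = lengthDistribution,
      positionBias = positionBias,
      plantedMotifs = plantedMotifs,
      seed = as.integer(seed))
}

#' Generate a synthetic miRNA sequence set with known ground truth
#'
#' Samples lengths from the configured histogram, draws background
#' nucleotides independently per position from the bias matrix, then
#' plants each configured motif: carriers are Bernoulli(prevalence) draws
#' per sequence, and the motif overwrites the sequence at a random
#' feasible offset (preserving the length distribution). The returned
#' truth records the exact carriers and offsets actually present -- when
#' several planted motifs are configured, a later plant can overwrite an
#' earlier one, and such evicted carriers are dropped from the truth.
#' Identical config (including seed) gives byte-identical output.
#'
#' @param config a [GeneratorConfig-class]
#' @return list with elements `set` (named [Biostrings::RNAStringSet],
#'   ids `syn-mir-0001`...) and `truth` (a [SyntheticTruth-class]).
#' @examples
#' gs <- generateSet(generatorConfig(nSequences = 20, seed = 42))
#' lengthStats(gs$set)
#' @export
generateSet <- function(config) {
  stopifnot(is(config, "GeneratorConfig"))
  validObject(config)
  n <- config@nSequences
  ld <- config@lengthDistribution
  bias <- config@positionBias
  withr::with_seed(config@seed, {
    lens <- as.integer(names(ld))[
      sample.int(length(ld), n, replace = TRUE, prob = ld)]
    maxLen <- max(as.integer(names(ld)))
    draws <- matrix("", n, maxLen)
    for (p in seq_len(maxLen))
      draws[, p] <- sample(RNA_BASES, n, replace = TRUE, prob = bias[, p])
    seqs <- vapply(seq_len(n), function(i)
      paste(draws[i, seq_len(lens[i])], collapse = ""), "")
    ids <- sprintf("syn-mir-%04d", seq_len(n))
    carriers <- list()
    for (pm in config@plantedMotifs) {
      k <- nchar(pm$motif)
      isCarrier <- runif(n) < pm$prevalence
      offs <- rep(NA_integer_, n)
      for (i in which(isCarrier)) {
        feasible <- 0:(lens[i] - k)
        if (identical(pm$policy, "seed_region"))
          feasible <- intersect(1:7, feasible)
        if (length(feasible) == 0L)
          stop("no feasible offset for motif ", pm$motif,
               " in a length-", lens[i], " sequence under policy ",
               pm$policy)
        off <- feasible[sample.int(length(feasible), 1L)]
        substr(seqs[i], off + 1L, off + k) <- pm$motif
        offs[i] <- off
      }
      carriers[[pm$motif]] <- data.frame(
        id = ids[isCarrier], offset = offs[isCarrier], row.names = NULL)
    }
    # later plants may have overwritten earlier ones: keep truth consistent
    for (m in names(carriers)) {
      cf <- carriers[[m]]
      ok <- vapply(seq_len(nrow(cf)), function(j) {
        s <- seqs[match(cf$id[j], ids)]
        substring(s, cf$offset[j] + 1L, cf$offset[j] + nchar(m)) == m
      }, logical(1))
      carriers[[m]] <- cf[ok, , drop = FALSE]
    }
    list(
      set = Biostrings::RNAStringSet(setNames(seqs, ids)),
      truth = new("SyntheticTruth", ids = ids, carriers = carriers)
    )
  })
}

#' Generate a target map coupled to planted motifs
#'
#' Emulates the structure of motif/target overlap tables: all carriers of
#' a planted motif tend to target the same genes. Each planted motif gets
#' `genesPerMotif` dedicated genes (named `<motif>_TG<i>`), and each
#' carrier targets each of them independently with probability
#' `coupling` -- so `coupling = 1` makes every coupled gene reach exactly
#' 100% in [summarizeTargets()]. `backgroundGenes` unlinked genes
#' (`BG<i>`) are assigned to every sequence independently with
#' probability 0.1.
#'
#' @param truth a [SyntheticTruth-class] from [generateSet()]
#' @param genesPerMotif dedicated genes per planted motif (default 6).
#' @param coupling probability in \[0, 1\] that a carrier targets each of
#'   its motif's genes (default 1).
#' @param backgroundGenes number of unlinked background genes (default 0).
#' @param seed integer RNG seed.
#' @return a [TargetMap-class]; its `provenance$geneCoupling` data.frame
#'   records which gene belongs to which motif (NA for background genes).
#' @export
generateTargetMap <- function(truth, genesPerMotif = 6, coupling = 1,
                              backgroundGenes = 0, seed = 1L) {
  stopifnot(is(truth, "SyntheticTruth"))
  if (genesPerMotif < 0) stop("genesPerMotif must be >= 0")
  if (coupling < 0 || coupling > 1) stop("coupling must lie in [0, 1]")
  withr::with_seed(as.integer(seed), {
    pairsId <- character(0)
    pairsGene <- character(0)
    coupled <- data.frame(gene = character(0), motif = character(0))
    for (m in names(truth@carriers)) {
      ids <- truth@carriers[[m]]$id
      if (genesPerMotif == 0 || length(ids) == 0L) next
      genes <- sprintf("%s_TG%d", m, seq_len(genesPerMotif))
      coupled <- rbind(coupled, data.frame(gene = genes, motif = m))
      for (g in genes) {
        hit <- ids[runif(length(ids)) < coupling]
        pairsId <- c(pairsId, hit)
        pairsGene <- c(pairsGene, rep(g, length(hit)))
      }
    }
    if (backgroundGenes > 0) {
      bg <- sprintf("BG%03d", seq_len(backgroundGenes))
      coupled <- rbind(coupled,
                       data.frame(gene = bg, motif = NA_character_))
      for (g in bg) {
        hit <- truth@ids[runif(length(truth@ids)) < 0.1]
        pairsId <- c(pairsId, hit)
        pairsGene <- c(pairsGene, rep(g, length(hit)))
      }
    }
    if (length(pairsId) == 0L)
      stop("generated target map is empty; raise coupling, genesPerMotif ",
           "or backgroundGenes")
    entries <- lapply(split(pairsGene, pairsId),
                      function(g) sort(unique(g)))
    entries <- entries[order(names(entries), method = "radix")]
    map <- new("TargetMap", entries = entries,
               provenance = list(geneCoupling = coupled))
    map
  })
}

#' Generate a labeled multi-species panel of synthetic sets
#'
#' Produces `nSpecies` sets from `baseConfig`, all sharing the given
#' planted motifs; for species index i (0-based), each shared motif's
#' prevalence is scaled by `max(0, 1 - divergence * i)`, so later species
#' carry the motifs at decreasing rates, emulating conservation decay.
#'
#' @param baseConfig a [GeneratorConfig-class]; its own `plantedMotifs`
#'   are replaced by `sharedMotifs`.
#' @param nSpecies number of species (>= 2).
#' @param sharedMotifs list of `list(motif=, prevalence=)` (optionally
#'   `policy=`); may be empty.
#' @param divergence per-species prevalence decay in \[0, 1\] (default 0).
#' @param seed integer; species i uses seed `seed + i`.
#' @return named list (`species1`...) of [Biostrings::RNAStringSet]; each
#'   carries its [SyntheticTruth-class] in `S4Vectors::metadata(x)$truth`
#'   and its label in `metadata(x)$species`.
#' @export
generateSpeciesPanel <- function(baseConfig, nSpecies, sharedMotifs = list(),
                                 divergence = 0, seed = 1L) {
  stopifnot(is(baseConfig, "GeneratorConfig"))
  nSpecies <- as.integer(nSpecies)
  if (is.na(nSpecies) || nSpecies < 2L) stop("nSpecies must be >= 2")
  if (divergence < 0 || divergence > 1)
    stop("divergence must lie in [0, 1]")
  panel <- lapply(seq_len(nSpecies), function(i) {
    scale <- max(0, 1 - divergence * (i - 1L))
    pm <- lapply(sharedMotifs, function(s) {
      s$prevalence <- s$prevalence * scale
      if (is.null(s$policy)) s$policy <- "uniform"
      s
    })
    cfg <- generatorConfig(
      nSequences = baseConfig@nSequences,
      lengthDistribution = baseConfig@lengthDistribution,
      positionBias = baseConfig@positionBias,
      plantedMotifs = pm,
      seed = as.integer(seed) + i
    )
    gs <- generateSet(cfg)
    S4Vectors::metadata(gs$set)$species <- paste0("species", i)
    S4Vectors::metadata(gs$set)$truth <- gs$truth
    gs$set
  })
  names(panel) <- paste0("species", seq_len(nSpecies))
  panel
}
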