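test_that("identical config and seed give byte-identical FASTA", {
  cfg <- generatorConfig(nSequences = 40, seed = 3,
                         plantedMotifs = list(list(motif = "AAGUGC",
                                                   prevalence = 0.5)))
  f1 <- withr::local_tempfile(fileext = ".fa")
  f2 <- withr::local_tempfile(fileext = ".fa")
  writeMiRNAFasta(generateSet(cfg)$set, f1)
  writeMiRNAFasta(generateSet(cfg)$set, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  # different seed differs
  cfg2 <- generatorConfig(nSequences = 40, seed = 4)
  expect_false(identical(as.character(generateSet(cfg)$set),
                         as.character(generateSet(cfg2)$set)))
})

test_that("truth records carriers whose motif is verifiably in place", {
  gs <- generateSet(generatorConfig(
    nSequences = 80, seed = 21,
    plantedMotifs = list(list(motif = "GUGCUUC", prevalence = 0.4),
                         list(motif = "UUUAGAG", prevalence = 0.3))))
  seqs <- setNames(as.character(gs$set), names(gs$set))
  for (m in names(gs$truth@carriers)) {
    cf <- gs$truth@carriers[[m]]
    for (j in seq_len(nrow(cf)))
      expect_identical(
        substring(seqs[[cf$id[j]]], cf$offset[j] + 1,
                  cf$offset[j] + nchar(m)), m)
  }
})

test_that("prevalence 1 plants the motif in every sequence", {
  gs <- generateSet(generatorConfig(
    nSequences = 50, seed = 5,
    plantedMotifs = list(list(motif = "AAGUGC", prevalence = 1))))
  expect_true(all(grepl("AAGUGC", as.character(gs$set), fixed = TRUE)))
  expect_equal(nrow(gs$truth@carriers[["AAGUGC"]]), 50L)
})

test_that("degenerate length distribution fixes every length", {
  gs <- generateSet(generatorConfig(nSequences = 30, seed = 6,
                                    lengthDistribution = c(`22` = 1)))
  expect_true(all(Biostrings::width(gs$set) == 22L))
})

test_that("the default distribution concentrates lengths at 21-23", {
  gs <- generateSet(generatorConfig(nSequences = 500, seed = 8))
  len <- Biostrings::width(gs$set)
  expect_true(all(len >= 17 & len <= 27))
  core <- mean(len %in% 21:23)
  expect_gt(core, 0.831 - 3 * sqrt(0.831 * 0.169 / 500))
  ls <- lengthStats(gs$set)
  expect_equal(ls@median, 22)
  expect_true(22L %in% ls@modes)
})

test_that("positional bias shows 5' adenine and 3' uracil enrichment", {
  gs <- generateSet(generatorConfig(nSequences = 400, seed = 9))
  pf <- positionFrequency(gs$set)
  expect_gt(mean(pf@percentages["A", 1:3]), mean(pf@percentages["A", 10:18]))
  expect_gt(mean(pf@percentages["U", 20:27]), mean(pf@percentages["U", 10:18]))
})

test_that("seed-region policy confines offsets to 1..7", {
  gs <- generateSet(generatorConfig(
    nSequences = 60, seed = 10,
    plantedMotifs = list(list(motif = "AGUGCUU", prevalence = 0.8,
                              policy = "seed_region"))))
  off <- gs$truth@carriers[["AGUGCUU"]]$offset
  expect_true(all(off >= 1 & off <= 7))
})

test_that("infeasible configs are rejected up front", {
  expect_error(generatorConfig(
    nSequences = 10, lengthDistribution = c(`17` = 1),
    plantedMotifs = list(list(motif = strrep("A", 18), prevalence = 1))),
    "longer")
  expect_error(generatorConfig(
    nSequences = 10,
    plantedMotifs = list(list(motif = "ACGU", prevalence = 1.5))),
    "prevalence")
  expect_error(generatorConfig(nSequences = 10,
                               lengthDistribution = c(`22` = 0.6)),
               "sum to 1")
})

test_that("target-map coupling hits its binomial expectation", {
  gs <- generateSet(generatorConfig(
    nSequences = 250, seed = 33,
    plantedMotifs = list(list(motif = "GCGCGCA", prevalence = 0.8))))
  nCarrier <- nrow(gs$truth@carriers[["GCGCGCA"]])
  map <- generateTargetMap(gs$truth, genesPerMotif = 4, coupling = 0.9,
                           seed = 34)
  s <- summarizeTargets(gs$set, map, "GCGCGCA", minPercentage = 0)
  t <- as.data.frame(s)
  tol <- 3 * sqrt(0.9 * 0.1 / nCarrier) * 100
  for (g in sprintf("GCGCGCA_TG%d", 1:4))
    expect_lt(abs(t$percentage[t$gene == g] - 90), tol)
  # coupling 0 with no background genes cannot produce a map
  expect_error(generateTargetMap(gs$truth, coupling = 0, seed = 1), "empty")
})

test_that("species panels scale planted prevalence by divergence", {
  panel <- generateSpeciesPanel(
    generatorConfig(nSequences = 200), nSpecies = 3,
    sharedMotifs = list(list(motif = "GCAAUGC", prevalence = 0.6)),
    divergence = 0.5, seed = 44)
  expect_identical(names(panel), c("species1", "species2", "species3"))
  frac <- vapply(panel, function(s)
    mean(grepl("GCAAUGC", as.character(s), fixed = TRUE)), 0)
  p <- 0.6 * c(1, 0.5, 0)
  tol <- 3 * sqrt(pmax(p * (1 - p), 0.25 * 0.75) / 200) + 0.05
  expect_true(all(abs(frac - p) < tol))
  # truth travels with each labeled set
  expect_s4_class(S4Vectors::metadata(panel$species1)$truth,
                  "SyntheticTruth")
  expect_error(generateSpeciesPanel(generatorConfig(nSequences = 5), 1),
               "nSpecies")
})
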