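test_that("presence semantics count each sequence once", {
  mt <- countMotifs(c(a = "CUGCUG", b = "ACUG"), k = 3)
  t <- as.data.frame(mt)
  expect_equal(t$count[t$motif == "CUG"], 2L)   # two occurrences in a, one hit
  expect_equal(t$percentage[t$motif == "CUG"], 100)
  expect_identical(t$motif[1], "CUG")           # count-descending order

  short <- countMotifs(c(a = "AU"), k = 3)
  expect_equal(nrow(as.data.frame(short)), 0L)

  expect_error(countMotifs(c(a = "ACGU"), k = 0), "positive")
  expect_error(countMotifs(character(0), k = 3), "empty")
})

test_that("motif tables agree with the naive double-loop oracle", {
  withr::with_seed(101, {
    for (case in 1:12) {
      seqs <- randomSeqSet(sample(3:25, 1), minLen = 8, maxLen = 27)
      k <- sample(3:8, 1)
      mt <- as.data.frame(countMotifs(seqs, k))
      oracle <- oracleMotifCounts(seqs, k)
      expect_identical(sort(mt$motif, method = "radix"), names(oracle))
      expect_identical(mt$count[match(names(oracle), mt$motif)],
                       unname(oracle))
    }
  })
})

test_that("presence counts are anti-monotone under motif extension", {
  withr::with_seed(77, {
    seqs <- randomSeqSet(30)
    for (k in 3:6) {
      tk <- as.data.frame(countMotifs(seqs, k))
      tk1 <- as.data.frame(countMotifs(seqs, k + 1))
      parentPrefix <- tk$count[match(substr(tk1$motif, 1, k), tk$motif)]
      parentSuffix <- tk$count[match(substring(tk1$motif, 2), tk$motif)]
      expect_true(all(tk1$count <= parentPrefix))
      expect_true(all(tk1$count <= parentSuffix))
      # loose global sanity bound on total presence mass
      expect_lte(sum(tk$count),
                 length(seqs) * (max(nchar(seqs)) - k + 1))
    }
  })
})

test_that("unique motifs are exactly the singletons", {
  mt <- countMotifs(c(a = "AAAC", b = "AAAG"), k = 3)
  expect_identical(uniqueMotifs(mt), c("AAC", "AAG"))
  all2 <- countMotifs(c(a = "AAA", b = "AAA"), k = 3)
  expect_identical(uniqueMotifs(all2), character(0))
  withr::with_seed(31, {
    seqs <- randomSeqSet(30, minLen = 10)
    um <- uniqueMotifs(countMotifs(seqs, 5))
    oracle <- oracleMotifCounts(seqs, 5)
    expect_identical(um, names(oracle)[oracle == 1L])
  })
})

test_that("threshold strata are strict filters of the table", {
  withr::with_seed(41, {
    seqs <- randomSeqSet(40, minLen = 12)
    mt <- countMotifs(seqs, 3)
    r <- thresholdReport(mt, minCount = 20, maxCount = 5)
    t <- as.data.frame(mt)
    expect_identical(r$most$motif, t$motif[t$count > 20])
    expect_identical(r$least$motif, t$motif[t$count < 5])
    # most stratum empty when the bound equals the set size
    expect_equal(nrow(thresholdReport(mt, minCount = 40)$most),
                 sum(t$count > 40))
  })
})

test_that("sequences without motifs are found by substring scan", {
  expect_identical(
    sequencesWithoutMotifs(c(a = "AAAA", b = "CUGA"), "CUG"), "a")
  # motifs covering every 3-mer of a sequence exclude it
  s <- c(x = "ACGUA")
  expect_identical(
    sequencesWithoutMotifs(s, c("ACG", "CGU", "GUA")), character(0))
  expect_error(sequencesWithoutMotifs(s, character(0)), "empty")
  expect_error(sequencesWithoutMotifs(s, "ACT"), "motif")

  withr::with_seed(55, {
    seqs <- randomSeqSet(40)
    motifList <- c("CUG", "AAGU", "GGG")
    got <- sequencesWithoutMotifs(seqs, motifList)
    oracle <- names(seqs)[vapply(seqs, function(s)
      !any(vapply(motifList, oracleHas, logical(1), s = s)), logical(1))]
    expect_identical(got, oracle)
  })
})

test_that("planted-motif complement rate matches its prevalence", {
  gs <- generateSet(generatorConfig(
    nSequences = 200, seed = 99,
    plantedMotifs = list(list(motif = "ACGCGCA", prevalence = 0.6))))
  missing <- sequencesWithoutMotifs(gs$set, "ACGCGCA")
  carrier <- gs$truth@carriers[["ACGCGCA"]]$id
  expect_identical(sort(missing), sort(setdiff(names(gs$set), carrier)))
})

test_that("maximal motifs match brute force on small sets", {
  r <- maximalMotifs(c(a = "GAAAC", b = "UAAAG", c = "AAAUU"),
                     support = 3, kmin = 3)
  expect_identical(motifs(r), "AAA")
  expect_identical(presenceCounts(r), 3L)

  withr::with_seed(61, {
    for (case in 1:8) {
      seqs <- randomSeqSet(sample(4:10, 1), minLen = 8, maxLen = 14)
      m <- sample(2:3, 1)
      got <- as.data.frame(maximalMotifs(seqs, support = m, kmin = 3))
      oracle <- oracleMaximal(seqs, m, 3)
      ord <- order(oracle$motif, method = "radix")
      got <- got[order(got$motif, method = "radix"), ]
      expect_identical(got$motif, oracle$motif[ord])
      expect_identical(got$count, oracle$count[ord])
      expect_identical(got$maximal, oracle$maximal[ord])
    }
  })
})

test_that("support 1 makes each full sequence maximal", {
  seqs <- c(a = "ACGUACG", b = "GGGCCCA")
  r <- as.data.frame(maximalMotifs(seqs, support = 1, kmin = 3))
  maxed <- r$motif[r$maximal]
  expect_setequal(maxed, unname(seqs))
  expect_error(maximalMotifs(seqs, support = 3), "exceeds set size")
})

test_that("a 20-mer planted in seven members is recovered at support 7", {
  withr::with_seed(70, {
    fam <- plantedFamily(7, "AAAGUGCUUCCCUUUAGAGU", len = 24)
    r <- as.data.frame(maximalMotifs(fam, support = 7, kmin = 3))
    row <- r[r$motif == "AAAGUGCUUCCCUUUAGAGU", ]
    expect_equal(nrow(row), 1L)
    expect_equal(row$count, 7L)
  })
})

test_that("motif hit index records every overlapping occurrence 0-based", {
  idx <- motifHitIndex(c(a = "AAAA", b = "CAAC"), c("AA", "CA"))
  expect_identical(idx@hits[["AA"]][["a"]], c(0L, 1L, 2L))
  expect_identical(idx@hits[["AA"]][["b"]], 1L)
  expect_identical(idx@hits[["CA"]][["b"]], 0L)
  expect_null(idx@hits[["CA"]][["a"]])
  # offsets always in [0, len - k]
  withr::with_seed(83, {
    seqs <- randomSeqSet(20)
    idx <- motifHitIndex(seqs, c("CUG", "AGUGC"))
    for (m in names(idx@hits))
      for (id in names(idx@hits[[m]])) {
        off <- idx@hits[[m]][[id]]
        expect_true(all(off >= 0 & off <= nchar(seqs[[id]]) - nchar(m)))
        expect_true(all(substring(seqs[[id]], off + 1,
                                  off + nchar(m)) == m))
      }
  })
})
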