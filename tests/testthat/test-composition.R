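test_that("length statistics handle symmetric sets, ties and singletons", {
  set <- c(a = strrep("A", 27), b = strrep("C", 27),
           c = strrep("G", 26), d = strrep("U", 26))
  ls <- lengthStats(set)
  expect_equal(ls@mean, 26.5)
  expect_equal(ls@median, 26.5)
  expect_setequal(ls@modes, c(26L, 27L))

  one <- c(solo = "ACGUACGU")
  expect_equal(lengthStats(one, "population")@variance, 0)
  expect_equal(lengthStats(one, "sample")@variance, 0)

  expect_error(lengthStats(character(0)), "empty")
})

test_that("population and sample variance differ by the n/(n-1) factor", {
  withr::with_seed(3, {
    set <- randomSeqSet(40)
    vp <- lengthStats(set, "population")@variance
    vs <- lengthStats(set, "sample")@variance
    expect_equal(vs, vp * 40 / 39)
  })
})

test_that("length histogram covers observed lengths and sums to set size", {
  withr::with_seed(5, {
    set <- randomSeqSet(60)
    h <- as.data.frame(lengthStats(set))
    expect_setequal(h$length, sort(unique(nchar(set))))
    expect_equal(sum(h$count), 60L)
    expect_equal(sum(h$percentage), 100)
  })
})

test_that("positional composition matches the stated examples", {
  pf <- positionFrequency(c(x = "AU", y = "AG"))
  expect_equal(pf@percentages["A", 1], 100)
  expect_equal(pf@percentages["U", 2], 50)
  expect_equal(pf@percentages["G", 2], 50)

  pf2 <- positionFrequency(c(x = "A", y = "AU"), denominator = "coverage")
  expect_equal(pf2@percentages["U", 2], 100)
  expect_equal(pf2@coverage, c(2L, 1L))

  pf3 <- positionFrequency(c(x = "A", y = "AU"), denominator = "total")
  expect_equal(pf3@percentages["U", 2], 50)
})

test_that("positional matrix equals an independent per-position tally", {
  withr::with_seed(8, {
    set <- randomSeqSet(50)
    pf <- positionFrequency(set)
    for (p in c(1, 5, 18, max(nchar(set)))) {
      reach <- set[nchar(set) >= p]
      for (b in c("A", "C", "G", "U")) {
        expect_identical(
          pf@counts[b, p],
          sum(substr(reach, p, p) == b),
          info = sprintf("base %s at position %d", b, p))
      }
    }
    # coverage non-increasing; percentages sum to 100 at covered positions
    expect_true(all(diff(pf@coverage) <= 0))
    expect_equal(unname(colSums(pf@percentages)),
                 rep(100, ncol(pf@percentages)))
  })
})

test_that("global nucleotide frequencies pool all positions", {
  expect_equal(unname(globalNucleotideFrequency(c(x = "AAAA"))["A"]), 100)
  gf <- globalNucleotideFrequency(c(x = "AU", y = "GC"))
  expect_equal(unname(gf), rep(25, 4))
})

test_that("global frequencies equal the coverage-weighted positional aggregate", {
  withr::with_seed(13, {
    set <- randomSeqSet(45)
    gf <- globalNucleotideFrequency(set)
    pf <- positionFrequency(set)
    agg <- 100 * rowSums(pf@counts) / sum(pf@counts)
    expect_equal(gf, agg)
  })
})

test_that("purine profile reproduces printed base counts and ranking", {
  pp <- purineProfile(c(
    "hsa-mir-765"  = "UGGAGGAGAAGGAAGGUGAUG",
    "hsa-mir-1281" = "UCGCCUCCUCCUCUCCC",
    "low"          = "CCCC"
  ))
  t <- as.data.frame(pp)
  expect_identical(t$id, c("hsa-mir-765", "hsa-mir-1281", "low"))
  r765 <- t[t$id == "hsa-mir-765", ]
  expect_equal(unlist(r765[c("A", "G", "C", "U")]),
               c(A = 7, G = 11, C = 0, U = 3))
  expect_equal(round(r765$purinePercent, 2), 85.71)
  expect_equal(round(t$purinePercent[t$id == "hsa-mir-1281"], 2), 5.88)
  expect_equal(t$purinePercent[t$id == "low"], 0)
  expect_equal(t$pyrimidinePercent[t$id == "low"], 100)
})

test_that("purine + pyrimidine percentages are exactly complementary", {
  withr::with_seed(21, {
    t <- as.data.frame(purineProfile(randomSeqSet(40)))
    expect_equal(t$purinePercent + t$pyrimidinePercent, rep(100, 40))
    expect_true(all(t$A + t$G + t$C + t$U == t$length))
    # ranking is descending with id tie-break
    expect_true(all(diff(t$purinePercent) <= 1e-12))
  })
})
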