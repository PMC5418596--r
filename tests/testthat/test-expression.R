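test_that("RPKM follows its definition and scales correctly", {
  expect_equal(computeRpkm(10, 1000, 1e6), 10)
  expect_equal(computeRpkm(0, 500, 1e6), 0)
  expect_equal(computeRpkm(50, 2000, 1e7), 2.5)
  ## linear in count, inverse in library total
  expect_equal(computeRpkm(30, 700, 2e6), 3 * computeRpkm(10, 700, 2e6))
  expect_equal(computeRpkm(10, 700, 4e6), computeRpkm(10, 700, 2e6) / 2)
  ## NOT invariant under joint scaling of count and total
  expect_false(isTRUE(all.equal(computeRpkm(20, 700, 4e6),
                                computeRpkm(10, 700, 2e6) * 2)))
  expect_equal(computeRpkm(20, 700, 4e6), computeRpkm(10, 700, 2e6))
})

test_that("the DE Fisher test contrasts locus vs rest-of-library", {
  expect_equal(deTest(0, 0, 100, 100), 1)
  expect_equal(deTest(2, 0, 4, 2), fisherExactTwoSided(2, 2, 0, 2),
               tolerance = 1e-15)
  expect_equal(deTest(2, 0, 4, 2), oracleFisherEnum(2, 2, 0, 2),
               tolerance = 1e-12)
  expect_equal(deTest(7, 7, 1000, 1000), 1)  # symmetric counts, equal totals
})

deCounts <- function(wt1, mut1, wt2 = wt1, mut2 = mut1, total = 1e6,
                     nOther = 60) {
  withr::with_seed(2, other <- matrix(rpois(nOther * 4, 50), nOther))
  m <- rbind(c(wt1, mut1, wt2, mut2), other)
  dimnames(m) <- list(c("target", paste0("bg", seq_len(nOther))),
                      c("wt1", "mut1", "wt2", "mut2"))
  LocusCounts(m, lengths = rep(1000, nOther + 1), libSizes = rep(total, 4))
}

dePairs <- list(c(wt = "wt1", mut = "mut1"), c(wt = "wt2", mut = "mut2"))

test_that("a log2 ratio of exactly 2 is not called up (strict threshold)", {
  x <- deCounts(wt1 = 999L, mut1 = 3999L)   # (3999+1)/(999+1) = 4 exactly
  calls <- callDifferential(x, dePairs)
  tgt <- calls[calls$locus == "target", ]
  expect_equal(tgt$log2.1, 2)
  expect_lt(tgt$fdr.1, 0.01)               # significant, but ratio not > 2
  expect_equal(tgt$finalCall, "unchanged")

  x2 <- deCounts(wt1 = 999L, mut1 = 4100L)  # ratio just above 4
  calls2 <- callDifferential(x2, dePairs)
  expect_equal(calls2[calls2$locus == "target", "finalCall"], "up")
})

test_that("final calls are the intersection across replicate pairs", {
  ## up in pair 1 only -> final unchanged
  x <- deCounts(wt1 = 100L, mut1 = 2000L, wt2 = 100L, mut2 = 110L)
  calls <- callDifferential(x, dePairs)
  tgt <- calls[calls$locus == "target", ]
  expect_equal(tgt$call.1, "up")
  expect_equal(tgt$call.2, "unchanged")
  expect_equal(tgt$finalCall, "unchanged")

  ## final call set is a subset of each per-pair call set
  withr::with_seed(17, {
    m <- matrix(rpois(400, 80) * sample(c(1L, 8L), 400, TRUE), 100)
    dimnames(m) <- list(paste0("l", 1:100), c("wt1", "mut1", "wt2", "mut2"))
    lc <- LocusCounts(m, lengths = rep(1500, 100), libSizes = rep(1e6, 4))
    calls <- callDifferential(lc, dePairs)
    final <- calls$finalCall != "unchanged"
    expect_true(all(calls$call.1[final] == calls$finalCall[final]))
    expect_true(all(calls$call.2[final] == calls$finalCall[final]))
  })
})

test_that("down calls are symmetric to up calls", {
  x <- deCounts(wt1 = 3999L, mut1 = 799L)  # (800)/(4000) = 1/5 < 1/4
  calls <- callDifferential(x, dePairs)
  expect_equal(calls[calls$locus == "target", "finalCall"], "down")
})

test_that("windowed log2 track recomputes per-window mean RPKM ratios", {
  loci <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(c(10e3, 40e3, 150e3, 160e3), width = 2000))
  m <- matrix(c(100L, 50L, 30L, 30L,      # wt1
                100L, 50L, 30L, 30L,      # mut1 identical
                100L, 50L, 30L, 30L,
                100L, 50L, 30L, 30L), ncol = 4,
              dimnames = list(paste0("l", 1:4),
                              c("wt1", "mut1", "wt2", "mut2")))
  lc <- LocusCounts(m, lengths = rep(2000, 4), libSizes = rep(1e6, 4))
  tr <- windowedLog2Track(loci, lc, c("wt1", "wt2"), c("mut1", "mut2"),
                          chromLengths = c(chr1 = 3e5))
  expect_equal(tr$log2Ratio[tr$nLoci > 0], c(0, 0))
  expect_true(all(is.na(tr$log2Ratio[tr$nLoci == 0])))

  ## one window with mutant mean 4x the wild type -> exactly 2
  m2 <- m; m2[, c("mut1", "mut2")] <- m[, c("wt1", "wt2")] * 4L
  lc2 <- LocusCounts(m2, lengths = rep(2000, 4), libSizes = rep(1e6, 4))
  tr2 <- windowedLog2Track(loci, lc2, c("wt1", "wt2"), c("mut1", "mut2"),
                           chromLengths = c(chr1 = 3e5))
  expect_equal(tr2$log2Ratio[tr2$nLoci > 0], c(2, 2))

  ## random fixture vs brute-force per-window recomputation
  withr::with_seed(25, {
    n <- 40
    starts <- sample(1:28e4, n)
    loci <- GenomicRanges::GRanges("chr1", IRanges::IRanges(starts, width = 999))
    cts <- matrix(rpois(n * 4, 60), n,
                  dimnames = list(paste0("g", 1:n),
                                  c("wt1", "mut1", "wt2", "mut2")))
    lc <- LocusCounts(cts, lengths = rep(999, n), libSizes = rep(2e6, 4))
    tr <- windowedLog2Track(loci, lc, c("wt1", "wt2"), c("mut1", "mut2"),
                            chromLengths = c(chr1 = 3e5))
    rpkm <- apply(cts, 2, function(cl) cl / (999 / 1000) / 2)
    mid <- floor((starts + starts + 998) / 2)
    for (w in seq_len(nrow(tr))) {
      i <- mid >= tr$start[w] & mid <= tr$end[w]
      if (!any(i)) { expect_true(is.na(tr$log2Ratio[w])); next }
      ref <- log2(mean(rowMeans(rpkm[i, c("mut1", "mut2"), drop = FALSE])) /
                    mean(rowMeans(rpkm[i, c("wt1", "wt2"), drop = FALSE])))
      expect_equal(tr$log2Ratio[w], ref, tolerance = 1e-12)
    }
  })
})

test_that("compartment enrichment matches the one-sample z formula", {
  mkGr <- function(comp) {
    g <- GenomicRanges::GRanges("chr1",
      IRanges::IRanges(seq_along(comp) * 1000, width = 100))
    S4Vectors::mcols(g)$compartment <- comp
    g
  }
  bg <- mkGr(rep(c("pericentromeric_het", "euchromatin"), c(20, 80)))
  sub <- mkGr(rep(c("pericentromeric_het", "euchromatin"), c(50, 50)))
  r <- compartmentEnrichment(sub, bg)
  expect_equal(r$z, 7.5)                      # (0.5-0.2)/sqrt(0.2*0.8/100)
  expect_equal(r$pValue, 2 * pnorm(-7.5))

  same <- compartmentEnrichment(bg, bg)       # subset = background
  expect_equal(same$z, 0)
  expect_equal(same$pValue, 1)

  expect_error(compartmentEnrichment(bg[0], bg), "empty")
})
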