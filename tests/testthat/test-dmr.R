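# small helpers to build matched smoothed methylomes by hand
twoTrack <- function(pos, methW, unmethW, methM, unmethM,
                     chrom = "chr1", context = "CG") {
  list(wt = makeSmoothed("WT", chrom, context, pos, methW, unmethW),
       mut = makeSmoothed("mut", chrom, context, pos, methM, unmethM))
}

test_that("callDmcs applies the Fisher test and strict rate-difference rule", {
  tk <- twoTrack(pos = c(100, 200, 300),
                 methW = c(10, 5, 10), unmethW = c(0, 5, 0),
                 methM = c(0, 5, 10), unmethM = c(10, 5, 0))
  dmcs <- callDmcs(tk$wt, tk$mut)
  ## pos 100: WT fully methylated, mut fully unmethylated -> hypo-DMC
  expect_equal(nrow(dmcs), 1L)
  expect_equal(dmcs$pos, 100)
  expect_equal(dmcs$type, "hypo")
  expect_equal(dmcs$diff, -1)
  expect_equal(dmcs$pValue, 2 / choose(20, 10), tolerance = 1e-12)

  ## a rate difference of exactly 0.08 never qualifies, however significant:
  ## WT rate 0.50, mut rate 0.58 at large smoothed counts
  tk2 <- twoTrack(pos = 1, methW = 5000, unmethW = 5000,
                  methM = 5800, unmethM = 4200)
  expect_equal(nrow(callDmcs(tk2$wt, tk2$mut)), 0L)
  ## and a difference of exactly the threshold 0.1 is excluded (strict >)
  tk3 <- twoTrack(pos = 1, methW = 5000, unmethW = 5000,
                  methM = 6000, unmethM = 4000)
  expect_equal(nrow(callDmcs(tk3$wt, tk3$mut)), 0L)
})

test_that("cytosines with undefined rate in either genotype are skipped", {
  tk <- twoTrack(pos = c(10, 20), methW = c(0, 10), unmethW = c(0, 0),
                 methM = c(0, 0), unmethM = c(10, 10))
  dmcs <- callDmcs(tk$wt, tk$mut)
  expect_equal(dmcs$pos, 20)
})

test_that("rounding of smoothed counts happens before the DMC test", {
  ## smoothed counts 2.5/0.4 vs 0.4/2.5 round (half away from zero) to
  ## 3/0 vs 0/3 -> p = 1/10; unrounded-count tests would differ
  tk <- twoTrack(pos = 1, methW = 2.5, unmethW = 0.4,
                 methM = 0.4, unmethM = 2.5)
  dmcs <- callDmcs(tk$wt, tk$mut, DmcParams(pMax = 0.2))
  expect_equal(dmcs$pValue, fisherExactTwoSided(0, 3, 3, 0),
               tolerance = 1e-12)
  expect_equal(dmcs$pValue, 1 / 10, tolerance = 1e-12)
})

mkDmcs <- function(pos, type, context = "CG", chrom = "chr1") {
  data.frame(chrom = chrom, pos = pos, context = context, type = type,
             pValue = 0.01, rateWT = 0.8, rateMut = 0.3, diff = -0.5)
}

test_that("DMC merging follows gap ceilings and opposite-type blocking", {
  ## CG gaps 100 and 80 both <= 160 -> one region with 3 DMCs
  r <- mergeDmcs(mkDmcs(c(100, 200, 280), "hypo"))
  expect_equal(nrow(r), 1L)
  expect_equal(c(r$start, r$end, r$nDmcs), c(100, 280, 3))

  ## an intervening hyper-DMC blocks the hypo chain
  r <- mergeDmcs(mkDmcs(c(100, 150, 220), c("hypo", "hyper", "hypo")))
  expect_equal(nrow(r), 3L)
  expect_true(all(r$nDmcs == 1L))
  expect_equal(r$type, c("hypo", "hyper", "hypo"))

  ## CHH gap of exactly 71 exceeds the 70 bp ceiling
  r <- mergeDmcs(mkDmcs(c(100, 171), "hypo", context = "CHH"))
  expect_equal(nrow(r), 2L)
  r <- mergeDmcs(mkDmcs(c(100, 170), "hypo", context = "CHH"))
  expect_equal(nrow(r), 1L)

  expect_error(mergeDmcs(mkDmcs(c(200, 100), "hypo")), "sorted")
})

test_that("merging matches the brute-force region constructor", {
  withr::with_seed(21, {
    for (rep in 1:200) {
      n <- sample(1:6, 1)
      pos <- sort(sample(1:500, n))
      type <- sample(c("hypo", "hyper"), n, replace = TRUE)
      cx <- sample(c("CG", "CHG", "CHH"), 1)
      got <- mergeDmcs(mkDmcs(pos, type, context = cx))
      ref <- oracleMerge(pos, type, MergeParams()@maxGap[[cx]])
      expect_equal(nrow(got), length(ref))
      expect_equal(got$start, unname(vapply(ref, `[[`, numeric(1), "start")))
      expect_equal(got$end, unname(vapply(ref, `[[`, numeric(1), "end")))
      expect_equal(got$nDmcs, unname(vapply(ref, `[[`, numeric(1), "n")))
      expect_equal(got$type, unname(vapply(ref, `[[`, character(1), "type")))
    }
  })
})

test_that("region test averages, rounds, and tests the region counts", {
  ## two cytosines averaging to (4.5, 5.5) in WT; rounding -> (5, 6)
  tk <- twoTrack(pos = c(100, 150),
                 methW = c(4, 5), unmethW = c(5, 6),
                 methM = c(9, 10), unmethM = c(1, 0))
  region <- data.frame(chrom = "chr1", start = 100, end = 150,
                       context = "CG", type = "hyper", nDmcs = 2L)
  r <- testRegions(region, tk$wt, tk$mut)
  expect_equal(r$pValue, fisherExactTwoSided(10, 1, 5, 6), tolerance = 1e-12)
  expect_equal(r$rateWT, 4.5 / 10)   # rates from unrounded averages
  expect_equal(r$rateMut, 9.5 / 10)
  expect_equal(r$diff, 0.5)

  ## identical tracks -> p = 1, diff = 0
  tkSame <- twoTrack(pos = c(1, 2), methW = c(3, 3), unmethW = c(3, 3),
                     methM = c(3, 3), unmethM = c(3, 3))
  r <- testRegions(data.frame(chrom = "chr1", start = 1, end = 2,
                              context = "CG", type = "hyper", nDmcs = 2L),
                   tkSame$wt, tkSame$mut)
  expect_equal(r$pValue, 1)
  expect_equal(r$diff, 0)
})

test_that("DMR filters enforce count, length, FDR and per-context difference", {
  base <- data.frame(chrom = "chr1", start = 100, end = 300, context = "CG",
                     type = "hypo", nDmcs = 6L, pValue = 1e-4, rateWT = 0.9,
                     rateMut = 0.3, diff = -0.6, fdr = 1e-3)
  expect_equal(nrow(filterDmrs(base)), 1L)
  few <- base; few$nDmcs <- 4L
  expect_equal(nrow(filterDmrs(few)), 0L)
  short <- base; short$end <- base$start + 48   # length 49 bp
  expect_equal(nrow(filterDmrs(short)), 0L)
  weak <- base; weak$diff <- -0.35              # CG needs >= 0.40
  expect_equal(nrow(filterDmrs(weak)), 0L)
  weakCHG <- weak; weakCHG$context <- "CHG"     # CHG needs only >= 0.20
  expect_equal(nrow(filterDmrs(weakCHG)), 1L)
  lax <- base; lax$fdr <- 0.06
  expect_equal(nrow(filterDmrs(lax)), 0L)
})

test_that("no emitted region holds an opposite-type DMC strictly inside", {
  withr::with_seed(33, {
    for (rep in 1:50) {
      n <- sample(2:6, 1)
      pos <- sort(sample(1:400, n))
      type <- sample(c("hypo", "hyper"), n, replace = TRUE)
      r <- mergeDmcs(mkDmcs(pos, type, context = "CHG"))
      for (k in seq_len(nrow(r))) {
        inside <- pos > r$start[k] & pos < r$end[k]
        expect_false(any(type[inside] != r$type[k]))
      }
    }
  })
})

test_that("DMR-feature mapping requires >= 1 overlapping nucleotide", {
  dmr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(100, 200))
  S4Vectors::mcols(dmr) <- S4Vectors::DataFrame(
    context = "CG", type = "hypo", nDmcs = 5L, pValue = 0.001, fdr = 0.01,
    rateWT = 0.9, rateMut = 0.2, diff = -0.7)
  feat <- GenomicRanges::GRanges("chr1", IRanges::IRanges(200, 300))
  S4Vectors::mcols(feat)$id <- "f1"
  expect_equal(nrow(mapDmrsToFeatures(dmr, feat)), 1L)  # 1-nt overlap
  feat2 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(201, 300))
  S4Vectors::mcols(feat2)$id <- "f1"
  expect_equal(nrow(mapDmrsToFeatures(dmr, feat2)), 0L)  # adjacency

  withr::with_seed(14, {
    for (rep in 1:100) {
      s1 <- sample(500, 1); e1 <- s1 + sample(0:80, 1)
      s2 <- sample(500, 1); e2 <- s2 + sample(0:80, 1)
      d <- GenomicRanges::GRanges("chr1", IRanges::IRanges(s1, e1))
      f <- GenomicRanges::GRanges("chr1", IRanges::IRanges(s2, e2))
      S4Vectors::mcols(f)$id <- "x"
      expect_equal(nrow(mapDmrsToFeatures(d, f)) == 1L,
                   oracleOverlaps(s1, e1, s2, e2))
    }
  })
})

test_that("overlap summary counts features hit by hypo-DMRs per context", {
  up <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(c(100, 1000, 5000), width = 200))
  none <- overlapSummary(GenomicRanges::GRanges(
    seqnames = character(0), ranges = IRanges::IRanges()), up)
  expect_true(all(none$nOverlap == 0))

  dmrs <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(c(150, 1100, 5100), width = 50))
  S4Vectors::mcols(dmrs) <- S4Vectors::DataFrame(
    context = c("CG", "CG", "CHH"), type = "hypo")
  s <- overlapSummary(dmrs, up)
  expect_equal(s$nOverlap[s$context == "CG"], 2L)
  expect_equal(s$nOverlap[s$context == "CHH"], 1L)
  expect_equal(s$nOverlap[s$context == "CHG"], 0L)
  expect_true(all(s$nUp == 3L))

  ## random fixture vs brute-force double loop
  withr::with_seed(8, {
    ds <- sample(2000, 30); de <- ds + sample(10:100, 30, replace = TRUE)
    us <- sample(2000, 10); ue <- us + sample(50:300, 10, replace = TRUE)
    cx <- sample(c("CG", "CHG", "CHH"), 30, replace = TRUE)
    dmrs <- GenomicRanges::GRanges("chr1", IRanges::IRanges(ds, de))
    S4Vectors::mcols(dmrs) <- S4Vectors::DataFrame(context = cx, type = "hypo")
    up <- GenomicRanges::GRanges("chr1", IRanges::IRanges(us, ue))
    s <- overlapSummary(dmrs, up)
    for (ctx in c("CG", "CHG", "CHH")) {
      hand <- sum(vapply(seq_along(us), function(u)
        any(vapply(which(cx == ctx), function(d)
          oracleOverlaps(ds[d], de[d], us[u], ue[u]), logical(1))),
        logical(1)))
      expect_equal(s$nOverlap[s$context == ctx], hand)
    }
  })
})
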