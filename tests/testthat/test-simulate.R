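smallGenomeSpec <- function(seed = 1L, nPcgs = 20L, nTes = 20L) {
  GenomeSpec(nChroms = 1L, chromLength = 2e5, nPcgs = nPcgs, nTes = nTes,
             cytosinesPerMb = c(CG = 8000, CHG = 6000, CHH = 14000),
             seed = seed)
}

test_that("generators are reproducible given the same seed", {
  g1 <- makeGenome(smallGenomeSpec(seed = 4L))
  g2 <- makeGenome(smallGenomeSpec(seed = 4L))
  expect_identical(g1$cytosines, g2$cytosines)
  expect_identical(as.data.frame(g1$features), as.data.frame(g2$features))

  m1 <- simulateMethylome(g1, MethylomeSpec(), "WT", seed = 2L)
  m2 <- simulateMethylome(g1, MethylomeSpec(), "WT", seed = 2L)
  expect_identical(m1$libraries, m2$libraries)
  m3 <- simulateMethylome(g1, MethylomeSpec(), "WT", seed = 3L)
  expect_false(identical(m1$libraries, m3$libraries))

  s1 <- simulateSrna(g1, seed = 6L)
  s2 <- simulateSrna(g1, seed = 6L)
  expect_identical(s1$coverage24, s2$coverage24)
})

test_that("TE compartment counts follow the het:eu density ratio", {
  spec <- GenomeSpec(nChroms = 2L, chromLength = 1e6, nPcgs = 10L,
                     nTes = 250L, teDensityRatio = 4,
                     cytosinesPerMb = c(CG = 1000, CHG = 1000, CHH = 1000),
                     seed = 9L)
  g <- makeGenome(spec)
  te <- g$features[S4Vectors::mcols(g$features)$kind == "TE"]
  nHet <- sum(S4Vectors::mcols(te)$compartment == "pericentromeric_het")
  ## het covers 40% of each chromosome; ratio 4 -> P(het) = 4*0.4/(4*0.4+0.6)
  pHet <- 4 * 0.4 / (4 * 0.4 + 0.6)
  bounds <- qbinom(c(0.005, 0.995), 500, pHet)
  expect_gte(nHet, bounds[1])
  expect_lte(nHet, bounds[2])
  ## features do not overlap within a class
  byClass <- split(te, as.character(GenomicRanges::seqnames(te)))
  for (cls in byClass)
    expect_equal(sum(GenomicRanges::countOverlaps(cls, cls) > 1), 0)
})

test_that("a genome without TEs still carries its PCGs", {
  g <- makeGenome(smallGenomeSpec(seed = 2L, nTes = 0L))
  expect_equal(sum(S4Vectors::mcols(g$features)$kind == "TE"), 0L)
  expect_equal(sum(S4Vectors::mcols(g$features)$kind == "PCG"), 20L)
})

test_that("empirical methylation rates converge to the base rates", {
  g <- makeGenome(smallGenomeSpec(seed = 5L))
  ## overdispersion 0, high coverage: law of large numbers per compartment
  spec <- MethylomeSpec(overdispersion = 0, coverage = 500, nLibraries = 1L)
  m <- simulateMethylome(g, spec, "WT", seed = 8L)
  lib <- m$libraries[[1]]
  peri <- c(GenomicRanges::start(g$pericentromere)[1],
            GenomicRanges::end(g$pericentromere)[1])
  het <- lib$pos >= peri[1] & lib$pos <= peri[2]
  for (cx in c("CG", "CHG", "CHH")) {
    i <- het & lib$context == cx
    emp <- sum(lib$meth[i]) / sum(lib$meth[i] + lib$unmeth[i])
    expect_lt(abs(emp - MethylomeSpec()@baseRates[cx, "pericentromeric_het"]),
              0.02)
  }
  i <- !het & lib$context == "CG"
  emp <- sum(lib$meth[i]) / sum(lib$meth[i] + lib$unmeth[i])
  expect_lt(abs(emp - 0.20), 0.02)
})

test_that("injected intervals impose their target methylation rate", {
  g <- makeGenome(smallGenomeSpec(seed = 5L))
  inj <- sampleInjections(g, 5, context = "CG", targetRate = 0,
                          lengthRange = c(400, 800), minSeparation = 1000,
                          seed = 3L)
  spec <- MethylomeSpec(coverage = 50, nLibraries = 1L)
  m <- simulateMethylome(g, spec, "mut", injections = inj, seed = 4L)
  lib <- m$libraries[[1]]
  for (k in seq_len(nrow(inj))) {
    i <- lib$pos >= inj$start[k] & lib$pos <= inj$end[k] &
      lib$context == "CG"
    emp <- sum(lib$meth[i]) / sum(lib$meth[i] + lib$unmeth[i])
    expect_lt(emp, 0.05)
  }
})

test_that("zero mean coverage produces all-zero records", {
  g <- makeGenome(smallGenomeSpec(seed = 5L))
  m <- simulateMethylome(g, MethylomeSpec(coverage = 0, nLibraries = 1L),
                         "WT", seed = 1L)
  expect_true(all(m$libraries[[1]]$meth == 0L))
  expect_true(all(m$libraries[[1]]$unmeth == 0L))
})

test_that("simulated cytosine tables round-trip through the native format", {
  g <- makeGenome(smallGenomeSpec(seed = 7L))
  m <- simulateMethylome(g, MethylomeSpec(nLibraries = 1L), "WT", seed = 2L)
  f <- withr::local_tempfile(fileext = ".tsv")
  writeCytosineTable(m$libraries[[1]], f)
  back <- readCytosineTable(f)
  expect_equal(back, m$libraries[[1]], ignore_attr = TRUE)
})

test_that("expression counts respect fold changes and dispersion limits", {
  g <- makeGenome(smallGenomeSpec(seed = 6L))
  ## fold = 1 everywhere: genotype means agree within sampling error
  e0 <- simulateExpression(g, baselineMean = 100, nDe = 0, seed = 5L)
  cts <- counts(e0$counts)
  expect_lt(abs(log2(mean(cts[, c("mut1", "mut2")]) /
                       mean(cts[, c("wt1", "wt2")]))), 0.25)

  ## injected 8-fold loci have mutant means ~8x their baseline
  e8 <- simulateExpression(g, baselineMean = 100, nDe = 10, fold = 8,
                           seed = 7L)
  de <- e8$truth$isDe
  expect_equal(sum(de), 10L)
  cts <- counts(e8$counts)
  ratio <- rowMeans(cts[de, c("mut1", "mut2"), drop = FALSE]) /
    pmax(e8$truth$baseline[de], 1)
  expect_gt(mean(ratio), 6)
  expect_lt(mean(ratio), 10)
  expect_true(all(e8$truth$baseline[de] >= 20))

  ## dispersion -> 0 approaches Poisson (variance ~ mean)
  eP <- simulateExpression(g, baselineMean = 50, dispersion = 0, seed = 8L)
  ctsP <- counts(eP$counts)
  ## per-locus variance across 4 libraries, averaged, against the mean
  vm <- mean(apply(ctsP, 1, var)) / mean(ctsP)
  expect_lt(vm, 1.5)
  eD <- simulateExpression(g, baselineMean = 50, dispersion = 0.3, seed = 8L)
  ctsD <- counts(eD$counts)
  expect_gt(mean(apply(ctsD, 1, var)) / mean(ctsD), 3)
})

test_that("small-RNA class totals are multinomial around their fractions", {
  g <- makeGenome(smallGenomeSpec(seed = 6L))
  s <- simulateSrna(g, classFractions = c("21" = 0.1, "24" = 0.6,
                                          "other" = 0.3),
                    libraryTotal = 1e6, seed = 2L)
  expect_equal(sum(s$classTotals), 1e6)
  for (cl in c("21", "24", "other")) {
    p <- c("21" = 0.1, "24" = 0.6, "other" = 0.3)[[cl]]
    bounds <- qbinom(c(0.005, 0.995), 1e6, p)
    expect_gte(s$classTotals[[cl]], bounds[1])
    expect_lte(s$classTotals[[cl]], bounds[2])
  }
  ## zero intensity loci receive zero reads
  s0 <- simulateSrna(g, pcgWeight = 0, seed = 3L)
  pcg <- S4Vectors::mcols(g$features)$kind == "PCG"
  expect_true(all(s0$perLocus$n24[pcg] == 0))
  ## 24-nt reads concentrate on TEs
  te <- !pcg
  expect_gt(sum(s$perLocus$n24[te]), 5 * sum(s$perLocus$n24[!te]))
})
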