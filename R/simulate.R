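#' Specification of a synthetic desk-scale genome
#'
#' Describes the genome emulated by [makeGenome()]: a few megabase-scale
#' chromosomes, each with a central pericentromeric-heterochromatin
#' compartment, transposable elements (TEs) enriched in heterochromatin,
#' protein-coding genes (PCGs) enriched in euchromatin, and per-context
#' cytosine positions at densities comparable to a compact plant genome
#' (roughly one CG site per 25 bp per megabase-scale chromosome).
#'
#' @slot nChroms Number of chromosomes (default 2).
#' @slot chromLength Chromosome length in bp (default 1e6).
#' @slot pericentromere Length-2 fractions of the chromosome covered by the
#'   pericentromeric compartment (default c(0.3, 0.7)).
#' @slot nPcgs,nTes Features per chromosome (defaults 150 and 125).
#' @slot teDensityRatio TE placement density ratio het:eu (default 4).
#' @slot pcgDensityRatio PCG placement density ratio het:eu (default 0.25).
#' @slot pcgMeanLen,teMeanLen Median feature lengths in bp (2000, 800).
#' @slot lenSdLog Log-normal sdlog of feature lengths (default 0.4).
#' @slot cytosinesPerMb Named per-context cytosine counts per Mb
#'   (CG 40000, CHG 30000, CHH 70000).
#' @slot seed Integer seed; all outputs are reproducible given the spec.
#' @export
setClass("GenomeSpec",
  representation(nChroms = "integer", chromLength = "numeric",
                 pericentromere = "numeric", nPcgs = "integer",
                 nTes = "integer", teDensityRatio = "numeric",
                 pcgDensityRatio = "numeric", pcgMeanLen = "numeric",
                 teMeanLen = "numeric", lenSdLog = "numeric",
                 cytosinesPerMb = "numeric", seed = "integer"),
  prototype(nChroms = 2L, chromLength = 1e6,
            pericentromere = c(0.3, 0.7), nPcgs = 150L, nTes = 125L,
            teDensityRatio = 4, pcgDensityRatio = 0.25,
            pcgMeanLen = 2000, teMeanLen = 800, lenSdLog = 0.4,
            cytosinesPerMb = c(CG = 40000, CHG = 30000, CHH = 70000),
            seed = 1L),
  validity = function(object) {
    pc <- object@pericentromere
    if (length(pc) != 2L || pc[1] < 0 || pc[2] > 1 || pc[1] >= pc[2])
      return("'pericentromere' must be fractions 0 <= a < b <= 1")
    if (!all(CONTEXTS %in% names(object@cytosinesPerMb)))
      return("'cytosinesPerMb' must name CG, CHG and CHH")
    if (object@nChroms < 1L) return("need at least one chromosome")
    TRUE
  })

#' @rdname GenomeSpec-class
#' @param ... Slot values overriding the defaults.
#' @return A \code{GenomeSpec}.
#' @examples
#' GenomeSpec(nChroms = 1L, seed = 7L)
#' @export
GenomeSpec <- function(...) {
  args <- list(...)
  for (s in c("nChroms", "nPcgs", "nTes", "seed"))
    if (!is.null(args[[s]])) args[[s]] <- as.integer(args[[s]])
  do.call(new, c(list("GenomeSpec"), args))
}

#' Specification of a synthetic methylome
#'
#' Parameters of the beta-binomial methylome sampler used by
#' [simulateMethylome()]. Base methylation rates depend on sequence
#' context and compartment, mirroring dense methylation of pericentromeric
#' heterochromatin in all three contexts; per-cytosine coverage is
#' Poisson; methylated counts are beta-binomial so that biological
#' overdispersion is present even between identically parameterised
#' genotypes.
#'
#' @slot baseRates 3x2 numeric matrix, rows CG/CHG/CHH, columns
#'   \code{pericentromeric_het} / \code{euchromatin}.
#' @slot overdispersion Beta-binomial intraclass correlation (default 0.05).
#' @slot coverage Mean per-library read coverage per cytosine (default 20).
#' @slot nLibraries Replicate libraries per genotype (default 2).
#' @export
setClass("MethylomeSpec",
  representation(baseRates = "matrix", overdispersion = "numeric",
                 coverage = "numeric", nLibraries = "integer"),
  prototype(
    baseRates = matrix(c(0.85, 0.55, 0.15, 0.20, 0.05, 0.03), 3,
                       dimnames = list(c("CG", "CHG", "CHH"),
                                       c("pericentromeric_het",
                                         "euchromatin"))),
    overdispersion = 0.05, coverage = 20, nLibraries = 2L),
  validity = function(object) {
    if (any(object@baseRates < 0 | object@baseRates > 1))
      return("base rates must lie in [0, 1]")
    if (object@overdispersion < 0 || object@overdispersion >= 1)
      return("'overdispersion' must be in [0, 1)")
    if (object@coverage < 0) return("'coverage' must be non-negative")
    if (object@nLibraries < 1L) return("need at least one library")
    TRUE
  })

#' @rdname MethylomeSpec-class
#' @param ... Slot values overriding the defaults.
#' @return A \code{MethylomeSpec}.
#' @export
MethylomeSpec <- function(...) {
  args <- list(...)
  if (!is.null(args$nLibraries)) args$nLibraries <- as.integer(args$nLibraries)
  do.call(new, c(list("MethylomeSpec"), args))
}

## place n non-overlapping features in [1, chromLength], compartment-biased
placeFeatures <- function(n, lengths, chromLength, periBp, densityRatio) {
  hetLen <- diff(periBp) + 1
  euLen <- chromLength - hetLen
  pHet <- densityRatio * hetLen / (densityRatio * hetLen + euLen)
  comp <- ifelse(runif(n) < pHet, "pericentromeric_het", "euchromatin")
  out <- data.frame(start = integer(n), end = integer(n), compartment = comp)
  for (cp in c("pericentromeric_het", "euchromatin")) {
    i <- which(comp == cp)
    if (!length(i)) next
    L <- lengths[i]
    segs <- if (cp == "pericentromeric_het")
      matrix(periBp, ncol = 2)
    else
      matrix(c(1, periBp[1] - 1, periBp[2] + 1, chromLength),
             ncol = 2, byrow = TRUE)
    segLen <- segs[, 2] - segs[, 1] + 1
    ## assign features to sub-segments proportionally, then stick-break gaps
    segOf <- sample(nrow(segs), length(i), replace = TRUE,
                    prob = segLen / sum(segLen))
    for (s in seq_len(nrow(segs))) {
      j <- i[segOf == s]
      if (!length(j)) next
      Ls <- lengths[j]
      slack <- segLen[s] - sum(Ls)
      if (slack < length(j) + 1)
        stop("infeasible feature density: features cannot fit", call. = FALSE)
      cuts <- sort(sample.int(slack, length(j)))
      ord <- sample(length(j))            # random feature order within segment
      starts <- segs[s, 1] + cuts + c(0, cumsum(Ls[ord]))[seq_along(j)]
      out$start[j[ord]] <- starts
      out$end[j[ord]] <- starts + Ls[ord] - 1L
    }
  }
  out
}

#' Generate a synthetic genome with features and cytosine positions
#'
#' Deterministically (given \code{spec@seed}) builds chromosome lengths, a
#' pericentromeric compartment per chromosome, non-overlapping PCG and TE
#' annotations whose compartment bias follows the spec's density ratios,
#' and per-context cytosine positions.
#'
#' @param spec A [GenomeSpec-class].
#' @return A list: \code{chromLengths} (named numeric),
#'   \code{pericentromere} (\code{GRanges}), \code{features}
#'   (\code{GRanges} with \code{id}, \code{kind}, \code{compartment},
#'   strand), \code{cytosines} (data.frame \code{chrom}, \code{pos},
#'   \code{strand}, \code{context}, sorted), and \code{spec}.
#' @export
makeGenome <- function(spec = GenomeSpec()) {
  stopifnot(is(spec, "GenomeSpec"))
  withSeed(spec@seed, {
    chroms <- paste0("chr", seq_len(spec@nChroms))
    chromLengths <- stats::setNames(rep(spec@chromLength, spec@nChroms),
                                    chroms)
    periBp <- round(spec@pericentromere * spec@chromLength)
    peri <- GenomicRanges::GRanges(chroms,
      IRanges::IRanges(start = periBp[1], end = periBp[2]))
    featList <- list()
    cytList <- list()
    for (ch in chroms) {
      pcgLen <- pmax(200L, as.integer(round(rlnorm(spec@nPcgs,
        log(spec@pcgMeanLen), spec@lenSdLog))))
      teLen <- pmax(100L, as.integer(round(rlnorm(spec@nTes,
        log(spec@teMeanLen), spec@lenSdLog))))
      pcg <- placeFeatures(spec@nPcgs, pcgLen, spec@chromLength, periBp,
                           spec@pcgDensityRatio)
      te <- placeFeatures(spec@nTes, teLen, spec@chromLength, periBp,
                          spec@teDensityRatio)
      pcg$kind <- rep("PCG", nrow(pcg))
      te$kind <- rep("TE", nrow(te))
      fd <- rbind(pcg, te)
      fd$chrom <- rep(ch, nrow(fd))
      fd$strand <- sample(c("+", "-"), nrow(fd), replace = TRUE)
      featList[[ch]] <- fd
      ## cytosine positions: unique positions split among contexts
      nPerCx <- round(spec@cytosinesPerMb * spec@chromLength / 1e6)
      nTot <- sum(nPerCx)
      pos <- sort(sample.int(spec@chromLength, nTot))
      cx <- sample(rep(CONTEXTS, times = nPerCx))
      cytList[[ch]] <- data.frame(
        chrom = ch, pos = pos,
        strand = sample(c("+", "-"), nTot, replace = TRUE),
        context = cx)
    }
    fd <- do.call(rbind, featList)
    features <- GenomicRanges::GRanges(fd$chrom,
      IRanges::IRanges(fd$start, fd$end), strand = fd$strand)
    serial <- stats::ave(seq_len(nrow(fd)), fd$kind, fd$chrom,
                         FUN = seq_along)
    S4Vectors::mcols(features) <- S4Vectors::DataFrame(
      id = sprintf("%s_%s_%04d", fd$kind, fd$chrom, serial),
      kind = fd$kind, compartment = fd$compartment)
    cyt <- do.call(rbind, cytList)
    cyt <- cyt[order(cyt$chrom, cyt$pos), ]
    rownames(cyt) <- NULL
    list(chromLengths = chromLengths, pericentromere = peri,
         features = features, cytosines = cyt, spec = spec)
  })
}

## compartment label per position, given the genome
positionCompartment <- function(genome, chrom, pos) {
  periBp <- c(GenomicRanges::start(genome$pericentromere)[1],
              GenomicRanges::end(genome$pericentromere)[1])
  ifelse(pos >= periBp[1] & pos <= periBp[2],
         "pericentromeric_het", "euchromatin")
}

## beta-binomial sampler: rho is the intraclass correlation; rho = 0
## degenerates to plain binomial
rbetabinom <- function(n, size, prob, rho) {
  if (rho == 0) return(rbinom(n, size, prob))
  a <- prob * (1 - rho) / rho
  b <- (1 - prob) * (1 - rho) / rho
  p <- numeric(n)
  ok <- prob > 0 & prob < 1
  p[ok] <- rbeta(sum(ok), a[ok], b[ok])
  p[!ok] <- prob[!ok]
  rbinom(n, size, p)
}

#' Sample non-overlapping intervals for methylome injections
#'
#' Picks \code{n} well-separated intervals inside the requested
#' compartment, to be used as injected (ground-truth) DMRs.
#'
#' @param genome A genome from [makeGenome()].
#' @param n Number of intervals.
#' @param context,type,targetRate Injection annotation: affected context,
#'   "hypo"/"hyper", and the methylation rate imposed inside the interval.
#' @param lengthRange Min/max interval length in bp (default c(300, 800)).
#' @param compartment Compartment to place intervals in.
#' @param minSeparation Minimum distance between intervals (default 2000).
#' @param seed Integer seed.
#' @return data.frame \code{chrom}, \code{start}, \code{end},
#'   \code{context}, \code{type}, \code{targetRate}.
#' @export
sampleInjections <- function(genome, n, context = "CG", type = "hypo",
                             targetRate = 0.1, lengthRange = c(300, 800),
                             compartment = "pericentromeric_het",
                             minSeparation = 2000, seed = 1L) {
  withSeed(seed, {
    chroms <- names(genome$chromLengths)
    periBp <- c(GenomicRanges::start(genome$pericentromere)[1],
                GenomicRanges::end(genome$pericentromere)[1])
    lo <- if (compartment == "pericentromeric_het") periBp[1] else 1
    hi <- if (compartment == "pericentromeric_het") periBp[2]
          else periBp[1] - 1
    out <- list()
    perChrom <- table(sample(chroms, n, replace = TRUE))
    for (ch in names(perChrom)) {
      k <- perChrom[[ch]]
      lens <- round(runif(k, lengthRange[1], lengthRange[2]))
      span <- hi - lo + 1 - sum(lens) - (k + 1) * minSeparation
      if (span < k) stop("injections cannot fit", call. = FALSE)
      cuts <- sort(sample.int(span, k))
      starts <- lo + minSeparation + cuts +
        c(0, cumsum(lens + minSeparation))[seq_len(k)]
      out[[ch]] <- data.frame(chrom = ch, start = starts,
                              end = starts + lens - 1)
    }
    res <- do.call(rbind, out)
    res$context <- context
    res$type <- type
    res$targetRate <- targetRate
    rownames(res) <- NULL
    res
  })
}

#' Simulate replicate bisulfite libraries for one genotype
#'
#' Per cytosine and library, read coverage is Poisson with the spec's mean
#' and the methylated count is beta-binomial around the compartment- and
#' context-specific base rate. Injected intervals override the base rate
#' with their target rate for cytosines of the matching context. Output
#' tables round-trip through [writeCytosineTable()] /
#' [readCytosineTable()].
#'
#' @param genome A genome from [makeGenome()].
#' @param spec A [MethylomeSpec-class].
#' @param genotype Genotype label.
#' @param injections Optional data.frame as from [sampleInjections()].
#' @param seed Integer seed.
#' @return list: \code{libraries} (list of per-cytosine data.frames, one
#'   per replicate), \code{truth} (the injections, possibly empty),
#'   \code{genotype}.
#' @export
simulateMethylome <- function(genome, spec = MethylomeSpec(),
                              genotype = "WT", injections = NULL,
                              seed = 1L) {
  stopifnot(is(spec, "MethylomeSpec"))
  cyt <- genome$cytosines
  comp <- positionCompartment(genome, cyt$chrom, cyt$pos)
  rate <- spec@baseRates[cbind(match(cyt$context, rownames(spec@baseRates)),
                               match(comp, colnames(spec@baseRates)))]
  if (!is.null(injections) && nrow(injections)) {
    for (i in seq_len(nrow(injections))) {
      hit <- cyt$chrom == injections$chrom[i] &
        cyt$pos >= injections$start[i] & cyt$pos <= injections$end[i] &
        cyt$context == injections$context[i]
      rate[hit] <- injections$targetRate[i]
    }
  }
  n <- nrow(cyt)
  libs <- vector("list", spec@nLibraries)
  for (l in seq_len(spec@nLibraries)) {
    libs[[l]] <- withSeed(childSeed(seed, paste0(genotype, ".lib", l)), {
      covv <- rpois(n, spec@coverage)
      meth <- rbetabinom(n, covv, rate, spec@overdispersion)
      data.frame(chrom = cyt$chrom, pos = cyt$pos, strand = cyt$strand,
                 context = cyt$context, meth = as.integer(meth),
                 unmeth = as.integer(covv - meth))
    })
  }
  names(libs) <- paste0(genotype, seq_len(spec@nLibraries))
  truth <- if (is.null(injections))
    data.frame(chrom = character(0), start = integer(0), end = integer(0),
               context = character(0), type = character(0),
               targetRate = numeric(0))
  else injections
  list(libraries = libs, truth = truth, genotype = genotype)
}

#' Simulate RNA-seq counts for two genotypes with optional DE loci
#'
#' Per-locus baseline expression is log-normal around
#' \code{baselineMean}; counts per library are negative binomial
#' (\code{var = mu + dispersion * mu^2}; \code{dispersion = 0} gives
#' Poisson). \code{nDe} loci with baseline at least \code{minBaseline}
#' reads are upregulated \code{fold}-fold in the mutant, preferentially
#' chosen from pericentromeric TEs with probability \code{hetBias}
#' (emulating heterochromatic silencing release).
#'
#' @param genome A genome from [makeGenome()].
#' @param baselineMean Median baseline expected count (default 100).
#' @param dispersion NB dispersion (default 0.05).
#' @param nDe Number of upregulated loci to inject (default 0).
#' @param fold Fold change of injected loci (default 8).
#' @param minBaseline Minimum baseline mean of injected loci (default 20).
#' @param hetBias Probability that an injected locus is drawn from the
#'   pericentromeric compartment (default 0.7).
#' @param nPairs Replicate libraries per genotype (default 2).
#' @param backgroundReads Mapped reads outside the analysed loci, added to
#'   each library size (default 2e6). Real libraries are dominated by
#'   reads from loci outside any tested set; without this, injecting
#'   strongly upregulated loci would deflate the mutant's RPKM genome-wide
#'   through the library-size normalisation.
#' @param seed Integer seed.
#' @return list: \code{counts} (a [LocusCounts-class], columns wt1..,
#'   mut1..), \code{loci} (\code{GRanges} matching rows), \code{pairs}
#'   (replicate pairing for [callDifferential()]), \code{truth}
#'   (data.frame \code{locus}, \code{baseline}, \code{fold}, \code{isDe},
#'   \code{compartment}).
#' @export
simulateExpression <- function(genome, baselineMean = 100, dispersion = 0.05,
                               nDe = 0, fold = 8, minBaseline = 20,
                               hetBias = 0.7, nPairs = 2,
                               backgroundReads = 2e6, seed = 1L) {
  loci <- genome$features
  ids <- S4Vectors::mcols(loci)$id
  comp <- S4Vectors::mcols(loci)$compartment
  kind <- S4Vectors::mcols(loci)$kind
  nL <- length(loci)
  withSeed(childSeed(seed, "expression"), {
    baseline <- rlnorm(nL, log(baselineMean), 0.8)
    isDe <- rep(FALSE, nL)
    if (nDe > 0) {
      eligible <- which(baseline >= minBaseline)
      het <- eligible[comp[eligible] == "pericentromeric_het" &
                        kind[eligible] == "TE"]
      eu <- setdiff(eligible, het)
      fromHet <- rbinom(1, nDe, hetBias)
      fromHet <- min(fromHet, length(het))
      pick <- c(sample(het, fromHet),
                sample(eu, min(nDe - fromHet, length(eu))))
      isDe[pick] <- TRUE
    }
    foldVec <- ifelse(isDe, fold, 1)
    libs <- c(paste0("wt", seq_len(nPairs)), paste0("mut", seq_len(nPairs)))
    cts <- matrix(0L, nL, length(libs), dimnames = list(ids, libs))
    for (j in seq_along(libs)) {
      mu <- baseline * (if (startsWith(libs[j], "mut")) foldVec else 1)
      cts[, j] <- if (dispersion == 0) rpois(nL, mu)
                  else rnbinom(nL, mu = mu, size = 1 / dispersion)
    }
    lc <- LocusCounts(cts, lengths = GenomicRanges::width(loci),
                      libSizes = colSums(cts) + backgroundReads)
    pairs <- lapply(seq_len(nPairs), function(i)
      c(wt = paste0("wt", i), mut = paste0("mut", i)))
    truth <- data.frame(locus = ids, baseline = baseline, fold = foldVec,
                        isDe = isDe, compartment = comp)
    list(counts = lc, loci = loci, pairs = pairs, truth = truth)
  })
}

#' Simulate a size-classed small-RNA library
#'
#' Library totals over the 18-26-nt range are split multinomially into
#' 21-nt, 24-nt and other size classes. Within the 24-nt (and 21-nt)
#' class, reads are distributed over loci with weights proportional to
#' locus length times a kind-specific intensity (24-nt siRNAs concentrate
#' on TEs), then spread uniformly over each locus' positions to give
#' per-position coverage.
#'
#' @param genome A genome from [makeGenome()].
#' @param classFractions Named fractions of the 18-26-nt total for
#'   \code{"21"}, \code{"24"} and \code{"other"} (must sum to <= 1).
#' @param libraryTotal Total 18-26-nt mapped reads (default 1e6).
#' @param teWeight,pcgWeight Relative per-bp read intensity of TEs and
#'   PCGs (defaults 20 and 1; 24-nt siRNAs are TE-concentrated).
#' @param seed Integer seed.
#' @return list: \code{classTotals} (named counts for 21/24/other),
#'   \code{perLocus} (data.frame \code{locus}, \code{n21}, \code{n24},
#'   raw counts), \code{coverage21}, \code{coverage24} (data.frames
#'   \code{chrom}, \code{pos}, \code{value}; value normalized to reads per
#'   million 18-26-nt reads), \code{total1826}, \code{truth} (locus
#'   weights).
#' @export
simulateSrna <- function(genome,
                         classFractions = c("21" = 0.15, "24" = 0.55,
                                            "other" = 0.30),
                         libraryTotal = 1e6, teWeight = 20, pcgWeight = 1,
                         seed = 1L) {
  stopifnot(sum(classFractions) <= 1 + 1e-12)
  loci <- genome$features
  ids <- S4Vectors::mcols(loci)$id
  kind <- S4Vectors::mcols(loci)$kind
  len <- GenomicRanges::width(loci)
  withSeed(childSeed(seed, "srna"), {
    tot <- as.vector(rmultinom(1, libraryTotal,
                               c(classFractions["21"], classFractions["24"],
                                 1 - classFractions["21"] -
                                   classFractions["24"])))
    names(tot) <- c("21", "24", "other")
    w24 <- len * ifelse(kind == "TE", teWeight, pcgWeight)
    w21 <- len * ifelse(kind == "TE", teWeight / 4, pcgWeight)
    n24 <- as.vector(rmultinom(1, tot[["24"]], w24 / sum(w24)))
    n21 <- as.vector(rmultinom(1, tot[["21"]], w21 / sum(w21)))
    covFrom <- function(nReads) {
      out <- list()
      chrom <- as.character(GenomicRanges::seqnames(loci))
      st <- GenomicRanges::start(loci)
      for (i in which(nReads > 0)) {
        hits <- as.vector(rmultinom(1, nReads[i], rep(1 / len[i], len[i])))
        nz <- which(hits > 0)
        out[[length(out) + 1L]] <- data.frame(
          chrom = chrom[i], pos = st[i] + nz - 1L, value = hits[nz])
      }
      cv <- if (length(out)) do.call(rbind, out)
            else data.frame(chrom = character(0), pos = integer(0),
                            value = numeric(0))
      ## overlapping loci could duplicate positions; aggregate
      if (nrow(cv)) {
        agg <- stats::aggregate(value ~ chrom + pos, cv, sum)
        agg <- agg[order(agg$chrom, agg$pos), ]
        rownames(agg) <- NULL
        agg$value <- normalizeSrna(agg$value, libraryTotal)
        agg
      } else cv
    }
    list(classTotals = tot,
         perLocus = data.frame(locus = ids, n21 = n21, n24 = n24),
         coverage21 = covFrom(n21), coverage24 = covFrom(n24),
         total1826 = libraryTotal,
         truth = data.frame(locus = ids, w21 = w21, w24 = w24))
  })
}
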