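#' Reads per kilobase per million mapped reads
#'
#' \code{RPKM = count / (length/1000) / (total/1e6)}.
#'
#' @param count Read count(s) at the locus.
#' @param lengthBp Locus length(s) in bp (>= 1).
#' @param totalMapped Total mapped reads in the library (>= 1).
#' @return Numeric RPKM value(s).
#' @examples
#' computeRpkm(10, 1000, 1e6)   # 10
#' computeRpkm(50, 2000, 1e7)   # 2.5
#' @export
computeRpkm <- function(count, lengthBp, totalMapped) {
  stopifnot(all(lengthBp >= 1), all(totalMapped >= 1))
  count / (lengthBp / 1000) / (totalMapped / 1e6)
}

#' Fisher's exact test for differential expression of one locus
#'
#' Two-sided Fisher's exact test on the 2x2 table contrasting the locus'
#' reads against the rest of the library in mutant and wild type:
#' \code{(countMut, totalMut - countMut; countWT, totalWT - countWT)}.
#'
#' @param countMut,countWT Locus read counts (vectors allowed).
#' @param totalMut,totalWT Total mapped reads per library.
#' @return P-value vector in (0, 1].
#' @export
deTest <- function(countMut, countWT, totalMut, totalWT) {
  stopifnot(all(countMut <= totalMut), all(countWT <= totalWT))
  fisherExactTwoSided(countMut, totalMut - countMut,
                      countWT, totalWT - countWT)
}

#' Call differentially expressed loci with replicate intersection
#'
#' For each replicate pair (one wild-type library against one mutant
#' library): RPKM is computed per locus, a per-locus two-sided Fisher's
#' exact test contrasts the locus counts against the rest of each library,
#' p-values are Benjamini-Hochberg adjusted across all loci of the pair,
#' and a locus is called \code{up} when \code{log2(RPKM_mut / RPKM_wt) > 2}
#' and \code{FDR < 0.01} (both strict), \code{down} symmetrically with
#' \code{< -2}. The final call is the per-pair call only when it is
#' identical in every replicate pair, otherwise \code{unchanged}. A
#' pseudocount (in reads, added to both genotypes before RPKM conversion)
#' stabilises the log2 ratio at zero counts; it never enters the Fisher
#' test.
#'
#' @param x A [LocusCounts-class] holding all libraries.
#' @param pairs List of length-2 character vectors \code{c(wt=, mut=)}
#'   naming columns of \code{counts(x)}; one element per replicate pair.
#' @param log2Threshold Log2 ratio threshold (default 2, strict).
#' @param fdrMax FDR ceiling (default 0.01, strict).
#' @param pseudo Pseudocount in reads (default 1).
#' @return data.frame with one row per locus: \code{locus}, per-pair
#'   columns \code{log2.<i>}, \code{pValue.<i>}, \code{fdr.<i>},
#'   \code{call.<i>}, and \code{finalCall}.
#' @export
callDifferential <- function(x, pairs, log2Threshold = 2, fdrMax = 0.01,
                             pseudo = 1) {
  stopifnot(is(x, "LocusCounts"), length(pairs) >= 1L)
  cts <- counts(x); len <- locusLengths(x); tot <- libSizes(x)
  names(tot) <- colnames(cts)
  res <- data.frame(locus = rownames(cts))
  callsPerPair <- matrix(NA_character_, nrow(cts), length(pairs))
  for (i in seq_along(pairs)) {
    pr <- pairs[[i]]
    wtLib <- pr[["wt"]]; mutLib <- pr[["mut"]]
    stopifnot(wtLib %in% colnames(cts), mutLib %in% colnames(cts))
    cW <- cts[, wtLib]; cM <- cts[, mutLib]
    rpkmW <- computeRpkm(cW + pseudo, len, tot[[wtLib]])
    rpkmM <- computeRpkm(cM + pseudo, len, tot[[mutLib]])
    l2 <- log2(rpkmM / rpkmW)
    p <- deTest(cM, cW, tot[[mutLib]], tot[[wtLib]])
    fdr <- benjaminiHochberg(p)
    call <- rep("unchanged", nrow(cts))
    call[l2 > log2Threshold & fdr < fdrMax] <- "up"
    call[l2 < -log2Threshold & fdr < fdrMax] <- "down"
    callsPerPair[, i] <- call
    res[[paste0("log2.", i)]] <- l2
    res[[paste0("pValue.", i)]] <- p
    res[[paste0("fdr.", i)]] <- fdr
    res[[paste0("call.", i)]] <- call
  }
  agree <- apply(callsPerPair, 1L, function(v) length(unique(v)) == 1L)
  res$finalCall <- ifelse(agree, callsPerPair[, 1L], "unchanged")
  res
}

#' Log2 expression-ratio track in fixed genomic windows
#'
#' Tiles each chromosome with non-overlapping windows (default 100 kb,
#' starting at position 1), assigns each locus to the window containing its
#' midpoint, and reports per window \code{log2(mean RPKM mutant / mean
#' RPKM wild type)}. Windows with no locus, or where either genotype's mean
#' RPKM is zero, emit \code{NA}. Each genotype's RPKM is averaged over its
#' libraries first.
#'
#' @param loci \code{GRanges} of loci (same order as rows of \code{x}).
#' @param x A [LocusCounts-class].
#' @param wtLibs,mutLibs Column names of the two genotypes' libraries.
#' @param chromLengths Named vector of chromosome lengths in bp.
#' @param windowBp Window size (default 1e5).
#' @return data.frame: \code{chrom}, \code{start}, \code{end},
#'   \code{log2Ratio}, \code{nLoci}.
#' @export
windowedLog2Track <- function(loci, x, wtLibs, mutLibs, chromLengths,
                              windowBp = 1e5) {
  stopifnot(length(loci) == nrow(counts(x)))
  cts <- counts(x); len <- locusLengths(x); tot <- libSizes(x)
  names(tot) <- colnames(cts)
  rpkm <- sapply(colnames(cts), function(lib)
    computeRpkm(cts[, lib], len, tot[[lib]]))
  meanW <- rowMeans(rpkm[, wtLibs, drop = FALSE])
  meanM <- rowMeans(rpkm[, mutLibs, drop = FALSE])
  mid <- floor((GenomicRanges::start(loci) + GenomicRanges::end(loci)) / 2)
  chrom <- as.character(GenomicRanges::seqnames(loci))
  out <- list()
  for (ch in names(chromLengths)) {
    starts <- seq(1L, chromLengths[[ch]], by = windowBp)
    ends <- pmin(starts + windowBp - 1L, chromLengths[[ch]])
    win <- findInterval(mid[chrom == ch], starts)
    mw <- meanW[chrom == ch]; mm <- meanM[chrom == ch]
    l2 <- nl <- rep(NA_real_, length(starts))
    for (w in seq_along(starts)) {
      i <- win == w
      nl[w] <- sum(i)
      if (nl[w] > 0) {
        num <- mean(mm[i]); den <- mean(mw[i])
        l2[w] <- if (num > 0 && den > 0) log2(num / den) else NA_real_
      }
    }
    out[[ch]] <- data.frame(chrom = ch, start = starts, end = ends,
                            log2Ratio = l2, nLoci = as.integer(nl))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Compartment enrichment of a feature subset
#'
#' One-sample two-sided z-test of the subset's pericentromeric-
#' heterochromatin proportion against the genome-wide background
#' proportion: \code{z = (phat - p0) / sqrt(p0 (1 - p0) / n)}, with the
#' p-value from the normal approximation. A negative z-score indicates
#' depletion of the subset in heterochromatin relative to all features.
#'
#' @param subset \code{GRanges} (e.g. upregulated loci) with a
#'   \code{compartment} metadata column.
#' @param background \code{GRanges} of all features, with
#'   \code{compartment}.
#' @param compartment Label counted as heterochromatic (default
#'   \code{"pericentromeric_het"}).
#' @return list with \code{observed}, \code{n}, \code{backgroundCount},
#'   \code{backgroundN}, \code{phat}, \code{p0}, \code{z}, \code{pValue}.
#' @export
compartmentEnrichment <- function(subset, background,
                                  compartment = "pericentromeric_het") {
  n <- length(subset)
  if (n == 0L) stop("'subset' is empty", call. = FALSE)
  obs <- sum(S4Vectors::mcols(subset)$compartment == compartment)
  bgN <- length(background)
  bg <- sum(S4Vectors::mcols(background)$compartment == compartment)
  p0 <- bg / bgN
  phat <- obs / n
  z <- if (p0 %in% c(0, 1)) 0 else (phat - p0) / sqrt(p0 * (1 - p0) / n)
  list(observed = obs, n = n, backgroundCount = bg, backgroundN = bgN,
       phat = phat, p0 = p0, z = z, pValue = 2 * pnorm(-abs(z)))
}
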