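#' Parameters for Savitzky-Golay smoothing of count tracks
#'
#' Per-cytosine methylated and unmethylated read counts are smoothed with a
#' Savitzky-Golay filter before differential testing: a polynomial of degree
#' \code{degree} is least-squares fitted over \code{window} index-adjacent
#' cytosines of the same sequence context and evaluated at the centre.
#' Defaults are a quadratic fit over 11 adjacent values.
#'
#' @slot window Odd integer, number of adjacent cytosines in the fit window.
#' @slot degree Integer polynomial degree, smaller than \code{window}.
#' @export
setClass("SmoothingParams",
  representation(window = "integer", degree = "integer"),
  prototype(window = 11L, degree = 2L),
  validity = function(object) {
    if (length(object@window) != 1L || object@window < 1L)
      return("'window' must be a positive scalar integer")
    if (object@window %% 2L == 0L)
      return("'window' must be odd")
    if (length(object@degree) != 1L || object@degree < 0L)
      return("'degree' must be a non-negative scalar integer")
    if (object@window <= object@degree)
      return("'window' must exceed 'degree'")
    TRUE
  })

#' @rdname SmoothingParams-class
#' @param window Odd integer window size (default 11).
#' @param degree Polynomial degree (default 2).
#' @return A \code{SmoothingParams} object.
#' @examples
#' SmoothingParams()
#' SmoothingParams(window = 7L, degree = 2L)
#' @export
SmoothingParams <- function(window = 11L, degree = 2L) {
  new("SmoothingParams", window = as.integer(window), degree = as.integer(degree))
}

#' Thresholds for calling differentially methylated cytosines
#'
#' A cytosine is a DMC when its two-sided Fisher's exact test p-value (on
#' rounded smoothed counts, mutant vs. wild type) is at most \code{pMax} and
#' the absolute smoothed methylation-rate difference (mutant minus wild type)
#' strictly exceeds \code{minAbsDiff}.
#'
#' @slot pMax Per-cytosine p-value ceiling (default 0.1, inclusive).
#' @slot minAbsDiff Minimum absolute rate difference (default 0.1, exclusive).
#' @export
setClass("DmcParams",
  representation(pMax = "numeric", minAbsDiff = "numeric"),
  prototype(pMax = 0.1, minAbsDiff = 0.1),
  validity = function(object) {
    if (!(object@pMax > 0 && object@pMax <= 1))
      return("'pMax' must be in (0, 1]")
    if (!(object@minAbsDiff >= 0 && object@minAbsDiff < 1))
      return("'minAbsDiff' must be in [0, 1)")
    TRUE
  })

#' @rdname DmcParams-class
#' @param pMax P-value ceiling.
#' @param minAbsDiff Rate-difference floor (strict).
#' @return A \code{DmcParams} object.
#' @export
DmcParams <- function(pMax = 0.1, minAbsDiff = 0.1) {
  new("DmcParams", pMax = pMax, minAbsDiff = minAbsDiff)
}

#' Context-specific merge distances for chaining DMCs into regions
#'
#' Same-type DMCs are merged into candidate regions when separated by at
#' most the context-specific distance and no DMC of the opposite type lies
#' strictly between them. Defaults: 160 bp (CG), 240 bp (CHG), 70 bp (CHH).
#'
#' @slot maxGap Named numeric vector of maximum gaps in bp for CG, CHG, CHH.
#' @export
setClass("MergeParams",
  representation(maxGap = "numeric"),
  prototype(maxGap = c(CG = 160, CHG = 240, CHH = 70)),
  validity = function(object) {
    if (!all(CONTEXTS %in% names(object@maxGap)))
      return("'maxGap' must be named with CG, CHG and CHH entries")
    if (any(object@maxGap < 1))
      return("all 'maxGap' values must be >= 1 bp")
    TRUE
  })

#' @rdname MergeParams-class
#' @param maxGap Named numeric vector (names CG, CHG, CHH) of gaps in bp.
#' @return A \code{MergeParams} object.
#' @export
MergeParams <- function(maxGap = c(CG = 160, CHG = 240, CHH = 70)) {
  new("MergeParams", maxGap = maxGap)
}

#' Filters that promote candidate regions to DMRs
#'
#' A candidate region is reported as a DMR when it holds at least
#' \code{minDmcs} DMCs, spans at least \code{minLengthBp}, has a
#' Benjamini-Hochberg adjusted region p-value at most \code{fdrMax}, and an
#' absolute region methylation-rate difference of at least the
#' context-specific threshold (0.40 for CG; 0.20 for CHG and CHH).
#'
#' @slot minDmcs Minimum member DMC count (default 5).
#' @slot minLengthBp Minimum region length in bp (default 50).
#' @slot fdrMax FDR ceiling (default 0.05, inclusive).
#' @slot minAbsDiff Named per-context rate-difference floor (inclusive).
#' @export
setClass("DmrFilterParams",
  representation(minDmcs = "integer", minLengthBp = "numeric",
                 fdrMax = "numeric", minAbsDiff = "numeric"),
  prototype(minDmcs = 5L, minLengthBp = 50,
            fdrMax = 0.05, minAbsDiff = c(CG = 0.40, CHG = 0.20, CHH = 0.20)),
  validity = function(object) {
    if (object@minDmcs < 1L) return("'minDmcs' must be positive")
    if (object@minLengthBp <= 0) return("'minLengthBp' must be positive")
    if (!(object@fdrMax > 0 && object@fdrMax <= 1))
      return("'fdrMax' must be in (0, 1]")
    if (!all(CONTEXTS %in% names(object@minAbsDiff)))
      return("'minAbsDiff' must be named with CG, CHG and CHH entries")
    if (any(object@minAbsDiff <= 0)) return("'minAbsDiff' values must be positive")
    TRUE
  })

#' @rdname DmrFilterParams-class
#' @param minDmcs,minLengthBp,fdrMax,minAbsDiff See slot descriptions.
#' @return A \code{DmrFilterParams} object.
#' @export
DmrFilterParams <- function(minDmcs = 5L, minLengthBp = 50, fdrMax = 0.05,
                            minAbsDiff = c(CG = 0.40, CHG = 0.20, CHH = 0.20)) {
  new("DmrFilterParams", minDmcs = as.integer(minDmcs),
      minLengthBp = minLengthBp, fdrMax = fdrMax, minAbsDiff = minAbsDiff)
}

#' Smoothed methylation track for one genotype, chromosome and context
#'
#' Holds per-cytosine smoothed methylated and unmethylated read counts
#' (non-negative reals, already summed across a genotype's replicate
#' libraries) at strictly increasing positions. The smoothed methylation
#' rate is \code{meth / (meth + unmeth)}, undefined (NA) where the smoothed
#' coverage is zero.
#'
#' @slot genotype Character label (e.g. "WT", "mut").
#' @slot chrom Chromosome name.
#' @slot context One of CG, CHG, CHH.
#' @slot pos Integer vector of 1-based positions, strictly increasing.
#' @slot meth,unmeth Numeric vectors of smoothed counts.
#' @export
setClass("SmoothedTrack",
  representation(genotype = "character", chrom = "character",
                 context = "character", pos = "integer",
                 meth = "numeric", unmeth = "numeric"),
  validity = function(object) {
    n <- length(object@pos)
    if (length(object@meth) != n || length(object@unmeth) != n)
      return("'pos', 'meth' and 'unmeth' must have equal length")
    if (n > 1L && any(diff(object@pos) <= 0L))
      return("'pos' must be strictly increasing")
    if (any(object@meth < 0) || any(object@unmeth < 0))
      return("smoothed counts must be non-negative")
    if (!object@context %in% CONTEXTS)
      return("'context' must be CG, CHG or CHH")
    TRUE
  })

#' @rdname SmoothedTrack-class
#' @param genotype,chrom,context,pos,meth,unmeth See slot descriptions.
#' @return A \code{SmoothedTrack}.
#' @export
SmoothedTrack <- function(genotype, chrom, context, pos, meth, unmeth) {
  new("SmoothedTrack", genotype = genotype, chrom = chrom,
      context = context, pos = as.integer(pos),
      meth = as.numeric(meth), unmeth = as.numeric(unmeth))
}

#' Collection of smoothed tracks covering a genotype's methylome
#'
#' A named list of [SmoothedTrack-class] objects (one per chromosome and
#' context, named \code{"<chrom>:<context>"}) together with the genotype
#' label. Produced by [smoothGenotype()].
#'
#' @slot genotype Character label.
#' @slot tracks Named list of \code{SmoothedTrack} objects.
#' @export
setClass("SmoothedMethylome",
  representation(genotype = "character", tracks = "list"),
  validity = function(object) {
    ok <- vapply(object@tracks, is, logical(1), "SmoothedTrack")
    if (!all(ok)) return("all elements of 'tracks' must be SmoothedTrack")
    want <- vapply(object@tracks, function(t)
      paste0(t@chrom, ":", t@context), character(1))
    if (!identical(unname(want), names(object@tracks)) &&
        !is.null(names(object@tracks)) && length(want) &&
        any(names(object@tracks) != want))
      return("track names must be '<chrom>:<context>'")
    TRUE
  })

#' Per-locus read counts with locus lengths and library sizes
#'
#' Container for RNA-seq (or small-RNA) per-locus counts: an integer matrix
#' with loci as rows and libraries as columns, locus lengths in bp, and the
#' total mapped reads per library used for RPKM and Fisher tests.
#'
#' @slot counts Integer matrix, loci x libraries.
#' @slot lengths Numeric vector of locus lengths (bp), one per row.
#' @slot libSizes Numeric vector of total mapped reads, one per column.
#' @export
setClass("LocusCounts",
  representation(counts = "matrix", lengths = "numeric", libSizes = "numeric"),
  validity = function(object) {
    if (nrow(object@counts) != length(object@lengths))
      return("'lengths' must have one entry per locus (row)")
    if (ncol(object@counts) != length(object@libSizes))
      return("'libSizes' must have one entry per library (column)")
    if (any(object@lengths < 1)) return("locus lengths must be >= 1 bp")
    if (any(object@counts < 0)) return("counts must be non-negative")
    if (any(object@libSizes < 1)) return("library sizes must be >= 1")
    bad <- sweep(object@counts, 2L, object@libSizes, `>`)
    if (any(bad)) return("counts cannot exceed their library size")
    if (is.null(rownames(object@counts)))
      return("'counts' must have locus ids as rownames")
    TRUE
  })

#' @rdname LocusCounts-class
#' @param counts Integer matrix with locus ids as rownames and library names
#'   as colnames.
#' @param lengths Locus lengths in bp.
#' @param libSizes Total mapped reads per library; defaults to column sums.
#' @return A \code{LocusCounts} object.
#' @examples
#' m <- matrix(c(10L, 0L, 5L, 20L), 2, dimnames = list(c("g1", "g2"), c("wt1", "mut1")))
#' LocusCounts(m, lengths = c(1000, 2000))
#' @export
LocusCounts <- function(counts, lengths, libSizes = colSums(counts)) {
  storage.mode(counts) <- "integer"
  new("LocusCounts", counts = counts, lengths = as.numeric(lengths),
      libSizes = as.numeric(libSizes))
}

setMethod("show", "SmoothedTrack", function(object) {
  cat(sprintf("SmoothedTrack: %s %s %s, %d cytosines [%s..%s]\n",
              object@genotype, object@chrom, object@context,
              length(object@pos),
              if (length(object@pos)) min(object@pos) else NA,
              if (length(object@pos)) max(object@pos) else NA))
})

setMethod("show", "SmoothedMethylome", function(object) {
  cat(sprintf("SmoothedMethylome '%s': %d tracks (%s)\n",
              object@genotype, length(object@tracks),
              paste(head(names(object@tracks), 6), collapse = ", ")))
})

setMethod("show", "LocusCounts", function(object) {
  cat(sprintf("LocusCounts: %d loci x %d libraries (%s)\n",
              nrow(object@counts), ncol(object@counts),
              paste(colnames(object@counts), collapse = ", ")))
})
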