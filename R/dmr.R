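#' Call differentially methylated cytosines between two genotypes
#'
#' For every cytosine where both genotypes have a defined smoothed
#' methylation rate, the rounded smoothed methylated/unmethylated counts of
#' mutant and wild type are compared with a two-sided Fisher's exact test.
#' A cytosine is a DMC when p <= \code{pMax} and the absolute rate
#' difference (mutant minus wild type, computed from the unrounded smoothed
#' counts) strictly exceeds \code{minAbsDiff}. DMCs with positive
#' difference are hyper-DMCs, with negative difference hypo-DMCs.
#'
#' @param wt,mut [SmoothedMethylome-class] objects covering the same
#'   chromosomes and contexts.
#' @param params A [DmcParams-class].
#' @return data.frame with columns \code{chrom}, \code{pos}, \code{context},
#'   \code{type} ("hyper"/"hypo"), \code{pValue}, \code{rateWT},
#'   \code{rateMut}, \code{diff}, sorted by (chrom, context, pos).
#' @export
callDmcs <- function(wt, mut, params = DmcParams()) {
  stopifnot(is(wt, "SmoothedMethylome"), is(mut, "SmoothedMethylome"),
            is(params, "DmcParams"))
  keys <- intersect(names(tracks(wt)), names(tracks(mut)))
  out <- vector("list", length(keys))
  for (k in seq_along(keys)) {
    tw <- tracks(wt)[[keys[k]]]
    tm <- tracks(mut)[[keys[k]]]
    pos <- intersect(tw@pos, tm@pos)
    iw <- match(pos, tw@pos); im <- match(pos, tm@pos)
    mW <- tw@meth[iw]; uW <- tw@unmeth[iw]
    mM <- tm@meth[im]; uM <- tm@unmeth[im]
    totW <- mW + uW; totM <- mM + uM
    defined <- totW > 0 & totM > 0          # rate defined in both genotypes
    rateW <- mW / totW; rateM <- mM / totM
    diffR <- rateM - rateW
    cand <- which(defined & abs(diffR) > params@minAbsDiff)
    if (!length(cand)) next
    p <- fisherExactTwoSided(roundHalfUp(mM[cand]), roundHalfUp(uM[cand]),
                             roundHalfUp(mW[cand]), roundHalfUp(uW[cand]))
    keep <- p <= params@pMax
    cand <- cand[keep]
    if (!length(cand)) next
    out[[k]] <- data.frame(
      chrom = tw@chrom, pos = pos[cand], context = tw@context,
      type = ifelse(diffR[cand] > 0, "hyper", "hypo"),
      pValue = p[keep], rateWT = rateW[cand], rateMut = rateM[cand],
      diff = diffR[cand])
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) return(emptyDmcFrame())
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$context, res$pos), ]
  rownames(res) <- NULL
  res
}

emptyDmcFrame <- function() {
  data.frame(chrom = character(0), pos = integer(0), context = character(0),
             type = character(0), pValue = numeric(0), rateWT = numeric(0),
             rateMut = numeric(0), diff = numeric(0))
}

emptyRegionFrame <- function() {
  data.frame(chrom = character(0), start = integer(0), end = integer(0),
             context = character(0), type = character(0), nDmcs = integer(0))
}

#' Merge DMCs of one chromosome and context into candidate regions
#'
#' Consecutive DMCs of the same type (hyper or hypo) are chained into one
#' candidate region when their positions differ by at most the
#' context-specific maximum gap AND no DMC of the opposite type lies
#' strictly between them. Chaining is transitive over consecutive valid
#' links. Every DMC ends up in exactly one candidate region; singletons are
#' allowed here and removed later by [filterDmrs()]. Region start/end are
#' the first/last member DMC positions.
#'
#' @param dmcs data.frame as from [callDmcs()], restricted to one
#'   chromosome and one context, sorted by position.
#' @param params A [MergeParams-class].
#' @return data.frame with one row per candidate region: \code{chrom},
#'   \code{start}, \code{end}, \code{context}, \code{type}, \code{nDmcs}.
#' @export
mergeDmcs <- function(dmcs, params = MergeParams()) {
  stopifnot(is(params, "MergeParams"))
  if (nrow(dmcs) == 0L) return(emptyRegionFrame())
  if (length(unique(dmcs$chrom)) > 1L || length(unique(dmcs$context)) > 1L)
    stop("'dmcs' must cover a single chromosome and context", call. = FALSE)
  if (is.unsorted(dmcs$pos, strictly = TRUE))
    stop("'dmcs' must be sorted by strictly increasing position", call. = FALSE)
  gap <- params@maxGap[[dmcs$context[1L]]]
  n <- nrow(dmcs)
  ## link i -> i+1 within the same type's run: valid iff gap small enough
  ## and no opposite-type DMC strictly between the two positions
  regionId <- integer(n)
  nextId <- 0L
  lastIdxOfType <- c(hyper = NA_integer_, hypo = NA_integer_)
  for (i in seq_len(n)) {
    ty <- dmcs$type[i]
    prev <- lastIdxOfType[[ty]]
    link <- FALSE
    if (!is.na(prev)) {
      withinGap <- (dmcs$pos[i] - dmcs$pos[prev]) <= gap
      blocked <- prev + 1L < i &&
        any(dmcs$type[(prev + 1L):(i - 1L)] != ty)
      link <- withinGap && !blocked
    }
    if (link) {
      regionId[i] <- regionId[prev]
    } else {
      nextId <- nextId + 1L
      regionId[i] <- nextId
    }
    lastIdxOfType[[ty]] <- i
  }
  splitIdx <- split(seq_len(n), regionId)
  res <- do.call(rbind, lapply(splitIdx, function(ix) {
    data.frame(chrom = dmcs$chrom[1L],
               start = min(dmcs$pos[ix]), end = max(dmcs$pos[ix]),
               context = dmcs$context[1L], type = dmcs$type[ix[1L]],
               nDmcs = length(ix))
  }))
  res <- res[order(res$start), ]
  rownames(res) <- NULL
  res
}

#' Region-level Fisher's exact test on averaged smoothed counts
#'
#' For each candidate region and each genotype, the smoothed methylated and
#' unmethylated counts are averaged over all cytosines of the region's
#' context inside [start, end] (zero-coverage cytosines contribute zeros),
#' each average is rounded (half away from zero), and a two-sided Fisher's
#' exact test compares mutant against wild type. Region rates and their
#' difference are computed from the unrounded averages. A region with zero
#' total rounded counts in both genotypes has p = 1.
#'
#' @param regions data.frame of candidate regions (from [mergeDmcs()], any
#'   number of chromosomes/contexts).
#' @param wt,mut [SmoothedMethylome-class] objects.
#' @return \code{regions} with added columns \code{pValue}, \code{rateWT},
#'   \code{rateMut}, \code{diff}.
#' @export
testRegions <- function(regions, wt, mut) {
  if (nrow(regions) == 0L) {
    regions$pValue <- numeric(0); regions$rateWT <- numeric(0)
    regions$rateMut <- numeric(0); regions$diff <- numeric(0)
    return(regions)
  }
  mW <- uW <- mM <- uM <- numeric(nrow(regions))
  for (i in seq_len(nrow(regions))) {
    key <- paste0(regions$chrom[i], ":", regions$context[i])
    tw <- tracks(wt)[[key]]; tm <- tracks(mut)[[key]]
    if (is.null(tw) || is.null(tm))
      stop("no smoothed track for ", key, call. = FALSE)
    iw <- tw@pos >= regions$start[i] & tw@pos <= regions$end[i]
    im <- tm@pos >= regions$start[i] & tm@pos <= regions$end[i]
    if (!any(iw) || !any(im))
      stop("region without cytosines in track: ", key, call. = FALSE)
    mW[i] <- mean(tw@meth[iw]); uW[i] <- mean(tw@unmeth[iw])
    mM[i] <- mean(tm@meth[im]); uM[i] <- mean(tm@unmeth[im])
  }
  regions$pValue <- fisherExactTwoSided(roundHalfUp(mM), roundHalfUp(uM),
                                        roundHalfUp(mW), roundHalfUp(uW))
  rW <- ifelse(mW + uW > 0, mW / (mW + uW), NA_real_)
  rM <- ifelse(mM + uM > 0, mM / (mM + uM), NA_real_)
  regions$rateWT <- rW
  regions$rateMut <- rM
  regions$diff <- rM - rW
  regions
}

#' Benjamini-Hochberg adjusted p-values (FDR)
#'
#' Step-up false-discovery-rate adjustment: the adjusted value of the i-th
#' order statistic is \code{min_{j >= i} (m * p_(j) / j)}, capped at 1.
#'
#' @param p Numeric vector of p-values in [0, 1].
#' @return Numeric vector of adjusted values, in the input order.
#' @export
benjaminiHochberg <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  p.adjust(p, method = "BH")
}

#' Filter candidate regions into DMRs
#'
#' Keeps regions with at least \code{minDmcs} member DMCs, length at least
#' \code{minLengthBp}, FDR at most \code{fdrMax}, and absolute region rate
#' difference at least the context-specific threshold. FDR must have been
#' computed across all candidate regions of each context (see
#' [callDmrs()]).
#'
#' @param regions data.frame of tested regions with an \code{fdr} column.
#' @param params A [DmrFilterParams-class].
#' @return The subset of \code{regions} passing all filters.
#' @export
filterDmrs <- function(regions, params = DmrFilterParams()) {
  stopifnot(is(params, "DmrFilterParams"))
  if (nrow(regions) == 0L) return(regions)
  stopifnot("fdr" %in% names(regions))
  thr <- params@minAbsDiff[regions$context]
  keep <- regions$nDmcs >= params@minDmcs &
    (regions$end - regions$start + 1) >= params@minLengthBp &
    regions$fdr <= params@fdrMax &
    !is.na(regions$diff) & abs(regions$diff) >= thr
  res <- regions[keep, , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Full DMR-calling pipeline between two genotypes
#'
#' Runs the complete differential-methylation procedure: DMC calling on the
#' smoothed methylomes, context-specific merging of DMCs into candidate
#' regions, region-level Fisher testing, Benjamini-Hochberg correction
#' within each context across all candidate regions of that context, and
#' final filtering.
#'
#' @param wt,mut [SmoothedMethylome-class] objects (see [smoothGenotype()]).
#' @param dmcParams,mergeParams,filterParams Parameter objects.
#' @param contexts Contexts to analyse (default all three).
#' @return A list with elements \code{dmcs} (data.frame), \code{candidates}
#'   (all merged regions with test results and FDR) and \code{dmrs} (a
#'   [GenomicRanges::GRanges] with metadata columns \code{context},
#'   \code{type}, \code{nDmcs}, \code{pValue}, \code{fdr}, \code{rateWT},
#'   \code{rateMut}, \code{diff}).
#' @export
callDmrs <- function(wt, mut, dmcParams = DmcParams(),
                     mergeParams = MergeParams(),
                     filterParams = DmrFilterParams(),
                     contexts = CONTEXTS) {
  dmcs <- callDmcs(wt, mut, dmcParams)
  dmcs <- dmcs[dmcs$context %in% contexts, , drop = FALSE]
  groups <- split(dmcs, list(dmcs$chrom, dmcs$context), drop = TRUE)
  cands <- lapply(groups, mergeDmcs, params = mergeParams)
  cands <- if (length(cands)) do.call(rbind, cands) else emptyRegionFrame()
  rownames(cands) <- NULL
  cands <- testRegions(cands, wt, mut)
  cands$fdr <- rep(NA_real_, nrow(cands))
  for (cx in unique(cands$context)) {
    i <- cands$context == cx
    cands$fdr[i] <- benjaminiHochberg(cands$pValue[i])
  }
  dmrs <- filterDmrs(cands, filterParams)
  list(dmcs = dmcs, candidates = cands, dmrs = dmrFrameToGRanges(dmrs))
}

dmrFrameToGRanges <- function(df) {
  gr <- GenomicRanges::GRanges(
    seqnames = if (nrow(df)) df$chrom else character(0),
    ranges = IRanges::IRanges(start = df$start, end = df$end))
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    context = df$context, type = df$type, nDmcs = df$nDmcs,
    pValue = df$pValue, fdr = df$fdr, rateWT = df$rateWT,
    rateMut = df$rateMut, diff = df$diff)
  gr
}

#' Map DMRs to overlapping genomic features
#'
#' A DMR maps to a feature when at least one nucleotide overlaps, i.e.
#' \code{max(starts) <= min(ends)} on 1-based inclusive coordinates. A DMR
#' may map to several features.
#'
#' @param dmrs \code{GRanges} of DMRs (as from [callDmrs()]).
#' @param features \code{GRanges} of annotated features (see
#'   [readFeatures()]).
#' @return data.frame with columns \code{dmr} (index into \code{dmrs}),
#'   \code{feature} (index into \code{features}) and \code{featureId} (the
#'   feature's \code{id} metadata column, if present).
#' @export
mapDmrsToFeatures <- function(dmrs, features) {
  hits <- GenomicRanges::findOverlaps(dmrs, features, minoverlap = 1L,
                                      ignore.strand = TRUE)
  ids <- S4Vectors::mcols(features)$id
  data.frame(dmr = S4Vectors::queryHits(hits),
             feature = S4Vectors::subjectHits(hits),
             featureId = if (is.null(ids)) NA_character_
                         else ids[S4Vectors::subjectHits(hits)])
}

#' Overlap between hypomethylated DMRs and upregulated loci
#'
#' Counts, per sequence context, how many upregulated features are
#' overlapped by at least one hypo-DMR of that context — the quantities
#' shown in a Venn diagram of hypo-DMRs against upregulated loci.
#'
#' @param hypoDmrs \code{GRanges} of hypo-DMRs with a \code{context}
#'   metadata column (hyper-DMRs, if present, are dropped using the
#'   \code{type} column).
#' @param upFeatures \code{GRanges} of upregulated features.
#' @return data.frame with one row per context: \code{context},
#'   \code{nDmrs}, \code{nUp}, \code{nOverlap} (upregulated features hit by
#'   >= 1 hypo-DMR of that context).
#' @export
overlapSummary <- function(hypoDmrs, upFeatures) {
  mc <- S4Vectors::mcols(hypoDmrs)
  if (!is.null(mc$type)) hypoDmrs <- hypoDmrs[mc$type == "hypo"]
  res <- lapply(CONTEXTS, function(cx) {
    d <- hypoDmrs[S4Vectors::mcols(hypoDmrs)$context == cx]
    hit <- unique(S4Vectors::subjectHits(
      GenomicRanges::findOverlaps(d, upFeatures, minoverlap = 1L,
                                  ignore.strand = TRUE)))
    data.frame(context = cx, nDmrs = length(d), nUp = length(upFeatures),
               nOverlap = length(hit))
  })
  do.call(rbind, res)
}
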