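#' Methylation metaprofile around feature ends
#'
#' Aligns stranded features at their 5' or 3' end and averages methylation
#' in fixed-width bins from \code{flank} bp upstream to \code{flank} bp
#' downstream of the anchor. Orientation is strand-aware: upstream of a
#' minus-strand feature is genomically downstream. Each bin's value is by
#' default the coverage-weighted methylation rate over all cytosines of the
#' requested context falling in that bin across all features
#' (\code{sum(meth) / sum(meth + unmeth)}); with
#' \code{weighted = FALSE} it is the unweighted mean of per-cytosine rates.
#' Bins containing no covered cytosine emit \code{NA}.
#'
#' @param cytosines data.frame of per-cytosine counts (columns
#'   \code{chrom}, \code{pos}, \code{context}, \code{meth}, \code{unmeth}).
#' @param features \code{GRanges} with strand.
#' @param context Context profiled (CG, CHG or CHH).
#' @param flank Flank size in bp (default 3000), divisible by \code{bin}.
#' @param bin Bin width in bp (default 100).
#' @param anchor \code{"5prime"} or \code{"3prime"}.
#' @param weighted Coverage-weighted bin rate (default TRUE).
#' @return data.frame: \code{bin} (index, 1-based from the most upstream
#'   bin), \code{offset} (bp of the bin's upstream edge relative to the
#'   anchor), \code{value}, \code{nCytosines}.
#' @export
methylationMetaprofile <- function(cytosines, features, context,
                                   flank = 3000L, bin = 100L,
                                   anchor = c("5prime", "3prime"),
                                   weighted = TRUE) {
  anchor <- match.arg(anchor)
  stopifnot(flank %% bin == 0)
  checkContext(context)
  cyt <- cytosines[cytosines$context == context, , drop = FALSE]
  nBins <- as.integer(2L * flank / bin)
  sumM <- sumT <- sumR <- nC <- numeric(nBins)
  chromPos <- split(seq_len(nrow(cyt)), cyt$chrom)
  strand <- as.character(GenomicRanges::strand(features))
  strand[strand == "*"] <- "+"
  fstart <- GenomicRanges::start(features)
  fend <- GenomicRanges::end(features)
  fchrom <- as.character(GenomicRanges::seqnames(features))
  for (f in seq_along(features)) {
    idx <- chromPos[[fchrom[f]]]
    if (is.null(idx)) next
    minus <- strand[f] == "-"
    anchorPos <- if ((anchor == "5prime") != minus) fstart[f] else fend[f]
    pos <- cyt$pos[idx]
    ## signed offset in transcription orientation
    off <- if (minus) anchorPos - pos else pos - anchorPos
    inRange <- off >= -flank & off < flank
    if (!any(inRange)) next
    b <- (off[inRange] + flank) %/% bin + 1L
    i <- idx[inRange]
    tot <- cyt$meth[i] + cyt$unmeth[i]
    covd <- tot > 0
    sumM <- sumM + tabSum(b[covd], cyt$meth[i][covd], nBins)
    sumT <- sumT + tabSum(b[covd], tot[covd], nBins)
    sumR <- sumR + tabSum(b[covd], (cyt$meth[i] / tot)[covd], nBins)
    nC <- nC + tabSum(b[covd], rep(1, sum(covd)), nBins)
  }
  value <- if (weighted) ifelse(sumT > 0, sumM / sumT, NA_real_)
           else ifelse(nC > 0, sumR / nC, NA_real_)
  data.frame(bin = seq_len(nBins),
             offset = seq(-flank, flank - bin, by = bin),
             value = value, nCytosines = as.integer(nC))
}

## sum `w` within integer bins 1..nBins
tabSum <- function(b, w, nBins) {
  out <- numeric(nBins)
  s <- vapply(split(w, b), sum, numeric(1))
  out[as.integer(names(s))] <- s
  out
}

#' Normalize small-RNA counts to reads per million 18-26-nt reads
#'
#' Library comparisons use counts scaled to the library's total number of
#' mapped reads in the 18-26-nt size range: \code{value = raw * 1e6 /
#' total1826}.
#'
#' @param x Raw counts (any numeric structure).
#' @param total1826 Total 18-26-nt mapped reads in the library (> 0).
#' @return \code{x} scaled to reads per million 18-26-nt reads.
#' @examples
#' normalizeSrna(100, 2e6)  # 50
#' @export
normalizeSrna <- function(x, total1826) {
  if (length(total1826) != 1L || total1826 <= 0)
    stop("'total1826' must be a positive scalar", call. = FALSE)
  x * 1e6 / total1826
}

#' Length-scaled siRNA profile over transposable elements
#'
#' Each TE body is divided into \code{bodyBins} bins of equal (possibly
#' fractional) length — position offset \code{o} in a TE of length L maps
#' to bin \code{floor(o / L * bodyBins)}, capped at the last bin — while
#' the upstream and downstream flanks use \code{flank} one-nucleotide bins.
#' Orientation is strand-aware. Per TE and bin the mean coverage of the
#' bin's positions is taken; the profile value is the mean across TEs
#' having at least one position in that bin.
#'
#' @param coverage data.frame of per-position normalized siRNA coverage:
#'   columns \code{chrom}, \code{pos}, \code{value}; positions absent from
#'   the table count as zero coverage.
#' @param tes \code{GRanges} of TEs with strand.
#' @param flank Flank size in bp = number of 1-nt flank bins (default 2000).
#' @param bodyBins Number of scaled body bins (default 2000).
#' @return data.frame: \code{bin} (1..flank upstream, then body, then
#'   downstream), \code{zone} ("upstream"/"body"/"downstream"),
#'   \code{value}, \code{nTes}.
#' @export
scaledTeProfile <- function(coverage, tes, flank = 2000L, bodyBins = 2000L) {
  nBins <- as.integer(flank + bodyBins + flank)
  total <- numeric(nBins)
  nTes <- numeric(nBins)
  covMap <- split(seq_len(nrow(coverage)), coverage$chrom)
  strand <- as.character(GenomicRanges::strand(tes))
  strand[strand == "*"] <- "+"
  tstart <- GenomicRanges::start(tes)
  tend <- GenomicRanges::end(tes)
  tchrom <- as.character(GenomicRanges::seqnames(tes))
  for (f in seq_along(tes)) {
    L <- tend[f] - tstart[f] + 1L
    minus <- strand[f] == "-"
    lo <- tstart[f] - flank; hi <- tend[f] + flank
    idx <- covMap[[tchrom[f]]]
    pos <- if (is.null(idx)) integer(0) else coverage$pos[idx]
    sel <- which(pos >= lo & pos <= hi)
    val <- numeric(hi - lo + 1L)           # dense, zeros where no coverage
    if (length(sel)) val[pos[sel] - lo + 1L] <- coverage$value[idx][sel]
    gpos <- lo:hi
    off <- if (minus) tend[f] - gpos else gpos - tstart[f]  # 5'-oriented
    if (minus) { val <- rev(val); off <- rev(off) }
    b <- integer(length(off))
    up <- off < 0
    down <- off >= L
    body <- !up & !down
    b[up] <- off[up] + flank + 1L
    b[body] <- flank + pmin((off[body] * bodyBins) %/% L, bodyBins - 1) + 1L
    b[down] <- flank + bodyBins + (off[down] - L) + 1L
    perBin <- vapply(split(val, b), mean, numeric(1))
    ib <- as.integer(names(perBin))
    total[ib] <- total[ib] + perBin
    nTes[ib] <- nTes[ib] + 1
  }
  zone <- rep(c("upstream", "body", "downstream"),
              c(flank, bodyBins, flank))
  data.frame(bin = seq_len(nBins), zone = zone,
             value = ifelse(nTes > 0, total / nTes, NA_real_),
             nTes = as.integer(nTes))
}
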