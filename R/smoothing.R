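## Savitzky-Golay convolution coefficients for the window centre:
## row of e1' (X'X)^-1 X' with X = outer(offsets, 0:degree, `^`).
sgCenterCoefficients <- function(window, degree) {
  h <- (window - 1L) %/% 2L
  x <- seq(-h, h)
  X <- outer(x, 0:degree, `^`)
  qr.solve(crossprod(X), t(X))[1L, ]
}

## Least-squares degree-`degree` fit over (x, y), evaluated at x = 0.
## Degree is reduced when the window holds fewer points than coefficients.
polyFitAtZero <- function(x, y, degree) {
  d <- min(degree, length(x) - 1L)
  X <- outer(x, 0:d, `^`)
  as.numeric(qr.solve(crossprod(X), crossprod(X, y))[1L])
}

#' Savitzky-Golay smoothing of an ordered count sequence
#'
#' Smooths a sequence by least-squares fitting a polynomial of degree
#' \code{degree} over a sliding window of \code{window} neighbouring entries
#' and taking the fitted value at the window centre. At sequence ends, where
#' a full centred window is unavailable, the fit uses the truncated window of
#' available entries (this preserves exact reproduction of polynomials up to
#' \code{degree} at every position, boundaries included). Because the values
#' being smoothed are read counts, the output is clamped at zero from below
#' by default.
#'
#' @param values Numeric vector of finite values in track order.
#' @param params A [SmoothingParams-class] (default: quadratic, window 11).
#' @param clamp Clamp negative fitted values to 0 (default TRUE).
#' @return Numeric vector of smoothed values, same length as \code{values}.
#' @examples
#' savitzkyGolaySmooth(rep(5, 15))          # constant preserved
#' savitzkyGolaySmooth(0:14)                # linear ramp preserved
#' @export
savitzkyGolaySmooth <- function(values, params = SmoothingParams(),
                                clamp = TRUE) {
  stopifnot(is(params, "SmoothingParams"))
  values <- as.numeric(values)
  if (length(values) == 0L) return(numeric(0))
  if (any(!is.finite(values)))
    stop("'values' must be finite", call. = FALSE)
  n <- length(values)
  w <- params@window
  d <- params@degree
  h <- (w - 1L) %/% 2L
  out <- numeric(n)
  if (n >= w) {
    cc <- sgCenterCoefficients(w, d)
    ## interior: convolution with the centre coefficient row
    interior <- (h + 1L):(n - h)
    conv <- stats::filter(values, rev(cc), sides = 2L)
    out[interior] <- conv[interior]
    ## boundaries: truncated-window fits
    for (i in seq_len(h)) {
      idx <- 1L:(i + h)
      out[i] <- polyFitAtZero(idx - i, values[idx], d)
      j <- n - i + 1L
      idx <- (j - h):n
      out[j] <- polyFitAtZero(idx - j, values[idx], d)
    }
  } else {
    for (i in seq_len(n)) {
      idx <- max(1L, i - h):min(n, i + h)
      out[i] <- polyFitAtZero(idx - i, values[idx], d)
    }
  }
  if (clamp) out <- pmax(out, 0)
  out
}

#' Smooth a genotype's methylome from its replicate libraries
#'
#' For each chromosome and sequence context, the methylated and
#' unmethylated read counts of each library are smoothed independently with
#' [savitzkyGolaySmooth()] over index-adjacent cytosines of the same context
#' in genomic order; the smoothed counts are then summed position-wise
#' across the genotype's libraries. Positions present in one library but
#' absent from another are treated as zero-count in the missing library.
#' Zero-coverage cytosines are legitimate smoothing neighbours and are
#' retained.
#'
#' @param libraries List of per-library cytosine tables, each a data.frame
#'   with columns \code{chrom}, \code{pos}, \code{strand}, \code{context},
#'   \code{meth}, \code{unmeth} (as returned by [readCytosineTable()] or
#'   [simulateMethylome()]).
#' @param genotype Genotype label stored on the result.
#' @param params A [SmoothingParams-class].
#' @param pool If TRUE, raw counts are pooled across libraries before a
#'   single smoothing pass (alternative replicate handling; default FALSE
#'   smooths each library independently, then sums).
#' @return A [SmoothedMethylome-class] with one track per (chromosome,
#'   context) present in any library.
#' @export
smoothGenotype <- function(libraries, genotype = "genotype",
                           params = SmoothingParams(), pool = FALSE) {
  stopifnot(length(libraries) >= 1L)
  libraries <- lapply(libraries, function(x) {
    x <- as.data.frame(x)
    stopifnot(all(c("chrom", "pos", "context", "meth", "unmeth") %in% names(x)))
    x
  })
  chromSets <- lapply(libraries, function(x) unique(x$chrom))
  if (length(libraries) > 1L &&
      length(unique(vapply(chromSets, function(s)
        paste(sort(s), collapse = ","), character(1)))) > 1L)
    warning("libraries cover different chromosome sets; using their union")

  keys <- unique(do.call(rbind, lapply(libraries, function(x)
    unique(x[, c("chrom", "context")]))))
  keys <- keys[order(keys$chrom, keys$context), , drop = FALSE]

  trackList <- vector("list", nrow(keys))
  names(trackList) <- paste0(keys$chrom, ":", keys$context)
  for (k in seq_len(nrow(keys))) {
    ch <- keys$chrom[k]; cx <- keys$context[k]
    subs <- lapply(libraries, function(x)
      x[x$chrom == ch & x$context == cx, c("pos", "meth", "unmeth")])
    pos <- sort(unique(unlist(lapply(subs, `[[`, "pos"))))
    n <- length(pos)
    meth <- matrix(0, n, length(subs))
    unmeth <- matrix(0, n, length(subs))
    for (j in seq_along(subs)) {
      i <- match(subs[[j]]$pos, pos)
      meth[i, j] <- subs[[j]]$meth
      unmeth[i, j] <- subs[[j]]$unmeth
    }
    if (pool) {
      sm <- savitzkyGolaySmooth(rowSums(meth), params)
      su <- savitzkyGolaySmooth(rowSums(unmeth), params)
    } else {
      sm <- rowSums(apply(meth, 2L, savitzkyGolaySmooth, params = params,
                          simplify = FALSE) |> vapplyCols(n))
      su <- rowSums(apply(unmeth, 2L, savitzkyGolaySmooth, params = params,
                          simplify = FALSE) |> vapplyCols(n))
    }
    trackList[[k]] <- SmoothedTrack(genotype, ch, cx, pos, sm, su)
  }
  new("SmoothedMethylome", genotype = genotype, tracks = trackList)
}

vapplyCols <- function(lst, n) {
  vapply(lst, identity, numeric(n))
}
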