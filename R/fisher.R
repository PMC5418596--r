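#' Two-sided Fisher's exact test for 2x2 tables
#'
#' Computes the standard two-sided Fisher's exact p-value for the table
#' \code{rbind(c(a, b), c(c, d))}: the sum of hypergeometric probabilities,
#' conditional on the table margins, of all tables at least as extreme as
#' (no more probable than) the observed one. Ties in probability are
#' resolved with a small relative tolerance, following the convention of
#' [stats::fisher.test()]. An all-zero table has p = 1 by convention.
#'
#' All four arguments are recycled to a common length, so many tables can
#' be tested in one call; this vectorised form is what the DMR caller uses
#' per cytosine and per region.
#'
#' @param a,b,c,d Non-negative integer vectors: cell counts, row-wise.
#' @return Numeric vector of p-values in (0, 1].
#' @examples
#' fisherExactTwoSided(2, 0, 0, 2)    # 1/3
#' fisherExactTwoSided(10, 0, 0, 10)  # 2/choose(20, 10)
#' @export
fisherExactTwoSided <- function(a, b, c, d) {
  n <- max(length(a), length(b), length(c), length(d))
  a <- rep_len(as.numeric(a), n); b <- rep_len(as.numeric(b), n)
  cc <- rep_len(as.numeric(c), n); d <- rep_len(as.numeric(d), n)
  if (any(a < 0 | b < 0 | cc < 0 | d < 0) ||
      any(a != floor(a) | b != floor(b) | cc != floor(cc) | d != floor(d)))
    stop("cell counts must be non-negative integers", call. = FALSE)
  p <- numeric(n)
  relErr <- 1 + 1e-7
  for (i in seq_len(n)) {
    r1 <- a[i] + b[i]          # row margins
    r2 <- cc[i] + d[i]
    s1 <- a[i] + cc[i]         # first column margin
    if (r1 + r2 == 0) { p[i] <- 1; next }
    lo <- max(0, s1 - r2)
    hi <- min(r1, s1)
    support <- lo:hi
    probs <- dhyper(support, r1, r2, s1)
    pObs <- probs[support == a[i]]
    p[i] <- min(1, sum(probs[probs <= pObs * relErr]))
  }
  p
}
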