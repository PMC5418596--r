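#' @import methods
#' @importFrom stats dhyper p.adjust phyper pnorm rbeta rbinom rlnorm rnbinom
#'   rpois runif rmultinom
#' @importFrom utils head tail
NULL

CONTEXTS <- c("CG", "CHG", "CHH")

#' Round half away from zero
#'
#' Rounding used wherever smoothed read counts enter a Fisher's exact test.
#' Unlike [base::round()], which rounds half to even, values with a
#' fractional part of exactly 0.5 are rounded away from zero (4.5 -> 5).
#'
#' @param x Numeric vector.
#' @return Numeric vector of rounded values.
#' @examples
#' roundHalfUp(c(0.5, 1.5, 2.49, 4.5))
#' @export
roundHalfUp <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

## Evaluate `expr` under a temporary RNG state seeded with `seed`,
## restoring the caller's RNG state afterwards.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

## Derive a stable child seed from a global seed and a stream label, so
## that adding a generator does not shift the random streams of others.
childSeed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 48271 + h * 1009) %% 2147483587) + 1L
}

stopifnot_scalar <- function(x, name = deparse(substitute(x))) {
  if (length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite scalar", name), call. = FALSE)
  invisible(x)
}

checkContext <- function(context) {
  bad <- setdiff(unique(as.character(context)), CONTEXTS)
  if (length(bad))
    stop("unknown methylation context token(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  invisible(context)
}
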