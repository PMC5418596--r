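#' Accessors for methylDMR containers
#'
#' @param x A methylDMR object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("genotype", function(x) standardGeneric("genotype"))

#' @rdname accessors
#' @export
setGeneric("tracks", function(x) standardGeneric("tracks"))

#' @rdname accessors
#' @export
setGeneric("methRate", function(x) standardGeneric("methRate"))

#' @rdname accessors
#' @export
setGeneric("counts", function(x) standardGeneric("counts"))

#' @rdname accessors
#' @export
setGeneric("locusLengths", function(x) standardGeneric("locusLengths"))

#' @rdname accessors
#' @export
setGeneric("libSizes", function(x) standardGeneric("libSizes"))

#' @rdname accessors
#' @export
setMethod("genotype", "SmoothedTrack", function(x) x@genotype)

#' @rdname accessors
#' @export
setMethod("genotype", "SmoothedMethylome", function(x) x@genotype)

#' @rdname accessors
#' @export
setMethod("tracks", "SmoothedMethylome", function(x) x@tracks)

#' Smoothed methylation rate of a track
#'
#' \code{meth / (meth + unmeth)} per cytosine; \code{NA} where the smoothed
#' coverage is zero (the rate is undefined there).
#'
#' @param x A [SmoothedTrack-class].
#' @return Numeric vector in [0, 1] with NA at zero-coverage cytosines.
#' @export
setMethod("methRate", "SmoothedTrack", function(x) {
  tot <- x@meth + x@unmeth
  ifelse(tot > 0, x@meth / tot, NA_real_)
})

#' @rdname accessors
#' @export
setMethod("counts", "LocusCounts", function(x) x@counts)

#' @rdname accessors
#' @export
setMethod("locusLengths", "LocusCounts", function(x) x@lengths)

#' @rdname accessors
#' @export
setMethod("libSizes", "LocusCounts", function(x) x@libSizes)
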