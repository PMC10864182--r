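#' Accessors for package classes
#'
#' `ldVariants()` and `ldR()` return the variant table and correlation matrix
#' of an [LDMatrix-class]; `pip()` and `credibleSet()` return the per-member
#' PIP vector (named by variant id) and the ordered 99 percent credible set
#' of a [PosteriorSet-class]; `patObserved()`, `patExpected()` and
#' `patRatioValue()` return the components of a [PATResult-class];
#' `isRobust()` returns the locus verdict of a [SlalomReport-class].
#'
#' @param x an object of the documented class.
#' @return See the individual descriptions.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("ldVariants", function(x) standardGeneric("ldVariants"))
#' @rdname accessors
#' @export
setGeneric("ldR", function(x) standardGeneric("ldR"))
#' @rdname accessors
#' @export
setGeneric("pip", function(x) standardGeneric("pip"))
#' @rdname accessors
#' @export
setGeneric("credibleSet", function(x) standardGeneric("credibleSet"))
#' @rdname accessors
#' @export
setGeneric("patObserved", function(x) standardGeneric("patObserved"))
#' @rdname accessors
#' @export
setGeneric("patExpected", function(x) standardGeneric("patExpected"))
#' @rdname accessors
#' @export
setGeneric("patRatioValue", function(x) standardGeneric("patRatioValue"))
#' @rdname accessors
#' @export
setGeneric("isRobust", function(x) standardGeneric("isRobust"))

#' @rdname accessors
setMethod("ldVariants", "LDMatrix", function(x) x@variants)
#' @rdname accessors
setMethod("ldR", "LDMatrix", function(x) x@r)
#' @rdname accessors
setMethod("pip", "PosteriorSet",
    function(x) setNames(x@members$pip, x@members$snp))
#' @rdname accessors
setMethod("credibleSet", "PosteriorSet", function(x) x@credibleSet)
#' @rdname accessors
setMethod("patObserved", "PATResult", function(x) x@observed)
#' @rdname accessors
setMethod("patExpected", "PATResult", function(x) x@expected)
#' @rdname accessors
setMethod("patRatioValue", "PATResult", function(x) x@ratio)
#' @rdname accessors
setMethod("isRobust", "SlalomReport", function(x) x@robust)

setMethod("show", "LDMatrix", function(object) {
    cat(sprintf("LDMatrix with %d variants (chr %s)\n",
        nrow(object@variants),
        paste(unique(object@variants$chr), collapse = ",")))
})

setMethod("show", "TransferSet", function(object) {
    cat(sprintf("TransferSet: lead %s, %d member(s) within 50 kb\n",
        object@lead$snp, nrow(object@members)))
})

setMethod("show", "PATResult", function(object) {
    cat(sprintf(
        "PATResult: observed %d / expected %.2f = ratio %.3f (95%% CI %.3f-%.3f), %d loci\n",
        object@observed, object@expected, object@ratio,
        object@ciLow, object@ciHigh, nrow(object@perLocus)))
})

setMethod("show", "FineMapLocus", function(object) {
    cat(sprintf("FineMapLocus: lead %s, %d members, %d ancestry group(s)\n",
        object@lead, nrow(object@members), ncol(object@beta)))
})

setMethod("show", "PosteriorSet", function(object) {
    cat(sprintf("PosteriorSet (%s): %d members, 99%% credible set of %d\n",
        object@mode, nrow(object@members), length(object@credibleSet)))
})

setMethod("show", "SlalomReport", function(object) {
    if (!object@applied)
        cat(sprintf("SlalomReport: not applied (max PIP %.3f <= 0.1)\n",
            object@maxPip))
    else
        cat(sprintf("SlalomReport: %d variants scanned, %d outlier(s) -> %s\n",
            nrow(object@table), sum(object@table$outlier, na.rm = TRUE),
            if (isTRUE(object@robust)) "robust" else "not robust"))
})
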