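#' @import methods
#' @importFrom stats pchisq pnorm qchisq rnorm runif rbeta median quantile
#'   setNames complete.cases lm coef density mad approx
#' @importFrom utils read.table write.table head
NULL

.VARIANT_COLS <- c("snp", "chr", "bp", "a1", "a2")

.check_variant_table <- function(v) {
    msg <- NULL
    if (!is.data.frame(v))
        return("'variants' must be a data.frame")
    miss <- setdiff(.VARIANT_COLS, names(v))
    if (length(miss))
        msg <- c(msg, paste0("variant table lacks column(s): ",
                             paste(miss, collapse = ", ")))
    if (is.null(msg) && nrow(v)) {
        if (any(v$bp < 1)) msg <- c(msg, "positions must be >= 1 (1-based)")
        if (any(v$a1 == v$a2)) msg <- c(msg, "effect and other allele must differ")
        if (anyDuplicated(v$snp)) msg <- c(msg, "duplicated variant ids")
    }
    msg
}

#' Variant-indexed LD correlation matrix
#'
#' An ancestry-specific linkage-disequilibrium reference: an ordered variant
#' table and the matching square matrix of signed allelic correlations r.
#' Validity enforces symmetry, a unit diagonal, |r| <= 1 and positive
#' semi-definiteness within a tolerance of 1e-8 on the minimum eigenvalue.
#'
#' @slot variants data.frame with columns `snp`, `chr`, `bp`, `a1`, `a2`,
#'   one row per variant, in matrix row order.
#' @slot r numeric matrix of signed correlations, `dimnames` set to the
#'   variant ids.
#'
#' @seealso [simulateLDMatrix()], [readLDMatrix()]
#' @export
setClass("LDMatrix",
    representation(variants = "data.frame", r = "matrix"))

setValidity("LDMatrix", function(object) {
    v <- object@variants
    r <- object@r
    msg <- .check_variant_table(v)
    if (nrow(r) != ncol(r)) msg <- c(msg, "r must be square")
    if (nrow(r) != nrow(v)) msg <- c(msg, "r dimension must match variant count")
    if (nrow(r)) {
        if (max(abs(r - t(r))) > 1e-8) msg <- c(msg, "r must be symmetric")
        if (max(abs(diag(r) - 1)) > 1e-8) msg <- c(msg, "diagonal of r must be 1")
        if (max(abs(r)) > 1 + 1e-8) msg <- c(msg, "|r| must be <= 1")
        ev <- min(eigen(r, symmetric = TRUE, only.values = TRUE)$values)
        if (ev < -1e-8)
            msg <- c(msg, sprintf("r not positive semi-definite (min eigenvalue %.3g)", ev))
    }
    if (is.null(msg)) TRUE else msg
})

#' Transferability credible set
#'
#' The lead variant of a published discovery locus together with its
#' correlated proxy set: all variants with r^2 >= 0.8 to the lead within a
#' 50 kb window whose discovery p-value is below 100 times the lead p-value.
#' The member count `N` (lead included) drives the penalized transferability
#' threshold.
#'
#' @slot lead one-row data.frame describing the discovery lead (canonical
#'   summary-statistic columns).
#' @slot members data.frame of member variants with their discovery
#'   statistics and `r2` to the lead; the lead is always a member.
#'
#' @seealso [buildTransferCredibleSet()], [callTransferable()]
#' @export
setClass("TransferSet",
    representation(lead = "data.frame", members = "data.frame"))

setValidity("TransferSet", function(object) {
    msg <- NULL
    if (nrow(object@lead) != 1L) msg <- c(msg, "lead must be a single row")
    if (!nrow(object@members)) msg <- c(msg, "members must include the lead")
    else {
        if (!object@lead$snp %in% object@members$snp)
            msg <- c(msg, "lead must be among the members")
        if (any(abs(object@members$bp - object@lead$bp) > 5e4))
            msg <- c(msg, "members must lie within 50 kb of the lead")
    }
    if (is.null(msg)) TRUE else msg
})

#' Power-adjusted transferability result
#'
#' Observed and power-expected counts of transferable discovery loci in a
#' target ancestry group, their ratio (the PAT ratio) and a percentile
#' bootstrap confidence interval, with the per-locus records underlying the
#' sums.
#'
#' @slot observed number of loci called transferable.
#' @slot expected sum of per-locus detection powers.
#' @slot ratio observed / expected.
#' @slot ciLow,ciHigh bootstrap 95 percent confidence limits for the ratio.
#' @slot perLocus data.frame with one row per assessable locus: credible-set
#'   size `n_set`, `power`, minimum target p-value, `transferable` and
#'   `nontransferable` flags.
#'
#' @seealso [patRatio()]
#' @export
setClass("PATResult",
    representation(observed = "numeric", expected = "numeric",
                   ratio = "numeric", ciLow = "numeric", ciHigh = "numeric",
                   perLocus = "data.frame"))

setValidity("PATResult", function(object) {
    msg <- NULL
    if (object@expected < 0) msg <- c(msg, "expected must be nonnegative")
    if (object@observed < 0) msg <- c(msg, "observed must be nonnegative")
    if (nrow(object@perLocus)) {
        p <- object@perLocus$power
        if (any(p < 0 | p > 1)) msg <- c(msg, "per-locus power must lie in [0, 1]")
        if (object@expected > nrow(object@perLocus) + 1e-8)
            msg <- c(msg, "expected cannot exceed the number of loci")
    }
    if (is.null(msg)) TRUE else msg
})

#' Fine-mapping locus
#'
#' All variants correlated at r^2 > 0.1 with a lead variant, their signed LD
#' to each other, and per-ancestry-group association statistics aligned to
#' the member order (NA where a group lacks the variant).
#'
#' @slot lead id of the lead variant.
#' @slot members data.frame (`snp`, `chr`, `bp`) ordered by position.
#' @slot beta,se numeric matrices, one row per member, one column per
#'   ancestry group; NA where unavailable.
#' @slot ld [LDMatrix-class] restricted to the members.
#'
#' @seealso [extractLocus()], [posteriorPips()]
#' @export
setClass("FineMapLocus",
    representation(lead = "character", members = "data.frame",
                   beta = "matrix", se = "matrix", ld = "LDMatrix"))

setValidity("FineMapLocus", function(object) {
    msg <- NULL
    n <- nrow(object@members)
    if (!object@lead %in% object@members$snp) msg <- c(msg, "lead must be a member")
    if (nrow(object@beta) != n || nrow(object@se) != n)
        msg <- c(msg, "beta/se rows must match member count")
    if (!identical(dim(object@beta), dim(object@se)))
        msg <- c(msg, "beta and se must have identical dimensions")
    if (nrow(object@ld@variants) != n)
        msg <- c(msg, "LD matrix must cover exactly the members")
    if (is.null(msg)) TRUE else msg
})

#' Per-locus posterior inclusion probabilities and 99 percent credible set
#'
#' Posterior inclusion probabilities (PIPs) over the members of a fine-mapped
#' locus, the per-member prior and cross-ancestry heterogeneity, and the
#' smallest descending-PIP prefix whose cumulative probability reaches 0.99.
#'
#' @slot members data.frame with per-member `snp`, `bp`, `chisq`, `i2`,
#'   `prior`, `pip` and logical `in_cs`.
#' @slot credibleSet character vector of member ids in descending PIP order.
#' @slot mode `"multi"` (heterogeneity prior applied) or `"single"`.
#'
#' @seealso [posteriorPips()], [credibleSetSize()]
#' @export
setClass("PosteriorSet",
    representation(members = "data.frame", credibleSet = "character",
                   mode = "character"))

setValidity("PosteriorSet", function(object) {
    msg <- NULL
    m <- object@members
    if (abs(sum(m$pip) - 1) > 1e-9) msg <- c(msg, "PIPs must sum to 1")
    if (abs(sum(m$prior) - 1) > 1e-9) msg <- c(msg, "priors must sum to 1")
    if (!length(object@credibleSet)) msg <- c(msg, "credible set must be nonempty")
    else {
        cum <- sum(m$pip[match(object@credibleSet, m$snp)])
        if (cum < 0.99 - 1e-9 && length(object@credibleSet) < nrow(m))
            msg <- c(msg, "credible set must reach cumulative PIP 0.99")
    }
    if (is.null(msg)) TRUE else msg
})

#' SLALOM-style summary-statistic QC report
#'
#' Per-variant DENTIST-S statistics around the lead of a fine-mapped locus,
#' the resulting outlier flags (DENTIST-S p < 1e-4 and r^2 to the lead
#' > 0.6), and the locus-level verdict. The check is only applied when the
#' largest PIP at the locus exceeds 0.1.
#'
#' @slot table data.frame with `snp`, `r` (signed LD to lead), `statistic`,
#'   `p` and logical `outlier` for each variant within the scan window.
#' @slot applied whether the check was run (max PIP > 0.1).
#' @slot robust TRUE when applied and no variant is an outlier; NA when not
#'   applied.
#' @slot maxPip largest PIP at the locus.
#'
#' @seealso [slalomQC()], [dentistS()]
#' @export
setClass("SlalomReport",
    representation(table = "data.frame", applied = "logical",
                   robust = "logical", maxPip = "numeric"))

setValidity("SlalomReport", function(object) {
    msg <- NULL
    if (object@applied && nrow(object@table)) {
        tab <- object@table
        if (any(tab$statistic < 0, na.rm = TRUE))
            msg <- c(msg, "DENTIST-S statistics must be nonnegative")
        bad <- tab$outlier & !(tab$p < 1e-4 & tab$r^2 > 0.6)
        if (any(bad, na.rm = TRUE))
            msg <- c(msg, "outlier flags must satisfy both clauses")
    }
    if (is.null(msg)) TRUE else msg
})
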