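## Power-adjusted transferability (PAT) of discovery loci -------------------
##
## A discovery locus is carried into a target ancestry group as a credible
## set (lead plus tightly linked discovery proxies). The significance
## threshold applied in the target group is penalized for the credible-set
## size, the per-locus detection power is computed from the discovery effect
## and target frequency/sample size, and the PAT ratio compares the observed
## number of transferable loci with the power-implied expectation.

#' Default penalization factors per ancestry group
#'
#' Empirically derived penalization-factor constants for the
#' credible-set-size correction of the transferability threshold, per target
#' ancestry group (African, East Asian, South Asian, Hispanic/Latin
#' American). Used when no null-trait summary statistics are available to
#' fit [estimatePenalizationFactor()] directly.
#'
#' @return named numeric vector.
#' @export
defaultPenalizationFactors <- function() {
    c(AFR = 0.008341, EAS = 0.007378, SAS = 0.006847, HIS = 0.003147)
}

#' Build the transferability credible set of a discovery locus
#'
#' Members are the lead plus every variant with `r^2 >= 0.8` to the lead
#' within +/- 50 kb whose discovery p-value is below `100 * p_lead`. When
#' the lead is absent from the LD panel the set degenerates to the lead
#' alone, with a warning.
#'
#' @param locus one-row known-loci data.frame (`snp chr bp beta_discovery
#'   eaf_discovery p_discovery`).
#' @param discovery discovery summary-statistics data.frame.
#' @param ld discovery-ancestry [LDMatrix-class].
#' @param r2Min,windowBp,pFactor membership thresholds.
#' @return a [TransferSet-class].
#' @export
buildTransferCredibleSet <- function(locus, discovery, ld,
                                     r2Min = 0.8, windowBp = 50000L,
                                     pFactor = 100) {
    p_lead <- locus$p_discovery
    lead_row <- data.frame(snp = locus$snp, chr = locus$chr, bp = locus$bp,
                           beta = locus$beta_discovery,
                           p = p_lead, r2 = 1, stringsAsFactors = FALSE)
    if (!locus$snp %in% ld@variants$snp) {
        warning("lead ", locus$snp, " absent from LD panel; credible set = {lead}")
        return(new("TransferSet", lead = lead_row, members = lead_row))
    }
    r2 <- ld@r[locus$snp, ]^2
    cand <- ld@variants
    cand$r2 <- r2
    cand <- cand[cand$r2 >= r2Min & abs(cand$bp - locus$bp) <= windowBp, ,
                 drop = FALSE]
    i <- match(cand$snp, discovery$snp)
    cand$beta <- discovery$beta[i]
    cand$p <- discovery$p[i]
    keep <- cand$snp == locus$snp |
        (!is.na(cand$p) & cand$p < pFactor * p_lead)
    cand <- cand[keep, c("snp", "chr", "bp", "beta", "p", "r2")]
    if (!locus$snp %in% cand$snp) cand <- rbind(lead_row, cand)
    ## the catalogue's own discovery record wins for the lead row
    i_lead <- which(cand$snp == locus$snp)
    cand$beta[i_lead] <- locus$beta_discovery
    cand$p[i_lead] <- p_lead
    cand <- cand[order(cand$bp), , drop = FALSE]
    rownames(cand) <- NULL
    new("TransferSet", lead = lead_row, members = cand)
}

#' Estimate the penalization factor from null-trait loci
#'
#' Fits an ordinary least-squares regression of `-log10(min p)` across each
#' null locus's credible-set members in the target group on the
#' credible-set size N. The slope is the penalization factor: it measures
#' how fast the best member p-value inflates with the effective number of
#' chances, for a trait unrelated to the target phenotype.
#'
#' @param minP per-locus minimum member p-value in the target group.
#' @param n per-locus credible-set size.
#' @return list with `pf` (slope), `intercept` and the `lm` `fit`.
#' @export
estimatePenalizationFactor <- function(minP, n) {
    stopifnot(length(minP) == length(n))
    if (length(minP) < 10) stop("at least 10 null loci required for a stable fit")
    y <- -log10(minP)
    fit <- lm(y ~ n)
    list(pf = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
         fit = fit)
}

#' Penalized transferability threshold
#'
#' `threshold = 10^(log10(0.05) - pf * (N - 1))`: 0.05 for a single-member
#' set, strictly decreasing in the credible-set size N for positive
#' penalization factors.
#'
#' @param n credible-set size (>= 1).
#' @param pf penalization factor.
#' @return p-value threshold.
#' @export
transferThreshold <- function(n, pf) {
    stopifnot(all(n >= 1))
    10^(log10(0.05) - pf * (n - 1))
}

#' Call a locus transferable in a target group
#'
#' TRUE when at least one credible-set member has a target p-value below the
#' penalized threshold for the set size and a target effect sign matching
#' its discovery sign. Loci with no member present in the target data are
#' unassessable and return NA.
#'
#' @param cs a [TransferSet-class] (target records harmonized to discovery
#'   effect alleles).
#' @param target target-group summary-statistics data.frame.
#' @param pf penalization factor for the target group.
#' @return logical flag (NA when unassessable), with attribute `threshold`.
#' @export
callTransferable <- function(cs, target, pf) {
    m <- cs@members
    i <- match(m$snp, target$snp)
    if (all(is.na(i))) {
        message("locus ", cs@lead$snp, ": no credible-set member in target data")
        return(structure(NA, threshold = NA_real_))
    }
    thr <- transferThreshold(nrow(m), pf)
    p_t <- target$p[i]; b_t <- target$beta[i]
    hit <- !is.na(p_t) & p_t < thr & sign(b_t) == sign(m$beta)
    structure(any(hit, na.rm = TRUE), threshold = thr)
}

#' Power to detect a locus in a target group
#'
#' Power of the additive 1-df association test at type I error `alpha`,
#' using the discovery effect estimate and the target group's allele
#' frequency and sample size. The expected standard error is the asymptotic
#' logistic-score form `1 / sqrt(2 f (1-f) (nCases + nControls) * phi *
#' (1-phi))` with case fraction `phi`; the noncentrality is `(beta/se)^2`
#' and power the upper tail of the noncentral chi-square beyond the central
#' `1 - alpha` quantile.
#'
#' @param beta discovery log-odds effect.
#' @param eaf target-group effect-allele frequency.
#' @param nCases,nControls target-group counts.
#' @param alpha type I error rate (default 0.05).
#' @return power in \[0, 1\] (vectorized).
#' @export
locusPower <- function(beta, eaf, nCases, nControls, alpha = 0.05) {
    n <- nCases + nControls
    phi <- nCases / n
    v <- 2 * eaf * (1 - eaf) * n * phi * (1 - phi)
    bad <- !is.finite(v) | v <= 0
    if (any(bad)) warning("degenerate allele frequency; power set to 0")
    ncp <- ifelse(bad, NA_real_, beta^2 * v)
    crit <- qchisq(1 - alpha, df = 1)
    out <- pchisq(crit, df = 1, ncp = ncp, lower.tail = FALSE)
    out[bad] <- 0
    out
}

#' Call a locus nontransferable
#'
#' TRUE when the locus was well powered but silent: at least one
#' credible-set member with power above `powerMin` (80 percent), no member
#' with target p below 0.05, and no variant within 50 kb of the lead with
#' target p below 1e-3.
#'
#' @param cs a [TransferSet-class].
#' @param target target-group summary-statistics data.frame.
#' @param powers per-member detection powers (recycled if scalar).
#' @param powerMin,pMember,pNeighbor rule thresholds.
#' @param windowBp neighbourhood width around the lead.
#' @return logical.
#' @export
callNontransferable <- function(cs, target, powers, powerMin = 0.8,
                                pMember = 0.05, pNeighbor = 1e-3,
                                windowBp = 50000L) {
    m <- cs@members
    powers <- rep_len(powers, nrow(m))
    if (max(powers, na.rm = TRUE) <= powerMin) return(FALSE)
    p_t <- target$p[match(m$snp, target$snp)]
    if (all(is.na(p_t))) return(FALSE)
    if (min(p_t, na.rm = TRUE) < pMember) return(FALSE)
    near <- target$chr == cs@lead$chr &
        abs(target$bp - cs@lead$bp) <= windowBp
    !any(target$p[near] < pNeighbor, na.rm = TRUE)
}

#' Power-adjusted transferability ratio
#'
#' `ratio = observed / expected` with `observed` the number of transferable
#' loci and `expected` the sum of per-locus powers; the 95 percent
#' confidence interval is a percentile bootstrap over loci, resampling each
#' locus's (flag, power) pair jointly. Loci with NA flags (unassessable in
#' the target group) are excluded from both sums.
#'
#' @param transferable logical per-locus flags (NA allowed).
#' @param power per-locus powers.
#' @param perLocus optional data.frame of per-locus records to carry along.
#' @param nBoot bootstrap replicates (default 1000).
#' @param seed optional integer seed for the bootstrap.
#' @return a [PATResult-class].
#' @export
patRatio <- function(transferable, power, perLocus = NULL, nBoot = 1000L,
                     seed = NULL) {
    keep <- !is.na(transferable)
    flag <- as.logical(transferable[keep])
    pw <- power[keep]
    if (!length(pw) || sum(pw) <= 0)
        stop("expected number of loci is zero; PAT ratio undefined")
    if (!is.null(seed)) set.seed(seed)
    observed <- sum(flag)
    expected <- sum(pw)
    ratio <- observed / expected
    n <- length(pw)
    ci <- c(NA_real_, NA_real_)
    if (nBoot > 0) {
        boots <- vapply(seq_len(nBoot), function(i) {
            j <- sample.int(n, n, replace = TRUE)
            e <- sum(pw[j])
            if (e <= 0) NA_real_ else sum(flag[j]) / e
        }, numeric(1))
        ci <- quantile(boots, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
    }
    if (is.null(perLocus))
        perLocus <- data.frame(transferable = flag, power = pw)
    new("PATResult", observed = as.numeric(observed), expected = expected,
        ratio = ratio, ciLow = ci[1], ciHigh = ci[2], perLocus = perLocus)
}

#' Assess transferability of a discovery catalogue in a target group
#'
#' End-to-end wrapper: builds the credible set of every catalogue locus from
#' the discovery statistics and LD panel, computes per-locus power from the
#' discovery effect and target frequency, calls transferable /
#' nontransferable status against the target statistics, and aggregates the
#' PAT ratio with its bootstrap interval.
#'
#' @param catalogue known-loci data.frame.
#' @param discovery,target summary-statistics data.frames (harmonized to
#'   common effect alleles).
#' @param ld discovery-ancestry [LDMatrix-class].
#' @param pf penalization factor of the target group.
#' @param nCases,nControls target-group counts (defaults taken from the
#'   target table's first row).
#' @param nBoot,seed bootstrap settings passed to [patRatio()].
#' @return a [PATResult-class]; per-locus records in `perLocus`.
#' @export
assessTransferability <- function(catalogue, discovery, target, ld, pf,
                                  nCases = NULL, nControls = NULL,
                                  nBoot = 1000L, seed = NULL) {
    if (is.null(nCases)) nCases <- target$n_cas[1]
    if (is.null(nControls)) nControls <- target$n_con[1]
    rows <- lapply(seq_len(nrow(catalogue)), function(i) {
        loc <- catalogue[i, , drop = FALSE]
        cs <- buildTransferCredibleSet(loc, discovery, ld)
        ti <- match(cs@members$snp, target$snp)
        eaf_t <- target$eaf[ti]
        pw <- locusPower(cs@members$beta, eaf_t, nCases, nControls)
        pw[is.na(pw)] <- 0
        flag <- callTransferable(cs, target, pf)
        nont <- if (is.na(flag)) NA else
            callNontransferable(cs, target, pw)
        data.frame(snp = loc$snp, n_set = nrow(cs@members),
                   power = max(pw, na.rm = TRUE),
                   min_p_target = suppressWarnings(
                       min(target$p[ti], na.rm = TRUE)),
                   transferable = as.logical(flag), nontransferable = nont,
                   stringsAsFactors = FALSE)
    })
    per <- do.call(rbind, rows)
    keep <- !is.na(per$transferable)
    patRatio(per$transferable, per$power, perLocus = per[keep, , drop = FALSE],
             nBoot = nBoot, seed = seed)
}
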