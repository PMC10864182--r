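## Multi-ancestry Bayesian fine mapping with heterogeneity priors -----------

#' Extract a fine-mapping locus around a lead variant
#'
#' Collects every variant with `r^2 > 0.1` to the lead in the multi-ancestry
#' LD reference, ordered by position, and attaches each ancestry group's
#' effect and standard error where available (NA where the group lacks the
#' variant).
#'
#' @param lead lead variant id (must be in the LD panel).
#' @param sumstatsByGroup named list of per-ancestry summary-statistics
#'   data.frames (harmonized to common effect alleles).
#' @param ld multi-ancestry [LDMatrix-class].
#' @param r2Min membership threshold (default 0.1, exclusive).
#' @return a [FineMapLocus-class].
#' @export
extractLocus <- function(lead, sumstatsByGroup, ld, r2Min = 0.1) {
    v <- ld@variants
    if (!lead %in% v$snp) stop("lead ", lead, " absent from LD panel")
    r2 <- ld@r[lead, ]^2
    keep <- r2 > r2Min | v$snp == lead
    members <- v[keep, c("snp", "chr", "bp")]
    ord <- order(members$bp)
    members <- members[ord, , drop = FALSE]
    rownames(members) <- NULL
    groups <- names(sumstatsByGroup)
    n <- nrow(members)
    B <- matrix(NA_real_, n, length(groups), dimnames = list(members$snp, groups))
    S <- B
    for (g in groups) {
        i <- match(members$snp, sumstatsByGroup[[g]]$snp)
        B[, g] <- sumstatsByGroup[[g]]$beta[i]
        S[, g] <- sumstatsByGroup[[g]]$se[i]
    }
    sub <- which(keep)[ord]
    ldSub <- new("LDMatrix", variants = v[sub, , drop = FALSE],
                 r = ld@r[sub, sub, drop = FALSE])
    new("FineMapLocus", lead = lead, members = members, beta = B, se = S,
        ld = ldSub)
}

#' Per-variant cross-ancestry pooling and heterogeneity
#'
#' For each member of a fine-mapping locus, pools the ancestry-group effect
#' estimates by fixed-effects IVW, and computes the pooled chi-square
#' statistic `(beta/se)^2`, Cochran's Q over groups and
#' `I2 = max(0, (Q - (k-1))/Q)`. Members observed in a single group have
#' `I2 = 0` by convention.
#'
#' @param locus a [FineMapLocus-class].
#' @return data.frame with `snp`, `bp`, `beta`, `se`, `chisq`, `q`, `i2`,
#'   `k` (groups contributing).
#' @export
perVariantMetaI2 <- function(locus) {
    n <- nrow(locus@members)
    out <- lapply(seq_len(n), function(i) {
        fit <- ivwMeta(locus@beta[i, ], locus@se[i, ])
        data.frame(snp = locus@members$snp[i], bp = locus@members$bp[i],
                   beta = fit$beta, se = fit$se, chisq = fit$z^2,
                   q = fit$q, i2 = fit$i2, k = fit$n_studies)
    })
    out <- do.call(rbind, out)
    rownames(out) <- NULL
    out
}

#' Heterogeneity-informed fine-mapping prior
#'
#' Converts per-member cross-ancestry heterogeneity into a causal prior:
#' `raw_i = max(eps, 1 - I2_i)`, normalized to sum to one. Variants whose
#' effect estimates diverge across ancestry groups receive smaller prior
#' probability of being causal; the floor `eps` keeps every member
#' admissible.
#'
#' @param i2 per-member I2 values in \[0, 1\].
#' @param eps prior floor (default 0.01).
#' @return normalized prior vector.
#' @export
heterogeneityPrior <- function(i2, eps = 0.01) {
    stopifnot(all(i2 >= -1e-9 & i2 <= 1 + 1e-9))
    raw <- pmax(eps, 1 - i2)
    raw / sum(raw)
}

#' Posterior inclusion probabilities and the 99 percent credible set
#'
#' In `multi` mode the posterior inclusion probability of member i is
#' proportional to `chisq_i * prior_i`; in `single` mode the heterogeneity
#' prior is dropped and PIPs are proportional to the chi-square statistics
#' alone. The 99 percent credible set is the smallest descending-PIP prefix
#' whose cumulative probability reaches 0.99, ties broken by position.
#'
#' @param stats per-member data.frame from [perVariantMetaI2()] (needs
#'   `snp`, `bp`, `chisq`, and `i2` for `multi` mode).
#' @param mode `"multi"` or `"single"`.
#' @param prior optional explicit prior (overrides the I2-derived one).
#' @param eps prior floor passed to [heterogeneityPrior()].
#' @param coverage credible-set mass (default 0.99).
#' @return a [PosteriorSet-class].
#' @export
posteriorPips <- function(stats, mode = c("multi", "single"), prior = NULL,
                          eps = 0.01, coverage = 0.99) {
    mode <- match.arg(mode)
    n <- nrow(stats)
    if (mode == "multi") {
        if (is.null(prior)) prior <- heterogeneityPrior(stats$i2, eps = eps)
    } else prior <- rep(1 / n, n)
    w <- stats$chisq * prior
    if (all(w == 0)) {
        warning("all chi-square statistics are zero; uniform PIPs")
        pip <- rep(1 / n, n)
    } else pip <- w / sum(w)
    ord <- order(-pip, stats$bp)
    cum <- cumsum(pip[ord])
    size <- which(cum >= coverage - 1e-12)[1]
    if (is.na(size)) size <- n
    cs <- stats$snp[ord[seq_len(size)]]
    members <- data.frame(snp = stats$snp, bp = stats$bp,
                          chisq = stats$chisq,
                          i2 = if ("i2" %in% names(stats)) stats$i2 else NA_real_,
                          prior = prior, pip = pip,
                          in_cs = stats$snp %in% cs,
                          stringsAsFactors = FALSE)
    new("PosteriorSet", members = members, credibleSet = cs, mode = mode)
}

#' Credible-set size and multi- vs single-ancestry comparison
#'
#' `credibleSetSize()` returns the size of the 99 percent credible set;
#' `compareCredibleSets()` compares the multi-ancestry and single-ancestry
#' posterior sets of one locus, and `summarizeCredibleSets()` aggregates a
#' list of such records into median sizes and the fraction of loci whose
#' multi-ancestry set is no larger.
#'
#' @param x a [PosteriorSet-class].
#' @return `credibleSetSize()`: integer.
#' @export
credibleSetSize <- function(x) length(x@credibleSet)

#' @rdname credibleSetSize
#' @param multi,single [PosteriorSet-class] objects for the same locus.
#' @return `compareCredibleSets()`: one-row data.frame with both sizes and
#'   `smaller_multi`.
#' @export
compareCredibleSets <- function(multi, single) {
    a <- credibleSetSize(multi); b <- credibleSetSize(single)
    data.frame(size_multi = a, size_single = b, smaller_multi = a <= b)
}

#' @rdname credibleSetSize
#' @param comparisons data.frame rbind of [compareCredibleSets()] rows.
#' @return `summarizeCredibleSets()`: list with `median_multi`,
#'   `median_single`, `fraction_smaller`.
#' @export
summarizeCredibleSets <- function(comparisons) {
    list(median_multi = median(comparisons$size_multi),
         median_single = median(comparisons$size_single),
         fraction_smaller = mean(comparisons$smaller_multi))
}

#' DENTIST-S consistency statistic
#'
#' Contrasts a variant's z-score with its LD-predicted value from the lead:
#' `T = (z - r * zLead)^2 / (1 - r^2)`, with a 1-df chi-square upper-tail
#' p-value. Signed r is used. Variants in perfect LD with the lead
#' (`|r| = 1` within tolerance) are undefined and return NA with a warning.
#'
#' @param z test-variant z-score(s).
#' @param zLead lead-variant z-score.
#' @param r signed LD between test variant(s) and lead.
#' @return data.frame with `statistic` and `p`.
#' @export
dentistS <- function(z, zLead, r) {
    bad <- abs(r) >= 1 - 1e-12
    if (any(bad)) warning("variant(s) in perfect LD with lead skipped")
    stat <- ifelse(bad, NA_real_, (z - r * zLead)^2 / (1 - r^2))
    data.frame(statistic = stat,
               p = pchisq(stat, df = 1, lower.tail = FALSE))
}

#' SLALOM-style robustness QC of a fine-mapped locus
#'
#' Applied only when the largest PIP at the locus exceeds `pipMin` (0.1).
#' The lead is the minimum-p (largest chi-square) variant; every variant of
#' the locus within +/- 1 Mb of the lead is scored with [dentistS()] against
#' the lead, and flagged as an outlier when its DENTIST-S p-value is below
#' `pOutlier` (1e-4) and its `r^2` with the lead exceeds `r2Outlier` (0.6).
#' The locus is robust when no variant is an outlier.
#'
#' @param locus a [FineMapLocus-class].
#' @param posterior the locus's [PosteriorSet-class].
#' @param z per-member z-scores of the statistics being checked (defaults
#'   to the pooled `sqrt(chisq)` with the pooled effect's sign from
#'   [perVariantMetaI2()] when `stats` is given).
#' @param stats optional [perVariantMetaI2()] table used to derive `z`.
#' @param windowBp scan window around the lead (default 1 Mb).
#' @param pipMin,pOutlier,r2Outlier rule thresholds.
#' @return a [SlalomReport-class].
#' @export
slalomQC <- function(locus, posterior, z = NULL, stats = NULL,
                     windowBp = 1e6, pipMin = 0.1, pOutlier = 1e-4,
                     r2Outlier = 0.6) {
    maxPip <- max(posterior@members$pip)
    if (maxPip <= pipMin)
        return(new("SlalomReport", table = data.frame(), applied = FALSE,
                   robust = NA, maxPip = maxPip))
    if (is.null(z)) {
        if (is.null(stats)) stats <- perVariantMetaI2(locus)
        z <- sign(stats$beta) * sqrt(stats$chisq)
    }
    m <- locus@members
    i_lead <- which.max(z^2)
    near <- abs(m$bp - m$bp[i_lead]) <= windowBp
    near[i_lead] <- FALSE   # the lead cannot be tested against itself
    r <- locus@ld@r[m$snp[i_lead], m$snp]
    d <- dentistS(z[near], z[i_lead], r[near])
    tab <- data.frame(snp = m$snp[near], r = unname(r[near]),
                      statistic = d$statistic, p = d$p,
                      stringsAsFactors = FALSE)
    tab$outlier <- !is.na(tab$p) & tab$p < pOutlier & tab$r^2 > r2Outlier
    new("SlalomReport", table = tab, applied = TRUE,
        robust = !any(tab$outlier), maxPip = maxPip)
}

#' Fine-map one locus end to end
#'
#' Wrapper: extracts the locus, pools across ancestry groups, forms the
#' heterogeneity prior and both posterior modes, and runs the SLALOM check
#' on the multi-ancestry posterior.
#'
#' @inheritParams extractLocus
#' @param eps prior floor.
#' @return list with `locus`, `stats`, `multi`, `single`, `slalom`.
#' @export
fineMapLocus <- function(lead, sumstatsByGroup, ld, r2Min = 0.1, eps = 0.01) {
    locus <- extractLocus(lead, sumstatsByGroup, ld, r2Min = r2Min)
    stats <- perVariantMetaI2(locus)
    multi <- posteriorPips(stats, mode = "multi", eps = eps)
    single <- posteriorPips(stats, mode = "single")
    slalom <- slalomQC(locus, multi, stats = stats)
    list(locus = locus, stats = stats, multi = multi, single = single,
         slalom = slalom)
}
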