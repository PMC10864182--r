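## Synthetic multi-ancestry summary statistics ------------------------------
##
## The generator works on the summary-statistic scale throughout: z-scores at
## a locus are drawn from the standard RSS model z ~ MVN(R lambda, R), where
## R is the signed LD matrix and lambda the vector of standardized
## noncentralities implied by the per-variant log-odds effects, allele
## frequencies and the effective half sample size of the case-control study.
## This reproduces exactly the arithmetic every downstream module consumes
## (beta = z * se, se from the allele-frequency/sample-size identity) without
## simulating genotypes.

#' Simulate a block-diagonal LD matrix
#'
#' Builds an autoregressive LD reference: within each block the signed
#' correlation between variants i and j is `rho^|i-j|`, blocks are
#' independent, and the result is positive semi-definite by construction.
#' Variants are laid out on one chromosome at `spacingBp` intervals.
#'
#' @param blockSizes integer vector of block sizes.
#' @param rho scalar or per-block AR-1 correlation, `|rho| < 1`.
#' @param chr chromosome label.
#' @param spacingBp distance in bp between adjacent variants.
#' @param startBp position of the first variant.
#' @param prefix variant-id prefix.
#' @return an [LDMatrix-class].
#' @export
simulateLDMatrix <- function(blockSizes, rho, chr = "1", spacingBp = 5000L,
                             startBp = 1L, prefix = "rs") {
    rho <- rep_len(rho, length(blockSizes))
    if (any(abs(rho) >= 1)) stop("|rho| must be < 1")
    n <- sum(blockSizes)
    r <- matrix(0, n, n)
    off <- 0L
    for (b in seq_along(blockSizes)) {
        m <- blockSizes[b]
        idx <- off + seq_len(m)
        r[idx, idx] <- rho[b]^abs(outer(seq_len(m), seq_len(m), "-"))
        off <- off + m
    }
    bp <- startBp + (seq_len(n) - 1L) * spacingBp
    v <- data.frame(snp = paste0(prefix, seq_len(n)), chr = chr, bp = bp,
                    a1 = "A", a2 = "G", stringsAsFactors = FALSE)
    dimnames(r) <- list(v$snp, v$snp)
    new("LDMatrix", variants = v, r = r)
}

#' Balding-Nichols ancestry-specific allele frequencies
#'
#' Draws per-group effect-allele frequencies around shared ancestral
#' frequencies: group frequency ~ Beta(p(1-F)/F, (1-p)(1-F)/F) for ancestral
#' frequency p and drift parameter F, clamped to \[0.01, 0.99\]. Larger F
#' gives stronger cross-group divergence; F in 0.05-0.15 is typical of
#' continental-level differentiation.
#'
#' @param nVariants number of variants.
#' @param fst drift parameter F in (0, 1).
#' @param ancestral optional vector of ancestral frequencies; drawn
#'   uniformly on \[0.05, 0.95\] when `NULL`.
#' @return numeric vector of frequencies in \[0.01, 0.99\].
#' @export
simulateAlleleFreqs <- function(nVariants, fst = 0.1, ancestral = NULL) {
    if (is.null(ancestral)) ancestral <- runif(nVariants, 0.05, 0.95)
    stopifnot(fst > 0, fst < 1)
    k <- (1 - fst) / fst
    f <- rbeta(length(ancestral), ancestral * k, (1 - ancestral) * k)
    pmin(pmax(f, 0.01), 0.99)
}

.block_ranges <- function(blockSizes) {
    end <- cumsum(blockSizes)
    Map(seq, end - blockSizes + 1L, end)
}

## block structure recovered from the zero pattern of R (exact for the
## generator's block-diagonal references; falls back to one block otherwise)
.detect_blocks <- function(r) {
    n <- nrow(r)
    blocks <- list(); i <- 1L
    while (i <= n) {
        j <- i
        repeat {
            nz <- which(r[, seq(i, j), drop = FALSE] != 0, arr.ind = TRUE)[, 1]
            jmax <- max(j, nz)
            if (jmax == j) break
            j <- jmax
        }
        blocks[[length(blocks) + 1L]] <- seq(i, j)
        i <- j + 1L
    }
    blocks
}

#' Simulate GWAS z-scores at a set of loci
#'
#' Draws per-variant association summaries from the summary-statistic model
#' `z ~ MVN(R lambda, R)` with noncentrality
#' `lambda_j = beta_j * sqrt(2 f_j (1 - f_j) * nEffHalf)`. Standard errors
#' follow `se_j = 1 / sqrt(2 f_j (1 - f_j) * nEffHalf)`, estimated effects
#' are `z_j * se_j`, and p-values are two-sided normal. Sampling is done
#' per LD block via Cholesky factors, so runtime is linear in the number of
#' blocks.
#'
#' @param ld an [LDMatrix-class] (block-diagonal references are exploited).
#' @param beta true per-variant log-odds effects (0 for non-causal).
#' @param eaf per-variant effect-allele frequencies in the group.
#' @param nCases,nControls case/control counts of the group.
#' @param info imputation info score column value (default 1).
#' @param nStudies value for the `n_studies` column (default 2).
#' @param seed optional integer seed.
#' @return summary-statistics data.frame with a `z` column in addition to
#'   the canonical columns.
#' @export
simulateZscores <- function(ld, beta, eaf, nCases, nControls,
                            info = 1, nStudies = 2L, seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    v <- ld@variants
    n <- nrow(v)
    beta <- unname(beta); eaf <- unname(eaf)
    nCases <- unname(nCases); nControls <- unname(nControls)
    stopifnot(length(beta) == n, length(eaf) == n)
    neff <- effectiveSampleSize(nCases, nControls)
    se <- 1 / sqrt(2 * eaf * (1 - eaf) * neff)
    lambda <- beta / se
    r <- ld@r
    z <- numeric(n)
    for (idx in .detect_blocks(r)) {
        rb <- r[idx, idx, drop = FALSE]
        mu <- drop(rb %*% lambda[idx])
        ## small jitter keeps Cholesky viable at |rho| ~ 1
        L <- chol(rb + diag(1e-10, length(idx)))
        z[idx] <- mu + drop(crossprod(L, rnorm(length(idx))))
    }
    data.frame(snp = v$snp, chr = v$chr, bp = v$bp, a1 = v$a1, a2 = v$a2,
               eaf = eaf, beta = z * se, se = se, p = zToP(z),
               n_cas = nCases, n_con = nControls, info = info,
               n_studies = nStudies, direction = NA_character_,
               z = z, stringsAsFactors = FALSE)
}

#' Build a known-loci catalogue from a discovery simulation
#'
#' Scans a simulated discovery summary-statistics table for genome-wide
#' significant variants (p < `threshold`), greedily clumps them by distance
#' (best p first, suppressing anything within `windowBp` on the same
#' chromosome) and returns one catalogue row per resulting lead.
#'
#' @param sumstats discovery summary-statistics data.frame.
#' @param threshold significance threshold (default 5e-8).
#' @param windowBp suppression window around each lead (default 500 kb,
#'   matching the locus-aggregation rule).
#' @param source label for the catalogue `source` column.
#' @return known-loci data.frame (`snp chr bp a1 a2 beta_discovery
#'   eaf_discovery p_discovery source`).
#' @export
generateKnownLoci <- function(sumstats, threshold = 5e-8, windowBp = 5e5,
                              source = "simulated_discovery") {
    sig <- sumstats[!is.na(sumstats$p) & sumstats$p < threshold, , drop = FALSE]
    leads <- sig[0, , drop = FALSE]
    while (nrow(sig)) {
        best <- which.min(sig$p)
        leads <- rbind(leads, sig[best, , drop = FALSE])
        near <- sig$chr == sig$chr[best] & abs(sig$bp - sig$bp[best]) <= windowBp
        sig <- sig[!near, , drop = FALSE]
    }
    leads <- leads[order(leads$chr, leads$bp), , drop = FALSE]
    data.frame(snp = leads$snp, chr = leads$chr, bp = leads$bp,
               a1 = leads$a1, a2 = leads$a2,
               beta_discovery = leads$beta, eaf_discovery = leads$eaf,
               p_discovery = leads$p,
               source = rep_len(source, nrow(leads)),
               stringsAsFactors = FALSE, row.names = NULL)
}

#' Simulate a two-sample MR instrument panel
#'
#' Generates exposure and outcome summary statistics for independent
#' instruments. True exposure effects are drawn uniformly on
#' \[0.1, 0.5\] (instrument relevance guaranteed); the outcome effect of
#' instrument j is `theta * betaX_j + alpha_j` plus estimation noise, where
#' `alpha_j` is 0 under `"none"`, a constant `alpha` under `"directional"`
#' pleiotropy, and a `outlierShift`-sized shift on `nOutliers` instruments
#' under `"outliers"`.
#'
#' @param nInstruments number of instruments (>= 3).
#' @param theta true causal effect of exposure on outcome.
#' @param pleiotropy one of `"none"`, `"directional"`, `"outliers"`.
#' @param alpha directional pleiotropy constant.
#' @param nOutliers number of outlier instruments under `"outliers"`.
#' @param outlierShift outcome shift of each outlier, in outcome s.e. units.
#' @param seX,seY exposure / outcome standard errors.
#' @param seed optional integer seed.
#' @return list with `exposure` and `outcome` summary-statistics
#'   data.frames and the true `theta`, `alpha` and `outliers` (ids).
#' @export
generateMRPair <- function(nInstruments, theta, pleiotropy = c("none",
                           "directional", "outliers"), alpha = 0.05,
                           nOutliers = 1L, outlierShift = 10,
                           seX = 0.02, seY = 0.05, seed = NULL) {
    pleiotropy <- match.arg(pleiotropy)
    if (nInstruments < 3) stop("at least 3 instruments required")
    if (!is.null(seed)) set.seed(seed)
    bx <- runif(nInstruments, 0.1, 0.5)
    a <- switch(pleiotropy,
        none = rep(0, nInstruments),
        directional = rep(alpha, nInstruments),
        outliers = {
            shift <- rep(0, nInstruments)
            shift[sample.int(nInstruments, nOutliers)] <- outlierShift * seY
            shift
        })
    bxh <- bx + rnorm(nInstruments, 0, seX)
    byh <- theta * bx + a + rnorm(nInstruments, 0, seY)
    snp <- paste0("iv", seq_len(nInstruments))
    mk <- function(b, se) {
        z <- b / se
        data.frame(snp = snp, chr = "1",
                   bp = seq_len(nInstruments) * 2e7, a1 = "A", a2 = "G",
                   eaf = 0.3, beta = b, se = se, p = zToP(z),
                   stringsAsFactors = FALSE)
    }
    list(exposure = mk(bxh, rep(seX, nInstruments)),
         outcome = mk(byh, rep(seY, nInstruments)),
         theta = theta, alpha = if (pleiotropy == "directional") alpha else 0,
         outliers = if (pleiotropy == "outliers") snp[a != 0] else character())
}

#' Simulate a multi-ancestry study set around shared causal variants
#'
#' Convenience wrapper for calibration studies: builds one LD reference per
#' ancestry group (same variant map, possibly different AR-1 correlation),
#' draws group-specific allele frequencies by the Balding-Nichols
#' construction around shared ancestral frequencies, places one causal
#' variant per LD block (the block centre) and simulates each group's
#' summary statistics.
#'
#' @param nLoci number of LD blocks (one candidate locus each).
#' @param blockSize variants per block.
#' @param rho named or unnamed vector of AR-1 correlations per group.
#' @param nEffHalf per-group effective half sample sizes (balanced designs
#'   are simulated, i.e. cases = controls = `nEffHalf`).
#' @param betaByGroup list of per-group causal effect vectors (length
#'   `nLoci`); a single vector is recycled to all groups.
#' @param fst per-group Balding-Nichols drift parameter.
#' @param spacingBp inter-variant spacing in bp.
#' @param seed integer seed.
#' @return list with `ld` (per-group [LDMatrix-class]), `sumstats`
#'   (per-group data.frame), `causal` (indices), `truth` (data.frame of
#'   per-group true effects).
#' @export
simulateStudySet <- function(nLoci, blockSize, rho, nEffHalf, betaByGroup,
                             fst = 0.1, spacingBp = 5000L, seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    groups <- names(nEffHalf)
    if (is.null(groups)) groups <- paste0("G", seq_along(nEffHalf))
    if (is.data.frame(betaByGroup) || !is.list(betaByGroup))
        betaByGroup <- rep(list(betaByGroup), length(groups))
    rho <- rep_len(rho, length(groups))
    fst <- rep_len(fst, length(groups))
    nv <- nLoci * blockSize
    causal <- (seq_len(nLoci) - 1L) * blockSize + ceiling(blockSize / 2)
    ancestral <- runif(nv, 0.1, 0.9)
    ld <- list(); ss <- list()
    for (g in seq_along(groups)) {
        ldg <- simulateLDMatrix(rep(blockSize, nLoci), rho[g],
                                spacingBp = spacingBp)
        f <- simulateAlleleFreqs(nv, fst = fst[g], ancestral = ancestral)
        beta <- numeric(nv)
        beta[causal] <- betaByGroup[[g]]
        ss[[g]] <- simulateZscores(ldg, beta, f, nEffHalf[g], nEffHalf[g])
        ld[[g]] <- ldg
    }
    names(ld) <- names(ss) <- groups
    truth <- data.frame(index = causal,
                        snp = ld[[1]]@variants$snp[causal])
    for (g in seq_along(groups)) truth[[paste0("beta_", groups[g])]] <-
        betaByGroup[[g]]
    list(ld = ld, sumstats = ss, causal = causal, truth = truth)
}
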