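## Bi-directional two-sample Mendelian randomization ------------------------

#' Select genetic instruments for an exposure
#'
#' Takes genome-wide significant exposure variants (p < 5e-8), clumps them
#' for independence, and falls back to the suggestive threshold (p < 5e-6)
#' when fewer than 10 independent instruments survive. Fails when even the
#' fallback yields fewer than 3 instruments, since the estimators are then
#' undefined.
#'
#' @param exposure exposure summary-statistics data.frame.
#' @param ld optional [LDMatrix-class] for clumping (distance-only clumping
#'   when `NULL`).
#' @param pPrimary,pFallback selection thresholds.
#' @param minPrimary minimum post-clumping count before the fallback fires.
#' @param r2Max,windowKb clumping parameters.
#' @return data.frame of independent instruments, attribute `threshold`
#'   recording the threshold used.
#' @export
selectInstruments <- function(exposure, ld = NULL, pPrimary = 5e-8,
                              pFallback = 5e-6, minPrimary = 10L,
                              r2Max = 0.001, windowKb = 10000) {
    pick <- function(thr) {
        sel <- exposure[!is.na(exposure$p) & exposure$p < thr, , drop = FALSE]
        if (!nrow(sel)) return(sel)
        clumpVariants(sel, ld = ld, r2Max = r2Max, windowKb = windowKb)
    }
    out <- pick(pPrimary)
    thr <- pPrimary
    if (nrow(out) < minPrimary) {
        out <- pick(pFallback)
        thr <- pFallback
    }
    if (nrow(out) < 3)
        stop("fewer than 3 independent instruments even at the suggestive threshold")
    structure(out, threshold = thr)
}

#' Greedy LD clumping
#'
#' Standard clumping by ascending p-value: keep the best remaining variant,
#' discard every variant with `r^2 > r2Max` to it within `windowKb`
#' kilobases on the same chromosome, repeat. Without an LD panel all
#' within-window variants count as correlated only if `r2Max < 0` is
#' impossible, so distance-only clumping discards everything within the
#' window.
#'
#' @param x summary-statistics data.frame with `snp`, `chr`, `bp`, `p`.
#' @param ld optional [LDMatrix-class].
#' @param r2Max correlation threshold (exclusive).
#' @param windowKb window in kb.
#' @return the retained rows, ordered by p.
#' @export
clumpVariants <- function(x, ld = NULL, r2Max = 0.001, windowKb = 10000) {
    x <- x[order(x$p), , drop = FALSE]
    kept <- x[0, , drop = FALSE]
    while (nrow(x)) {
        top <- x[1, , drop = FALSE]
        kept <- rbind(kept, top)
        inwin <- x$chr == top$chr & abs(x$bp - top$bp) <= windowKb * 1000
        if (!is.null(ld) && top$snp %in% ld@variants$snp) {
            r2 <- rep(1, nrow(x))
            hit <- x$snp %in% ld@variants$snp
            r2[hit] <- ld@r[top$snp, x$snp[hit]]^2
            drop <- inwin & r2 > r2Max
        } else drop <- inwin
        drop[1] <- TRUE
        x <- x[!drop, , drop = FALSE]
    }
    rownames(kept) <- NULL
    kept
}

#' Harmonize an exposure/outcome record pair into an instrument
#'
#' Flips the outcome record onto the exposure effect allele (sign flip plus
#' frequency complement when the allele labels are swapped; strand flips
#' recognised by complementation). Palindromic pairs are dropped when the
#' minor-allele frequency is in (0.42, 0.5] on either side, and otherwise
#' orientated by frequency.
#'
#' @param exp,out one-row summary-statistics data.frames for the same
#'   variant.
#' @return one-row instrument data.frame (`snp beta_exposure se_exposure
#'   p_exposure beta_outcome se_outcome eaf`), or `NULL` when the pair is
#'   dropped.
#' @export
harmonizePair <- function(exp, out) {
    if (exp$snp != out$snp) stop("records refer to different variants")
    aligned <- harmonizeToReference(out, exp$a1, exp$a2, refEaf = exp$eaf)
    if (is.null(aligned)) return(NULL)
    data.frame(snp = exp$snp, beta_exposure = exp$beta,
               se_exposure = exp$se, p_exposure = exp$p,
               beta_outcome = aligned$beta, se_outcome = aligned$se,
               eaf = exp$eaf, stringsAsFactors = FALSE)
}

#' Harmonize instrument tables
#'
#' Applies [harmonizePair()] across the variants present in both the
#' exposure and outcome tables; dropped pairs are counted in the `dropped`
#' attribute.
#'
#' @param exposure,outcome summary-statistics data.frames.
#' @return instrument data.frame.
#' @export
harmonizeInstruments <- function(exposure, outcome) {
    shared <- intersect(exposure$snp, outcome$snp)
    rows <- lapply(shared, function(s)
        harmonizePair(exposure[exposure$snp == s, , drop = FALSE],
                      outcome[outcome$snp == s, , drop = FALSE]))
    dropped <- sum(vapply(rows, is.null, logical(1)))
    if (dropped) message(dropped, " instrument pair(s) dropped in harmonization")
    out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
    structure(out, dropped = dropped)
}

.mr_result <- function(method, beta, se, n, egger_intercept = NA_real_,
                       egger_intercept_p = NA_real_, q = NA_real_,
                       q_p = NA_real_) {
    z <- beta / se
    data.frame(method = method, beta = beta, se = se, p = zToP(z),
               n_snps = n, egger_intercept = egger_intercept,
               egger_intercept_p = egger_intercept_p, q = q, q_p = q_p,
               stringsAsFactors = FALSE)
}

.ratio_estimates <- function(x) {
    keep <- x$beta_exposure != 0
    if (any(!keep)) message(sum(!keep), " instrument(s) with zero exposure effect dropped")
    x <- x[keep, , drop = FALSE]
    list(x = x, r = x$beta_outcome / x$beta_exposure,
         se = x$se_outcome / abs(x$beta_exposure))
}

#' Two-sample MR estimators
#'
#' Five estimators over a harmonized instrument table:
#' * `mrIVW()` — inverse-variance-weighted regression of outcome on
#'   exposure effects through the origin, weights `1/se_outcome^2`
#'   (fixed-effect standard error `1/sqrt(sum(w x^2))`), with Cochran's Q;
#' * `mrEgger()` — the same weighted regression with a free intercept; the
#'   intercept and its p-value diagnose directional pleiotropy;
#' * `mrWeightedMedian()` — weighted median of the per-instrument ratio
#'   estimates with inverse-variance weights; standard error by parametric
#'   bootstrap;
#' * `mrSimpleMode()` / `mrWeightedMode()` — mode of the kernel-smoothed
#'   ratio-estimate density (uniform / inverse-variance weights), standard
#'   error by parametric bootstrap.
#'
#' @param instruments instrument data.frame from [harmonizeInstruments()].
#' @return one-row data.frame (`method beta se p n_snps egger_intercept
#'   egger_intercept_p q q_p`).
#' @export
mrIVW <- function(instruments) {
    x <- instruments$beta_exposure; y <- instruments$beta_outcome
    w <- 1 / instruments$se_outcome^2
    if (length(x) < 2) stop("IVW needs at least 2 instruments")
    theta <- sum(w * x * y) / sum(w * x^2)
    se <- 1 / sqrt(sum(w * x^2))
    q <- sum(w * (y - theta * x)^2)
    q_p <- pchisq(q, df = length(x) - 1, lower.tail = FALSE)
    .mr_result("IVW", theta, se, length(x), q = q, q_p = q_p)
}

#' @rdname mrIVW
#' @export
mrEgger <- function(instruments) {
    x <- instruments$beta_exposure; y <- instruments$beta_outcome
    w <- 1 / instruments$se_outcome^2
    n <- length(x)
    if (n < 3) stop("Egger regression needs at least 3 instruments")
    ## orientation convention: exposure effects positive
    y <- y * sign(x); x <- abs(x)
    fit <- lm(y ~ x, weights = w)
    sm <- summary(fit)$coefficients
    q <- sum(w * fit$residuals^2)
    .mr_result("Egger", sm["x", 1], sm["x", 2], n,
               egger_intercept = sm["(Intercept)", 1],
               egger_intercept_p = sm["(Intercept)", 4],
               q = q, q_p = pchisq(q, df = n - 2, lower.tail = FALSE))
}

.weighted_median <- function(r, w) {
    ord <- order(r)
    r <- r[ord]; w <- w[ord] / sum(w)
    cw <- cumsum(w) - w / 2
    approx(cw, r, xout = 0.5, rule = 2)$y
}

#' @rdname mrIVW
#' @param nBoot parametric-bootstrap replicates for the standard error.
#' @param seed optional integer seed for the bootstrap.
#' @export
mrWeightedMedian <- function(instruments, nBoot = 1000L, seed = NULL) {
    re <- .ratio_estimates(instruments)
    n <- nrow(re$x)
    if (n < 3) stop("weighted median needs at least 3 instruments")
    w <- 1 / re$se^2
    est <- .weighted_median(re$r, w)
    if (!is.null(seed)) set.seed(seed)
    boots <- vapply(seq_len(nBoot), function(i) {
        bx <- rnorm(n, re$x$beta_exposure, re$x$se_exposure)
        by <- rnorm(n, re$x$beta_outcome, re$x$se_outcome)
        rb <- by / bx
        .weighted_median(rb, 1 / (re$x$se_outcome / abs(bx))^2)
    }, numeric(1))
    .mr_result("weighted_median", est, stats::sd(boots), n)
}

.mode_estimate <- function(r, w, bandwidth) {
    s <- 0.9 * min(stats::sd(r), mad(r)) / length(r)^(1 / 5)
    if (!is.finite(s) || s <= 0) s <- stats::sd(r) / length(r)^(1 / 5)
    if (!is.finite(s) || s <= 0) return(r[1])
    ## density() warns when bw is tiny relative to the spread of near-ties;
    ## the mode location is unaffected
    d <- suppressWarnings(density(r, weights = w / sum(w), bw = bandwidth * s))
    d$x[which.max(d$y)]
}

.mr_mode <- function(instruments, weighted, bandwidth, nBoot, seed, label) {
    re <- .ratio_estimates(instruments)
    n <- nrow(re$x)
    if (n < 3) stop("mode estimators need at least 3 instruments")
    w <- if (weighted) 1 / re$se^2 else rep(1, n)
    est <- .mode_estimate(re$r, w, bandwidth)
    if (!is.null(seed)) set.seed(seed)
    boots <- vapply(seq_len(nBoot), function(i) {
        bx <- rnorm(n, re$x$beta_exposure, re$x$se_exposure)
        by <- rnorm(n, re$x$beta_outcome, re$x$se_outcome)
        wb <- if (weighted) 1 / (re$x$se_outcome / abs(bx))^2 else w
        .mode_estimate(by / bx, wb, bandwidth)
    }, numeric(1))
    .mr_result(label, est, stats::sd(boots), n)
}

#' @rdname mrIVW
#' @param bandwidth kernel bandwidth multiplier (default 1).
#' @export
mrSimpleMode <- function(instruments, bandwidth = 1, nBoot = 1000L,
                         seed = NULL) {
    .mr_mode(instruments, weighted = FALSE, bandwidth, nBoot, seed,
             "simple_mode")
}

#' @rdname mrIVW
#' @export
mrWeightedMode <- function(instruments, bandwidth = 1, nBoot = 1000L,
                           seed = NULL) {
    .mr_mode(instruments, weighted = TRUE, bandwidth, nBoot, seed,
             "weighted_mode")
}

#' Run all five MR estimators
#'
#' @param instruments instrument data.frame.
#' @param nBoot,seed bootstrap settings for the median/mode estimators.
#' @return data.frame with one row per method.
#' @export
mrAll <- function(instruments, nBoot = 1000L, seed = NULL) {
    rbind(mrIVW(instruments), mrEgger(instruments),
          mrWeightedMedian(instruments, nBoot = nBoot, seed = seed),
          mrSimpleMode(instruments, nBoot = nBoot, seed = seed),
          mrWeightedMode(instruments, nBoot = nBoot, seed = seed))
}

#' Cochran heterogeneity of the instrument set
#'
#' `Q = sum_j (beta_outcome_j - theta * beta_exposure_j)^2 / se_outcome_j^2`
#' against the IVW estimate (or a supplied one), p from a chi-square with
#' n - 1 degrees of freedom. Per-instrument contributions are returned for
#' outlier diagnosis.
#'
#' @param instruments instrument data.frame.
#' @param theta causal estimate (defaults to the IVW estimate).
#' @return list with `q`, `p`, `df` and per-instrument `contributions`
#'   (named).
#' @export
heterogeneityQ <- function(instruments, theta = NULL) {
    if (is.null(theta)) theta <- mrIVW(instruments)$beta
    contr <- (instruments$beta_outcome - theta * instruments$beta_exposure)^2 /
        instruments$se_outcome^2
    q <- sum(contr)
    df <- nrow(instruments) - 1
    list(q = q, p = pchisq(q, df = df, lower.tail = FALSE), df = df,
         contributions = setNames(contr, instruments$snp))
}

#' Iterative heterogeneity-based outlier removal
#'
#' While the global Cochran test rejects homogeneity at `alpha` and more
#' than 3 instruments remain, removes the instrument with the largest Q
#' contribution and re-estimates. Every removal is recorded in the audit
#' trail.
#'
#' @param instruments instrument data.frame (>= 4 rows).
#' @param alpha rejection level of the global test (default 0.05).
#' @return list with `instruments` (pruned), `removed` (audit data.frame:
#'   snp, q contribution, global q and p at removal), `q` (final test).
#' @export
removeOutliers <- function(instruments, alpha = 0.05) {
    if (nrow(instruments) < 4)
        stop("outlier removal needs at least 4 instruments")
    audit <- data.frame(snp = character(), contribution = numeric(),
                        q = numeric(), q_p = numeric(),
                        stringsAsFactors = FALSE)
    repeat {
        het <- heterogeneityQ(instruments)
        if (het$p >= alpha || nrow(instruments) <= 3) break
        worst <- which.max(het$contributions)
        audit <- rbind(audit, data.frame(
            snp = instruments$snp[worst],
            contribution = unname(het$contributions[worst]),
            q = het$q, q_p = het$p, stringsAsFactors = FALSE))
        instruments <- instruments[-worst, , drop = FALSE]
    }
    list(instruments = instruments, removed = audit,
         q = heterogeneityQ(instruments))
}
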