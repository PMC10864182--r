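## Inverse-variance-weighted fixed-effects meta-analysis and diagnostics ----

#' IVW fixed-effects pooling of one variant across studies
#'
#' Pools per-study log-odds effects with weights `w_i = 1/se_i^2`:
#' `beta = sum(w b) / sum(w)`, `se = 1/sqrt(sum(w))`, z and two-sided normal
#' p, Cochran's `Q = sum(w (b - beta)^2)` and `I2 = max(0, (Q - (k-1))/Q)`.
#' Studies with nonpositive standard errors are excluded with a warning.
#'
#' @param beta per-study effects.
#' @param se per-study standard errors.
#' @return list with `beta`, `se`, `z`, `p`, `log10p`, `q`, `q_p`, `i2`,
#'   `n_studies` and the METAL-style `direction` string (`+`/`-` per study
#'   in input order, `?` for excluded entries).
#' @export
ivwMeta <- function(beta, se) {
    ok <- !is.na(beta) & !is.na(se) & se > 0
    if (any(!is.na(se) & se <= 0))
        warning("study with nonpositive standard error excluded")
    direction <- rep("?", length(beta))
    direction[ok] <- ifelse(beta[ok] >= 0, "+", "-")
    b <- beta[ok]; s <- se[ok]
    k <- length(b)
    if (!k) stop("no usable studies")
    w <- 1 / s^2
    bhat <- sum(w * b) / sum(w)
    sehat <- 1 / sqrt(sum(w))
    z <- bhat / sehat
    q <- sum(w * (b - bhat)^2)
    i2 <- if (k > 1 && q > 0) max(0, (q - (k - 1)) / q) else 0
    q_p <- if (k > 1) pchisq(q, df = k - 1, lower.tail = FALSE) else NA_real_
    list(beta = bhat, se = sehat, z = z, p = zToP(z), log10p = log10P(z),
         q = q, q_p = q_p, i2 = i2, n_studies = k,
         direction = paste(direction, collapse = ""))
}

#' Meta-analyse a set of harmonized study tables
#'
#' Runs [ivwMeta()] variant by variant across a list of summary-statistics
#' data.frames (already harmonized to common effect alleles). The pooled
#' effect-allele frequency is the effective-sample-size-weighted mean of the
#' study frequencies; case/control counts are summed over contributing
#' studies.
#'
#' @param studies named list of summary-statistics data.frames.
#' @return meta-analysis summary-statistics data.frame with `q`, `q_p`,
#'   `i2`, `n_studies`, `direction` and `z` columns.
#' @export
metaAnalyze <- function(studies) {
    snps <- unique(unlist(lapply(studies, `[[`, "snp")))
    k <- length(studies)
    get_col <- function(col) vapply(studies, function(s) {
        out <- rep(NA_real_, length(snps))
        i <- match(s$snp, snps)
        out[i] <- s[[col]]
        out
    }, numeric(length(snps)))
    B <- get_col("beta"); S <- get_col("se")
    first <- studies[[1]][match(snps, studies[[1]]$snp), ]
    for (s in studies[-1]) {
        gap <- is.na(first$snp)
        if (!any(gap)) break
        first[gap, ] <- s[match(snps[gap], s$snp), ]
    }
    res <- lapply(seq_along(snps), function(i) ivwMeta(B[i, ], S[i, ]))
    pick <- function(f) vapply(res, `[[`, numeric(1), f)
    eafW <- get_col("eaf")
    nW <- get_col("n_cas") + get_col("n_con")
    eaf <- rowSums(eafW * nW, na.rm = TRUE) / rowSums(nW * !is.na(eafW),
                                                     na.rm = TRUE)
    data.frame(snp = snps, chr = first$chr, bp = first$bp, a1 = first$a1,
               a2 = first$a2, eaf = eaf,
               beta = pick("beta"), se = pick("se"), p = pick("p"),
               n_cas = rowSums(get_col("n_cas"), na.rm = TRUE),
               n_con = rowSums(get_col("n_con"), na.rm = TRUE),
               info = NA_real_,
               n_studies = as.integer(pick("n_studies")),
               direction = vapply(res, `[[`, character(1), "direction"),
               z = pick("z"), log10p = pick("log10p"),
               q = pick("q"), i2 = pick("i2"),
               stringsAsFactors = FALSE, row.names = NULL)
}

#' Minimum-study filter
#'
#' Retains variants contributed by at least `minStudies` studies (default 2).
#'
#' @param meta meta-analysis data.frame with an `n_studies` column.
#' @param minStudies threshold.
#' @return filtered data.frame.
#' @export
minStudyFilter <- function(meta, minStudies = 2L) {
    out <- meta[!is.na(meta$n_studies) & meta$n_studies >= minStudies, ,
                drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Sensitivity-mode study inclusion filter
#'
#' In sensitivity mode, excludes studies with an extreme case-control ratio
#' (`n_cases / n_controls < 0.25`, strictly) and studies flagged as
#' adolescent cohorts. In default mode all studies are retained.
#'
#' @param studies data.frame with `study_id`, `n_cases`, `n_controls` and
#'   optionally logical `adolescent`.
#' @param sensitivity logical.
#' @param minRatio exclusion threshold on the case-control ratio.
#' @return the included rows.
#' @export
studyInclusionFilter <- function(studies, sensitivity = FALSE,
                                 minRatio = 0.25) {
    if (!sensitivity) return(studies)
    ratio <- studies$n_cases / studies$n_controls
    adol <- if ("adolescent" %in% names(studies))
        studies$adolescent %in% TRUE
    else rep(FALSE, nrow(studies))
    out <- studies[ratio >= minRatio & !adol, , drop = FALSE]
    rownames(out) <- NULL
    out
}

.CHI1_MEDIAN <- 0.4549364

#' Genomic inflation factor
#'
#' `lambda = median(chi^2) / 0.4549364`, the median of the 1-df chi-square
#' distribution, with chi-square statistics recovered from two-sided
#' p-values.
#'
#' @param p p-values (or `chisq` supplied directly).
#' @param chisq optional 1-df chi-square statistics, used instead of `p`.
#' @return lambda.
#' @export
genomicLambda <- function(p = NULL, chisq = NULL) {
    if (is.null(chisq)) {
        if (is.null(p) || !length(p)) stop("no p-values supplied")
        chisq <- qchisq(p, df = 1, lower.tail = FALSE)
    }
    if (!length(chisq)) stop("no statistics supplied")
    median(chisq) / .CHI1_MEDIAN
}

#' Sample-size-standardized inflation factor
#'
#' `lambda_1000 = 1 + (lambda - 1) * (1/nCases + 1/nControls) * 500`,
#' the genomic inflation rescaled to a study of 1,000 cases and 1,000
#' controls.
#'
#' @param lambda genomic inflation factor.
#' @param nCases,nControls crude case and control counts.
#' @return lambda_1000.
#' @export
lambda1000 <- function(lambda, nCases, nControls) {
    1 + (lambda - 1) * (1 / nCases + 1 / nControls) * 500
}

#' LDSC-intercept correction of meta-analysis test statistics
#'
#' Divides the association chi-square statistics by a supplied LDSC
#' intercept (equivalently scales standard errors by `sqrt(intercept)`),
#' recomputing z and p; effect estimates are unchanged. The intercept is an
#' input, never estimated here.
#'
#' @param meta meta-analysis data.frame with `beta` and `se`.
#' @param intercept LDSC intercept (> 0; values >= 1 expected).
#' @return corrected data.frame; attribute `intercept` records the value.
#' @export
applyInterceptCorrection <- function(meta, intercept) {
    if (!is.numeric(intercept) || intercept <= 0)
        stop("intercept must be positive")
    meta$se <- meta$se * sqrt(intercept)
    z <- meta$beta / meta$se
    if ("z" %in% names(meta)) meta$z <- z
    meta$p <- zToP(z)
    if ("log10p" %in% names(meta)) meta$log10p <- log10P(z)
    structure(meta, intercept = intercept)
}

#' Aggregate independent leads into loci
#'
#' Each independent lead defines an interval of +/- `flankBp` (250 kb).
#' Leads on the same chromosome separated by less than `mergeBp` (500 kb)
#' are aggregated transitively into a single locus with multiple member
#' leads; the locus lead is the minimum-p member and the span is the final
#' lead +/- `flankBp`. Loci are returned sorted by chromosome and position.
#'
#' @param leads data.frame of independent lead variants (`snp`, `chr`,
#'   `bp`, `p`).
#' @param flankBp flank on each side of the lead.
#' @param mergeBp lead-to-lead aggregation distance.
#' @return data.frame with one row per locus: `snp chr bp p start end
#'   n_signals members` (members semicolon-separated).
#' @export
defineLoci <- function(leads, flankBp = 250000L, mergeBp = 500000L) {
    if (!nrow(leads)) return(data.frame())
    leads <- leads[order(leads$chr, leads$bp), , drop = FALSE]
    grp <- integer(nrow(leads)); g <- 0L
    for (i in seq_len(nrow(leads))) {
        if (i == 1L || leads$chr[i] != leads$chr[i - 1L] ||
            leads$bp[i] - leads$bp[i - 1L] >= mergeBp) g <- g + 1L
        grp[i] <- g
    }
    out <- do.call(rbind, lapply(split(leads, grp), function(m) {
        lead <- m[which.min(m$p), , drop = FALSE]
        data.frame(snp = lead$snp, chr = lead$chr, bp = lead$bp, p = lead$p,
                   start = max(1L, lead$bp - flankBp), end = lead$bp + flankBp,
                   n_signals = nrow(m),
                   members = paste(m$snp, collapse = ";"),
                   stringsAsFactors = FALSE)
    }))
    out <- out[order(out$chr, out$bp), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Classify a lead variant as novel
#'
#' A lead is novel when, for every previously reported variant, it is both
#' uncorrelated (`r^2 < 0.1`) and more than 250 kb away. Catalogue variants
#' absent from the LD panel (or when no panel is given) are compared by
#' distance only, with a warning.
#'
#' @param lead one-row data.frame (`snp`, `chr`, `bp`).
#' @param catalogue known-loci data.frame (`snp`, `chr`, `bp`).
#' @param ld optional [LDMatrix-class] covering lead and catalogue variants.
#' @param r2Max,distBp thresholds of the conjunction rule.
#' @return logical.
#' @export
classifyNovel <- function(lead, catalogue, ld = NULL, r2Max = 0.1,
                          distBp = 250000L) {
    if (!nrow(catalogue)) return(TRUE)
    dist_ok <- lead$chr != catalogue$chr | abs(lead$bp - catalogue$bp) > distBp
    r2 <- rep(0, nrow(catalogue))
    have_ld <- FALSE
    if (!is.null(ld) && lead$snp %in% ld@variants$snp) {
        hit <- catalogue$snp %in% ld@variants$snp
        r2[hit] <- ld@r[lead$snp, catalogue$snp[hit]]^2
        have_ld <- TRUE
        if (any(!hit))
            warning("catalogue variant(s) absent from LD panel; distance-only rule used for them")
    } else {
        warning("lead absent from LD panel; distance-only novelty rule applied")
    }
    r2[catalogue$snp == lead$snp] <- 1
    all(dist_ok & r2 < r2Max)
}
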