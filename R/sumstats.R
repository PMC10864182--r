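## Canonical summary-statistics table ---------------------------------------
##
## A summary-statistics table is a plain data.frame with (lower-case) columns
##   snp chr bp a1 a2 eaf beta se p n_cas n_con info n_studies direction
## a1 is the effect allele. On disk the canonical dialect uses the upper-case
## headers SNP CHR BP A1 A2 EAF BETA SE P N_CAS N_CON INFO N_STUDIES DIRECTION
## with "." for missing values, tab-delimited, header required.

.CANON <- c(SNP = "snp", CHR = "chr", BP = "bp", A1 = "a1", A2 = "a2",
            EAF = "eaf", BETA = "beta", SE = "se", P = "p",
            N_CAS = "n_cas", N_CON = "n_con", INFO = "info",
            N_STUDIES = "n_studies", DIRECTION = "direction")

.MANDATORY <- c("snp", "chr", "bp", "a1", "a2", "beta", "se", "p")
.NUMERIC_COLS <- c("bp", "eaf", "beta", "se", "p", "n_cas", "n_con",
                   "info", "n_studies")

#' Read GWAS summary statistics
#'
#' Reads a tab-separated summary-statistics file in the canonical dialect
#' (columns `SNP CHR BP A1 A2 EAF BETA SE P N_CAS N_CON INFO N_STUDIES
#' DIRECTION`, `"."` for missing) or a user dialect mapping file headers to
#' canonical names. Rows missing a mandatory field (id, position, alleles,
#' beta, se, p) are dropped; the number dropped is reported via a message and
#' the `"dropped"` attribute.
#'
#' @param path path to a tab-delimited file with a header line.
#' @param dialect named character vector mapping file column names to
#'   canonical names, e.g. `c(rsid = "snp", pos = "bp")`; `NULL` for the
#'   canonical dialect.
#' @return data.frame of summary statistics with attribute `dropped`.
#' @seealso [writeSumstats()]
#' @export
readSumstats <- function(path, dialect = NULL) {
    if (!file.exists(path)) stop("file not found: ", path)
    raw <- read.table(path, header = TRUE, sep = "\t", na.strings = ".",
                      stringsAsFactors = FALSE, check.names = FALSE,
                      colClasses = "character")
    map <- if (is.null(dialect)) .CANON else dialect
    hit <- names(raw) %in% names(map)
    names(raw)[hit] <- unname(map[names(raw)[hit]])
    raw <- raw[, names(raw) %in% unname(.CANON), drop = FALSE]
    miss <- setdiff(.MANDATORY, names(raw))
    if (length(miss))
        stop("mandatory column(s) missing from ", path, ": ",
             paste(miss, collapse = ", "))
    for (col in intersect(.NUMERIC_COLS, names(raw)))
        raw[[col]] <- suppressWarnings(as.numeric(raw[[col]]))
    ok <- complete.cases(raw[, .MANDATORY])
    dropped <- sum(!ok)
    if (dropped) message(dropped, " row(s) dropped for missing mandatory fields")
    out <- raw[ok, , drop = FALSE]
    rownames(out) <- NULL
    structure(out, dropped = dropped)
}

#' Write GWAS summary statistics
#'
#' Writes a summary-statistics data.frame in the canonical tab-delimited
#' dialect, `"."` for missing values.
#'
#' @param x summary-statistics data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeSumstats <- function(x, path) {
    cols <- .CANON[unname(.CANON) %in% names(x)]
    out <- x[, unname(cols), drop = FALSE]
    names(out) <- names(cols)
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                na = ".")
    invisible(path)
}

#' Recode indel alleles to insertion/deletion codes
#'
#' Multi-base (or length-discordant) allele pairs are recoded so that the
#' longer allele becomes `"I"` and the shorter `"D"`. Positions at which two
#' or more distinct indel patterns occur have all their indel records
#' removed, and equal-length multi-base pairs are dropped with a warning
#' since the longer/shorter rule cannot orient them. SNVs pass through
#' untouched.
#'
#' @param x summary-statistics data.frame.
#' @return the recoded data.frame.
#' @export
recodeIndels <- function(x) {
    l1 <- nchar(x$a1); l2 <- nchar(x$a2)
    is_indel <- l1 > 1L | l2 > 1L
    ambiguous <- is_indel & l1 == l2
    if (any(ambiguous)) {
        warning(sum(ambiguous),
                " equal-length multi-base record(s) dropped (ambiguous pattern)")
    }
    pattern <- ifelse(is_indel & !ambiguous,
                      paste(pmin(x$a1, x$a2), pmax(x$a1, x$a2)), NA)
    key <- paste(x$chr, x$bp)
    multi <- vapply(split(pattern[is_indel & !ambiguous],
                          key[is_indel & !ambiguous]),
                    function(p) length(unique(p)) > 1L, logical(1))
    clash <- is_indel & !ambiguous & key %in% names(multi)[multi]
    keep <- !(ambiguous | clash)
    x <- x[keep, , drop = FALSE]
    is_indel <- is_indel[keep]; l1 <- l1[keep]; l2 <- l2[keep]
    a1 <- x$a1; a2 <- x$a2
    x$a1[is_indel] <- ifelse(l1[is_indel] > l2[is_indel], "I", "D")
    x$a2[is_indel] <- ifelse(l1[is_indel] > l2[is_indel], "D", "I")
    rownames(x) <- NULL
    x
}

.flip_allele <- function(a) {
    chartr("ACGT", "TGCA", a)
}

.is_palindromic <- function(a1, a2) {
    (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

#' Harmonize a record to reference alleles
#'
#' Aligns one association record to a reference effect/other allele pair.
#' When the record's alleles are swapped relative to the reference the
#' effect sign is flipped and the effect-allele frequency complemented;
#' strand-flipped orientations are recognised through base complementation.
#' Palindromic pairs (A/T, C/G) are orientated by frequency only when both
#' the record and reference frequency are available and both clearly off
#' 0.5 (both < 0.42 or both > 0.58 on the minor side); otherwise the record
#' is excluded. An incompatible allele pair is excluded.
#'
#' @param rec one-row summary-statistics data.frame.
#' @param refA1,refA2 reference effect and other allele.
#' @param refEaf reference effect-allele frequency (used for palindromic
#'   resolution only).
#' @return the harmonized one-row data.frame, or `NULL` when the record is
#'   excluded (incompatible or unresolvable palindromic pair).
#' @export
harmonizeToReference <- function(rec, refA1, refA2, refEaf = NA_real_) {
    a1 <- rec$a1; a2 <- rec$a2
    if (.is_palindromic(a1, a2)) {
        eaf <- rec$eaf
        if (is.na(eaf) || is.na(refEaf)) return(NULL)
        if (!((a1 == refA1 && a2 == refA2) || (a1 == refA2 && a2 == refA1)))
            return(NULL)
        ## allele labels cannot orient a palindromic pair (a label swap and a
        ## strand flip are the same operation), so frequency decides: when
        ## both EAFs sit clearly on the same side of 0.5 the effect alleles
        ## are taken as matched; anything else is unresolvable and excluded
        if ((eaf < 0.42 && refEaf < 0.42) || (eaf > 0.58 && refEaf > 0.58))
            swapped <- FALSE
        else return(NULL)
    } else if ((a1 == refA1 && a2 == refA2) ||
               (.flip_allele(a1) == refA1 && .flip_allele(a2) == refA2)) {
        swapped <- FALSE
    } else if ((a1 == refA2 && a2 == refA1) ||
               (.flip_allele(a1) == refA2 && .flip_allele(a2) == refA1)) {
        swapped <- TRUE
    } else {
        return(NULL)
    }
    if (swapped) {
        rec$beta <- -rec$beta
        if ("eaf" %in% names(rec)) rec$eaf <- 1 - rec$eaf
    }
    rec$a1 <- refA1; rec$a2 <- refA2
    rec
}

#' Post-imputation quality-control filter
#'
#' Keeps records with imputation info score >= 0.7 and effective allele
#' count `2 * MAF * (1 - MAF) * N * R^2 >= 50`, where MAF is the minor
#' allele frequency and R^2 the info score. Small studies (effective half
#' sample size below `smallStudyNeff`, default 2,000) are additionally
#' required to have MAF >= 0.05. Records with missing info or frequency are
#' removed. Per-criterion removal counts are attached as attribute
#' `"filtered"`.
#'
#' @param x summary-statistics data.frame with `eaf` and `info` columns.
#' @param nTotal total sample size used in the effective-allele-count
#'   formula.
#' @param smallStudy logical; apply the MAF >= 0.05 small-study rule.
#' @param infoMin,eacMin,mafMin thresholds.
#' @return the filtered data.frame with attribute `filtered` (named counts).
#' @export
qcFilter <- function(x, nTotal, smallStudy = FALSE,
                     infoMin = 0.7, eacMin = 50, mafMin = 0.05) {
    maf <- pmin(x$eaf, 1 - x$eaf)
    eac <- 2 * maf * (1 - maf) * nTotal * x$info
    fail_info <- is.na(x$info) | x$info < infoMin
    fail_eac <- is.na(eac) | eac < eacMin
    fail_maf <- if (smallStudy) is.na(maf) | maf < mafMin else rep(FALSE, nrow(x))
    keep <- !(fail_info | fail_eac | fail_maf)
    out <- x[keep, , drop = FALSE]
    rownames(out) <- NULL
    structure(out, filtered = c(info = sum(fail_info), eac = sum(fail_eac),
                                maf = sum(fail_maf)))
}

#' Score-test statistics to beta / log-odds scale
#'
#' `scoreToBeta()` converts a score-test numerator and its variance to an
#' effect and standard error: `beta = score / variance`,
#' `se = sqrt(variance) / variance`. `logorScale()` then rescales both onto
#' the log-odds-ratio scale by dividing by `pi * (1 - pi)`, `pi` being the
#' case proportion of the analysis. The z-statistic `beta / se` is invariant
#' under the second step.
#'
#' @param score score-test numerator.
#' @param variance score variance (> 0).
#' @return `scoreToBeta()`: list with `beta` and `se`.
#' @export
scoreToBeta <- function(score, variance) {
    if (any(variance <= 0)) stop("score variance must be positive")
    list(beta = score / variance, se = sqrt(variance) / variance)
}

#' @rdname scoreToBeta
#' @param beta,se effect and standard error on the score-derived scale.
#' @param caseFraction case proportion `pi` in (0, 1).
#' @return `logorScale()`: list with rescaled `beta` and `se`.
#' @export
logorScale <- function(beta, se, caseFraction) {
    if (any(caseFraction <= 0 | caseFraction >= 1))
        stop("case fraction must lie strictly between 0 and 1")
    k <- caseFraction * (1 - caseFraction)
    list(beta = beta / k, se = se / k)
}

#' Effective half sample size of a case-control study
#'
#' Returns `2 / (1/nCases + 1/nControls)`, i.e. half the conventional
#' effective sample size `4 / (1/nCases + 1/nControls)`. Equal to the
#' per-arm count for a balanced design.
#'
#' @param nCases,nControls positive counts.
#' @return effective half sample size.
#' @export
effectiveSampleSize <- function(nCases, nControls) {
    if (any(nCases <= 0) || any(nControls <= 0))
        stop("case and control counts must be positive")
    2 / (1 / nCases + 1 / nControls)
}

## log10 p from z without underflow: two-sided normal tail
.z_to_log10p <- function(z) {
    (pnorm(abs(z), lower.tail = FALSE, log.p = TRUE) + log(2)) / log(10)
}

#' Two-sided normal p-value from a z-statistic
#'
#' Returns the two-sided p-value; `log10P()` returns its base-10 logarithm
#' computed in log space so extreme statistics do not underflow.
#'
#' @param z z-statistic(s).
#' @return numeric vector.
#' @export
zToP <- function(z) 2 * pnorm(abs(z), lower.tail = FALSE)

#' @rdname zToP
#' @export
log10P <- function(z) .z_to_log10p(z)

## LD matrix I/O -------------------------------------------------------------

#' Read / write an LD matrix
#'
#' The on-disk format is a variant-list file (canonical columns `SNP CHR BP
#' A1 A2`) plus a dense whitespace-delimited square matrix of signed r with
#' rows in variant-list order; `readLDMatrix()` reconstructs the validated
#' [LDMatrix-class].
#'
#' @param variantPath,matrixPath paths of the two files.
#' @return an [LDMatrix-class].
#' @export
readLDMatrix <- function(variantPath, matrixPath) {
    v <- read.table(variantPath, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
    names(v) <- unname(.CANON[names(v)])
    r <- as.matrix(read.table(matrixPath, header = FALSE))
    dimnames(r) <- list(v$snp, v$snp)
    new("LDMatrix", variants = v, r = r)
}

#' @rdname readLDMatrix
#' @param ld an [LDMatrix-class].
#' @export
writeLDMatrix <- function(ld, variantPath, matrixPath) {
    v <- ld@variants[, .VARIANT_COLS]
    names(v) <- names(.CANON)[match(names(v), unname(.CANON))]
    write.table(v, variantPath, sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(ld@r, matrixPath, sep = " ", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    invisible(variantPath)
}

#' Read a known-loci catalogue
#'
#' A catalogue of previously reported leads: tab-delimited with columns
#' `SNP CHR BP A1 A2 BETA_DISCOVERY EAF_DISCOVERY P_DISCOVERY SOURCE`.
#'
#' @param path file path.
#' @return data.frame with lower-case canonical names (`beta_discovery`,
#'   `eaf_discovery`, `p_discovery`, `source`).
#' @export
readKnownLoci <- function(path) {
    x <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
    names(x) <- tolower(names(x))
    x
}

#' @rdname readKnownLoci
#' @param x catalogue data.frame.
#' @export
writeKnownLoci <- function(x, path) {
    out <- x
    names(out) <- toupper(names(out))
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
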