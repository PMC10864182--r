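## Desk-scale calibration study designs -------------------------------------
##
## These functions wire the synthetic generator to the analysis modules in
## the three designs used to validate the pipeline: transferability
## parameter recovery, fine-mapping credible-set calibration, and DENTIST-S
## outlier calibration. They are exported so the same study definitions are
## shared by the test suite, the acceptance script and user re-runs.

#' Reference ancestry-group cohort sizes
#'
#' Case and control totals of the four non-European ancestry-group
#' meta-analyses (African, East Asian, South Asian, Hispanic/Latin
#' American) of the large multi-ancestry major-depression GWAS setting this
#' package addresses, together with the European-inclusive totals. Used for
#' cohort-accounting checks and worked examples.
#'
#' @return list with `groups` (data.frame: group, n_cases, n_controls) and
#'   `total` (named vector: n_cases, n_controls of the full multi-ancestry
#'   analysis).
#' @export
ancestryGroupCounts <- function() {
    list(groups = data.frame(
             group = c("AFR", "EAS", "SAS", "HIS"),
             n_cases = c(36818, 21980, 4505, 25013),
             n_controls = c(161679, 360956, 27176, 352946),
             stringsAsFactors = FALSE),
         total = c(n_cases = 345389, n_controls = 1469702))
}

## bind per-locus LD references into one block-diagonal panel, each locus on
## its own chromosome so distance rules never couple loci
.bind_ld <- function(lds) {
    ns <- vapply(lds, function(l) nrow(l@variants), integer(1))
    n <- sum(ns)
    r <- matrix(0, n, n)
    vs <- vector("list", length(lds))
    off <- 0L
    for (i in seq_along(lds)) {
        idx <- off + seq_len(ns[i])
        r[idx, idx] <- lds[[i]]@r
        v <- lds[[i]]@variants
        v$chr <- as.character(i)
        v$snp <- sprintf("rs%d_%d", i, seq_len(ns[i]))
        vs[[i]] <- v
        off <- off + ns[i]
    }
    v <- do.call(rbind, vs)
    dimnames(r) <- list(v$snp, v$snp)
    new("LDMatrix", variants = v, r = r)
}

#' One-seed transferability parameter-recovery study
#'
#' Simulates a European-style discovery group and one target ancestry group
#' over `nLoci` independent loci (one causal variant each, at the block
#' centre, each locus on its own chromosome), with a fraction `tau` of loci
#' sharing the causal effect in the target group and the remainder null
#' there. The discovery catalogue is built from the discovery scan, and the
#' full transferability assessment is run against the target group. Effects
#' are sized so target-group power is essentially complete, isolating the
#' transfer decision from the power model.
#'
#' @param tau true transferable fraction in \[0, 1\].
#' @param seed integer seed.
#' @param nLoci,blockSize,rho locus architecture (AR-1 blocks).
#' @param beta causal log-odds effect.
#' @param fst Balding-Nichols drift of each group from the shared
#'   ancestral frequencies (drawn uniformly on \[0.2, 0.8\]).
#' @param nEffHalfDiscovery,nEffHalfTarget effective half sample sizes
#'   (balanced designs are simulated).
#' @param pf penalization factor for the target group.
#' @param nBoot bootstrap replicates for the PAT interval.
#' @return a [PATResult-class]; attribute `nCatalogue` records the number
#'   of discovered loci entering the assessment.
#' @export
simulateTransferabilityStudy <- function(tau, seed = NULL, nLoci = 40L,
                                         blockSize = 5L, rho = 0.6,
                                         beta = 0.12, fst = 0.05,
                                         nEffHalfDiscovery = 50000,
                                         nEffHalfTarget = 20000,
                                         pf = 0.008341, nBoot = 200L) {
    if (!is.null(seed)) set.seed(seed)
    ld <- .bind_ld(replicate(nLoci,
        simulateLDMatrix(blockSize, rho, spacingBp = 10000L),
        simplify = FALSE))
    nv <- nLoci * blockSize
    causal <- (seq_len(nLoci) - 1L) * blockSize + ceiling(blockSize / 2)
    ancestral <- runif(nv, 0.2, 0.8)
    fD <- simulateAlleleFreqs(nv, fst = fst, ancestral = ancestral)
    fT <- simulateAlleleFreqs(nv, fst = fst, ancestral = ancestral)
    shared <- seq_len(nLoci) <= round(tau * nLoci)
    bD <- bT <- numeric(nv)
    bD[causal] <- beta
    bT[causal[shared]] <- beta
    discovery <- simulateZscores(ld, bD, fD, nEffHalfDiscovery,
                                 nEffHalfDiscovery)
    target <- simulateZscores(ld, bT, fT, nEffHalfTarget, nEffHalfTarget)
    catalogue <- generateKnownLoci(discovery)
    res <- assessTransferability(catalogue, discovery, target, ld, pf = pf,
                                 nCases = nEffHalfTarget,
                                 nControls = nEffHalfTarget, nBoot = nBoot)
    attr(res, "nCatalogue") <- nrow(catalogue)
    res
}

#' Fine-mapping credible-set calibration study
#'
#' Simulates `nLoci` independent single-causal loci (causal variant at the
#' block centre of an AR-1 LD block) in several ancestry groups sharing the
#' causal effect but differing in LD decay — the feature of real
#' multi-ancestry panels that drives credible-set refinement, since proxies
#' tagging the causal variant in one group fail to tag it in another. Each
#' locus is fine-mapped with the multi-ancestry posterior (all groups
#' pooled, heterogeneity prior, members taken from the averaged
#' multi-ancestry LD panel) and with the single-ancestry comparator (first
#' group only, its own LD panel, no prior); the study records whether each
#' 99 percent credible set contains the causal variant and how large it is.
#'
#' @param nLoci number of simulated loci.
#' @param seed integer seed.
#' @param blockSize variants per locus.
#' @param rho per-group AR-1 correlations; the length sets the number of
#'   ancestry groups. The default emulates a high-LD discovery group plus
#'   a low-LD group.
#' @param beta shared causal log-odds effect.
#' @param fst Balding-Nichols drift per group.
#' @param nEffHalf per-group effective half sample size.
#' @return data.frame, one row per locus: `covered_multi`,
#'   `covered_single`, `size_multi`, `size_single`, `lead_is_causal`.
#' @export
simulateFineMapCalibration <- function(nLoci = 500L, seed = NULL,
                                       blockSize = 30L, rho = c(0.9, 0.5),
                                       beta = 0.07, fst = 0.05,
                                       nEffHalf = 20000) {
    if (!is.null(seed)) set.seed(seed)
    nGroups <- length(rho)
    rows <- vector("list", nLoci)
    for (l in seq_len(nLoci)) {
        lds <- lapply(rho, function(rg) simulateLDMatrix(blockSize, rg))
        rbar <- Reduce(`+`, lapply(lds, ldR)) / nGroups
        multiLD <- new("LDMatrix", variants = lds[[1]]@variants, r = rbar)
        causal <- ceiling(blockSize / 2)
        ancestral <- runif(blockSize, 0.2, 0.8)
        b <- numeric(blockSize); b[causal] <- beta
        groups <- lapply(seq_len(nGroups), function(g) {
            f <- simulateAlleleFreqs(blockSize, fst = fst,
                                     ancestral = ancestral)
            simulateZscores(lds[[g]], b, f, nEffHalf, nEffHalf)
        })
        names(groups) <- paste0("G", seq_len(nGroups))
        ## lead = minimum-p variant of the pooled statistics
        pooled <- perVariantMetaI2(
            extractLocus(lds[[1]]@variants$snp[1], groups, multiLD,
                         r2Min = -1))
        lead <- pooled$snp[which.max(pooled$chisq)]
        multi <- posteriorPips(
            perVariantMetaI2(extractLocus(lead, groups, multiLD)),
            mode = "multi")
        single <- posteriorPips(
            perVariantMetaI2(extractLocus(lead, groups[1], lds[[1]])),
            mode = "single")
        causal_id <- lds[[1]]@variants$snp[causal]
        rows[[l]] <- data.frame(
            covered_multi = causal_id %in% credibleSet(multi),
            covered_single = causal_id %in% credibleSet(single),
            size_multi = credibleSetSize(multi),
            size_single = credibleSetSize(single),
            lead_is_causal = lead == causal_id)
    }
    do.call(rbind, rows)
}

#' DENTIST-S calibration study
#'
#' Simulates `nLoci` consistent single-causal loci (LD reference matching
#' the generating model) and runs the SLALOM scan on each. With
#' `plantFlip = TRUE`, the z-score of the variant adjacent to the causal
#' variant (r^2 = rho^2 to it) has its sign flipped before the scan,
#' emulating an allele-alignment error.
#'
#' @param nLoci number of loci.
#' @param seed integer seed.
#' @param blockSize,rho LD architecture.
#' @param beta causal log-odds effect (sized for lead z around 8).
#' @param nEffHalf effective half sample size.
#' @param plantFlip plant a sign-flip outlier at each locus.
#' @return list: `nScanned` variants scanned, `nOutliers` flagged,
#'   `outlierRate` per scanned variant, `lociApplied`, and with a planted
#'   flip `plantFlagged` / `plantRate` (loci where the planted variant was
#'   flagged).
#' @export
simulateDentistCalibration <- function(nLoci = 300L, seed = NULL,
                                       blockSize = 10L, rho = 0.9,
                                       beta = 0.09, nEffHalf = 20000,
                                       plantFlip = FALSE) {
    if (!is.null(seed)) set.seed(seed)
    nScan <- 0L; nOut <- 0L; applied <- 0L; plantHit <- 0L
    for (l in seq_len(nLoci)) {
        ld <- simulateLDMatrix(blockSize, rho)
        causal <- ceiling(blockSize / 2)
        f <- runif(blockSize, 0.2, 0.8)
        b <- numeric(blockSize); b[causal] <- beta
        ss <- simulateZscores(ld, b, f, nEffHalf, nEffHalf)
        plant_id <- ld@variants$snp[causal + 1L]
        if (plantFlip) {
            i <- causal + 1L
            ss$z[i] <- -ss$z[i]
            ss$beta[i] <- -ss$beta[i]
        }
        fm <- fineMapLocus(ld@variants$snp[causal], list(G1 = ss), ld)
        sl <- fm$slalom
        if (!sl@applied) next
        applied <- applied + 1L
        nScan <- nScan + nrow(sl@table)
        nOut <- nOut + sum(sl@table$outlier)
        if (plantFlip &&
            isTRUE(sl@table$outlier[match(plant_id, sl@table$snp)]))
            plantHit <- plantHit + 1L
    }
    out <- list(nScanned = nScan, nOutliers = nOut,
                outlierRate = if (nScan) nOut / nScan else NA_real_,
                lociApplied = applied)
    if (plantFlip) {
        out$plantFlagged <- plantHit
        out$plantRate <- if (applied) plantHit / applied else NA_real_
    }
    out
}
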