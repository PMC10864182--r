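test_that("locus extraction applies the r2 > 0.1 rule deterministically", {
    # rho chosen so r2 crosses 0.1 between lag 3 and 4: 0.68^6 = 0.099,
    # 0.68^4... use explicit check below
    ld <- simulateLDMatrix(9, 0.68)
    v <- ldVariants(ld)
    lead <- v$snp[5]
    r2 <- ldR(ld)[lead, ]^2
    locus <- extractLocus(lead, list(G = make_ss(v$snp, v$bp,
        rep(0.1, 9), rep(0.02, 9))), ld)
    expect_setequal(locus@members$snp, v$snp[r2 > 0.1])
    expect_false(any(r2[setdiff(v$snp, locus@members$snp)] > 0.1))
    # member order is by position and stable
    expect_equal(locus@members$bp, sort(locus@members$bp))
    # no correlated neighbour: single-member locus
    ld0 <- simulateLDMatrix(c(1, 1, 1), 0)
    ss0 <- make_ss(ldVariants(ld0)$snp, ldVariants(ld0)$bp, rep(0.1, 3),
                   rep(0.02, 3))
    expect_equal(nrow(extractLocus("rs2", list(G = ss0), ld0)@members), 1)
    expect_error(extractLocus("nope", list(G = ss0), ld0), "absent")
})

test_that("per-variant pooling reduces to ivwMeta and yields hand I2", {
    ld <- simulateLDMatrix(2, 0.5)
    v <- ldVariants(ld)
    gA <- make_ss(v$snp, v$bp, c(0.2, 0.1), c(0.02, 0.05))
    gB <- make_ss(v$snp, v$bp, c(-0.2, 0.1), c(0.02, 0.05))
    locus <- extractLocus(v$snp[1], list(A = gA, B = gB), ld)
    stats <- perVariantMetaI2(locus)
    # hand evaluation: +0.2/-0.2 at se 0.02 -> Q = 200, I2 = 0.995
    expect_equal(stats$q[1], 200)
    expect_equal(stats$i2[1], 0.995)
    expect_equal(stats$beta[1], 0)
    # identical estimates in both groups: I2 = 0
    expect_equal(stats$i2[2], 0)
    # oracle equivalence with the meta-analysis module
    fit <- ivwMeta(c(0.2, -0.2), c(0.02, 0.02))
    expect_equal(stats$beta[1], fit$beta)
    expect_equal(stats$chisq[1], fit$z^2)
    # a member observed in one group only: I2 = 0 by convention
    gB2 <- gB[1, ]
    stats2 <- perVariantMetaI2(extractLocus(v$snp[1],
        list(A = gA, B = gB2), ld))
    expect_equal(stats2$i2[2], 0)
    expect_equal(stats2$k[2], 1)
})

test_that("heterogeneity prior is monotone, floored and normalized", {
    expect_equal(heterogeneityPrior(c(0, 0, 0)), rep(1 / 3, 3))
    expect_equal(heterogeneityPrior(c(0, 0.5)), c(2 / 3, 1 / 3))
    pri <- heterogeneityPrior(seq(0, 1, 0.1))
    expect_equal(sum(pri), 1)
    expect_true(all(diff(pri[1:10]) < 0))     # decreasing below the floor
    # the floor keeps fully heterogeneous members admissible
    expect_gt(heterogeneityPrior(c(0, 1))[2], 0)
})

test_that("PIPs follow chi-square-times-prior weighting and accumulate", {
    stats <- data.frame(snp = c("a", "b"), bp = c(1, 2), chisq = c(10, 5),
                        i2 = c(0, 0))
    ps <- posteriorPips(stats, mode = "multi")
    expect_equal(unname(pip(ps)), c(2 / 3, 1 / 3))
    ps2 <- posteriorPips(stats, mode = "multi", prior = c(0.8, 0.2))
    expect_equal(unname(pip(ps2)), c(8 / 9, 1 / 9))
    # single mode ignores the prior
    stats$i2 <- c(0.9, 0)
    ps3 <- posteriorPips(stats, mode = "single")
    expect_equal(unname(pip(ps3)), c(2 / 3, 1 / 3))
    # single-member locus
    ps4 <- posteriorPips(data.frame(snp = "a", bp = 1, chisq = 3, i2 = 0))
    expect_equal(unname(pip(ps4)), 1)
    expect_equal(credibleSetSize(ps4), 1)
    # all-zero statistics: uniform with a warning
    expect_warning(ps5 <- posteriorPips(data.frame(snp = c("a", "b"),
        bp = 1:2, chisq = c(0, 0), i2 = c(0, 0))), "zero")
    expect_equal(unname(pip(ps5)), c(0.5, 0.5))
})

test_that("credible sets are minimal descending-PIP prefixes", {
    mk <- function(pips) {
        n <- length(pips)
        # chisq proportional to pips with uniform prior reproduces them
        posteriorPips(data.frame(snp = letters[1:n], bp = 1:n,
                                 chisq = pips * 100, i2 = rep(0, n)),
                      mode = "single")
    }
    expect_equal(credibleSetSize(mk(c(0.6, 0.3, 0.08, 0.02))), 4)
    expect_equal(credibleSetSize(mk(c(0.995, 0.004, 0.001))), 1)
    ps <- mk(c(0.5, 0.3, 0.15, 0.04, 0.01))
    expect_equal(credibleSet(ps), c("a", "b", "c", "d"))
    expect_gte(sum(pip(ps)[credibleSet(ps)]), 0.99)
    # PIPs and priors sum to one (validity enforces it too)
    expect_equal(sum(pip(ps)), 1, tolerance = 1e-12)
    # with one ancestry group multi equals single exactly (all I2 = 0)
    stats1 <- data.frame(snp = letters[1:4], bp = 1:4,
                         chisq = c(9, 4, 1, 0.2), i2 = rep(0, 4))
    expect_equal(pip(posteriorPips(stats1, "multi")),
                 pip(posteriorPips(stats1, "single")))
})

test_that("multi- vs single-ancestry set comparison summarizes sizes", {
    stats <- data.frame(snp = letters[1:3], bp = 1:3,
                        chisq = c(50, 1, 0.5), i2 = c(0, 0.9, 0.9))
    cmp <- compareCredibleSets(posteriorPips(stats, "multi"),
                               posteriorPips(stats, "single"))
    expect_true(all(c("size_multi", "size_single") %in% names(cmp)))
    summ <- summarizeCredibleSets(rbind(cmp, cmp))
    expect_equal(summ$median_multi, cmp$size_multi)
    # identical inputs and uniform priors give equal sizes
    stats0 <- data.frame(snp = letters[1:3], bp = 1:3,
                         chisq = c(5, 3, 2), i2 = rep(0, 3))
    cmp0 <- compareCredibleSets(posteriorPips(stats0, "multi"),
                                posteriorPips(stats0, "single"))
    expect_equal(cmp0$size_multi, cmp0$size_single)
})

test_that("DENTIST-S matches hand arithmetic and its invariances", {
    # perfect consistency: z_i = r * z_lead
    expect_equal(dentistS(5.4, 6, 0.9)$statistic, 0, tolerance = 1e-12)
    expect_equal(dentistS(5.4, 6, 0.9)$p, 1)
    # r = 0 reduces to z^2
    expect_equal(dentistS(2, 7, 0)$statistic, 4)
    # hand case: (1 - 5.4)^2 / 0.19
    d <- dentistS(1, 6, 0.9)
    expect_equal(d$statistic, (1 - 5.4)^2 / (1 - 0.81))
    expect_lt(d$p, 1e-4)
    # sign symmetries: flipping the trait direction (both z-scores) or
    # flipping one variant's effect allele (its z together with r) leaves
    # the statistic unchanged
    set.seed(51)
    for (i in 1:20) {
        z <- rnorm(1, 0, 3); zl <- rnorm(1, 0, 3); r <- runif(1, -0.99, 0.99)
        expect_equal(dentistS(z, zl, r)$statistic,
                     dentistS(-z, -zl, r)$statistic)
        expect_equal(dentistS(z, zl, r)$statistic,
                     dentistS(-z, zl, -r)$statistic)
    }
    expect_warning(d1 <- dentistS(1, 2, 1), "perfect LD")
    expect_true(is.na(d1$statistic))
})

test_that("SLALOM gates on max PIP and flags planted inconsistencies", {
    ld <- simulateLDMatrix(10, 0.9)
    v <- ldVariants(ld)
    ss <- simulateZscores(ld, beta = c(rep(0, 4), 0.09, rep(0, 5)),
                          eaf = rep(0.3, 10), 20000, 20000, seed = 61)
    fm <- fineMapLocus(v$snp[5], list(G = ss), ld)
    expect_true(fm$slalom@applied)
    # low-PIP loci are not scanned
    flat <- posteriorPips(data.frame(snp = v$snp, bp = v$bp,
        chisq = rep(1, 10), i2 = rep(0, 10)), mode = "single")
    rep0 <- slalomQC(fm$locus, flat)
    expect_false(rep0@applied)
    expect_true(is.na(rep0@robust))
    # planting a sign flip at r2 = 0.81 next to a strong lead gets flagged
    ss2 <- ss
    i_lead <- which.max(abs(ss$z))
    nb <- i_lead + if (i_lead < 10) 1L else -1L
    ss2$z[nb] <- -ss2$z[nb]; ss2$beta[nb] <- -ss2$beta[nb]
    fm2 <- fineMapLocus(v$snp[5], list(G = ss2), ld)
    tab <- fm2$slalom@table
    expect_true(tab$outlier[tab$snp == v$snp[nb]])
    expect_false(isRobust(fm2$slalom))
})

test_that("fine-mapping calibration covers the causal variant", {
    fm <- simulateFineMapCalibration(nLoci = 60, seed = 71)
    expect_gte(mean(fm$covered_multi), 0.95)
    expect_true(all(fm$size_multi >= 1))
})
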