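test_that("transfer credible sets enforce the three membership rules", {
    # panel: lead rs3 with neighbours at 10 kb spacing, rho = 0.95
    ld <- simulateLDMatrix(5, 0.95, spacingBp = 10000L)
    v <- ldVariants(ld)
    disc <- make_ss(v$snp, v$bp, beta = rep(0.1, 5), se = rep(0.01, 5),
                    p = c(5e-9, 4e-10, 1e-11, 9e-10, 5e-8))
    cat <- make_catalogue("rs3", v$bp[3], 0.1, p = 1e-11)
    cs <- buildTransferCredibleSet(cat, disc, ld)
    # rs1/rs5 are 20 kb away with r2 = 0.95^4 = 0.81... all within 50 kb;
    # membership depends on r2 >= 0.8 and p < 100 * p_lead = 1e-9
    expect_true("rs3" %in% cs@members$snp)
    expect_true("rs2" %in% cs@members$snp)   # r2 = 0.9 > 0.8, p 4e-10 < 1e-9
    expect_false("rs1" %in% cs@members$snp)  # p = 5e-9 >= 100 * p_lead
    expect_false("rs5" %in% cs@members$snp)

    # window rule: a correlated neighbour beyond 50 kb is excluded
    ld2 <- simulateLDMatrix(3, 0.95, spacingBp = 60000L)
    v2 <- ldVariants(ld2)
    disc2 <- make_ss(v2$snp, v2$bp, rep(0.1, 3), rep(0.01, 3),
                     p = c(1e-11, 1e-11, 1e-11))
    cs2 <- buildTransferCredibleSet(make_catalogue("rs1", v2$bp[1], 0.1,
                                                   p = 1e-11), disc2, ld2)
    expect_equal(cs2@members$snp, "rs1")

    # lead absent from the panel degrades to {lead} with a warning
    cat3 <- make_catalogue("zz", 123, 0.1)
    expect_warning(cs3 <- buildTransferCredibleSet(cat3, disc, ld), "absent")
    expect_equal(nrow(cs3@members), 1)
})

test_that("penalized threshold follows the printed formula", {
    expect_equal(transferThreshold(1, 0.008341), 0.05)
    expect_equal(transferThreshold(1, 0.9), 0.05)
    expect_equal(transferThreshold(11, 0.008341), 0.05 * 10^(-0.08341))
    expect_equal(transferThreshold(11, 0.008341), 0.04126, tolerance = 1e-4)
    # strictly decreasing in N for positive pf
    thr <- transferThreshold(1:50, 0.007378)
    expect_true(all(diff(thr) < 0))
})

test_that("penalization factor regression recovers the null-order slope", {
    # all equal responses: slope 0
    fit0 <- estimatePenalizationFactor(rep(0.01, 20), rep(1:4, 5))
    expect_equal(fit0$pf, 0, tolerance = 1e-12)
    expect_error(estimatePenalizationFactor(rep(0.5, 5), 1:5), "at least 10")

    # Monte-Carlo oracle: min of N independent uniforms per locus; the
    # regression of -log10(min p) on N has a positive slope matching an
    # independent large-sample regression of the analytic expectation
    set.seed(21)
    N <- sample(1:20, 4000, replace = TRUE)
    minp <- vapply(N, function(n) min(runif(n)), numeric(1))
    fit <- estimatePenalizationFactor(minp, N)
    # oracle: E[-log10 min p] = H_N / ln 10 (minimum of N uniforms)
    hN <- vapply(1:20, function(n) sum(1 / seq_len(n)), numeric(1)) / log(10)
    oracle <- lm(hN ~ seq(1, 20))
    se_slope <- summary(fit$fit)$coefficients[2, 2]
    expect_gt(fit$pf, 0)
    expect_lt(abs(fit$pf - coef(oracle)[2]), 2 * se_slope)

    # configured-constants mode: published per-group values used directly
    pf <- defaultPenalizationFactors()
    expect_equal(unname(pf["AFR"]), 0.008341)
    expect_equal(unname(pf["HIS"]), 0.003147)
})

test_that("transferable calls require both significance and sign", {
    ld <- simulateLDMatrix(1, 0)
    v <- ldVariants(ld)
    cat <- make_catalogue("rs1", v$bp[1], beta = 0.1, p = 1e-11)
    disc <- make_ss("rs1", v$bp[1], 0.1, 0.01, p = 1e-11)
    cs <- buildTransferCredibleSet(cat, disc, ld)
    tgt <- make_ss("rs1", v$bp[1], 0.05, 0.02, p = 0.03)
    expect_true(callTransferable(cs, tgt, pf = 0.008))
    tgt$beta <- -0.05                       # opposite sign
    expect_false(callTransferable(cs, tgt, pf = 0.008))
    tgt$beta <- 0.05; tgt$p <- 0.2          # not significant
    expect_false(callTransferable(cs, tgt, pf = 0.008))
    # absent from target data: unassessable
    tgt2 <- make_ss("other", 999, 0.1, 0.1)
    expect_message(flag <- callTransferable(cs, tgt2, pf = 0.008), "no credible")
    expect_true(is.na(flag))
})

test_that("locus power matches the individual-level logistic oracle", {
    # size: beta = 0 gives power alpha
    expect_equal(locusPower(0, 0.3, 5000, 5000), 0.05)
    # worked case: beta 0.15, f 0.3, 5,000/5,000
    p_analytic <- locusPower(0.15, 0.3, 5000, 5000)
    expect_equal(p_analytic, 0.998, tolerance = 2e-3)
    set.seed(31)
    p_mc <- mc_logistic_power(0.15, 0.3, 5000, 5000, nRep = 3000)
    expect_lt(abs(p_analytic - p_mc), 0.006)
    # a weaker effect, away from the power ceiling
    p2 <- locusPower(0.05, 0.3, 5000, 5000)
    set.seed(32)
    p2_mc <- mc_logistic_power(0.05, 0.3, 5000, 5000, nRep = 3000)
    expect_lt(abs(p2 - p2_mc), 4 * sqrt(p2_mc * (1 - p2_mc) / 3000) + 0.01)
    # monotonicity in |beta|, N, f(1-f)
    expect_true(all(diff(locusPower(seq(0, 0.3, 0.05), 0.3, 5000, 5000)) > 0))
    expect_lt(locusPower(0.1, 0.3, 1000, 1000), locusPower(0.1, 0.3, 5000, 5000))
    expect_lt(locusPower(0.1, 0.05, 5000, 5000), locusPower(0.1, 0.5, 5000, 5000))
    expect_warning(p0 <- locusPower(0.1, 0, 1000, 1000), "degenerate")
    expect_equal(p0, 0)
})

test_that("PAT ratio arithmetic, bootstrap and degeneracies behave", {
    # all transferable at power 1: ratio 1, degenerate CI
    res <- patRatio(rep(TRUE, 10), rep(1, 10), seed = 1)
    expect_equal(patRatioValue(res), 1)
    expect_equal(c(res@ciLow, res@ciHigh), c(1, 1))
    # plain arithmetic: 10 observed / 40 expected
    res2 <- patRatio(c(rep(TRUE, 10), rep(FALSE, 30)), rep(1, 40), seed = 2)
    expect_equal(patObserved(res2), 10)
    expect_equal(patExpected(res2), 40)
    expect_equal(patRatioValue(res2), 0.25)
    # CI contains the point estimate; ordering invariance
    expect_lte(res2@ciLow, 0.25); expect_gte(res2@ciHigh, 0.25)
    perm <- sample(40)
    res3 <- patRatio(c(rep(TRUE, 10), rep(FALSE, 30))[perm], rep(1, 40)[perm],
                     seed = 2)
    expect_equal(patRatioValue(res3), 0.25)
    # NA flags are excluded from both sums
    res4 <- patRatio(c(TRUE, NA, FALSE), c(0.9, 0.9, 0.9), seed = 3)
    expect_equal(patObserved(res4), 1)
    expect_equal(patExpected(res4), 1.8)
    expect_error(patRatio(logical(0), numeric(0)), "undefined")
})

test_that("nontransferable calls require power, silence and a quiet window", {
    ld <- simulateLDMatrix(2, 0.9, spacingBp = 10000L)
    v <- ldVariants(ld)
    cat <- make_catalogue("rs1", v$bp[1], 0.2, p = 1e-12)
    disc <- make_ss(v$snp, v$bp, c(0.2, 0.19), c(0.01, 0.01),
                    p = c(1e-12, 1e-11))
    cs <- buildTransferCredibleSet(cat, disc, ld)
    tgt <- make_ss(v$snp, v$bp, c(0.01, 0.01), c(0.05, 0.05),
                   p = c(0.2, 0.5))
    # powered and silent, quiet window -> nontransferable
    expect_true(callNontransferable(cs, tgt, powers = 0.9))
    # a sub-threshold neighbour within 50 kb vetoes the call
    tgt2 <- rbind(tgt, make_ss("near", v$bp[1] + 20000, 0.3, 0.05, p = 1e-4))
    expect_false(callNontransferable(cs, tgt2, powers = 0.9))
    # low power vetoes regardless of p
    expect_false(callNontransferable(cs, tgt, powers = 0.5))
    # a nominally significant member vetoes
    tgt3 <- tgt; tgt3$p[1] <- 0.01
    expect_false(callNontransferable(cs, tgt3, powers = 0.9))
})

test_that("transferable and nontransferable calls are mutually exclusive", {
    set.seed(41)
    for (i in 1:10) {
        res <- simulateTransferabilityStudy(runif(1), nLoci = 15,
                                            nBoot = 50)
        per <- res@perLocus
        expect_false(any(per$transferable & per$nontransferable,
                         na.rm = TRUE))
    }
})
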