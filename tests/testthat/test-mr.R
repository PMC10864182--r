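test_that("instrument selection applies thresholds with the 10-IV fallback", {
    bp <- seq_len(20) * 2e7      # far apart: clumping never interferes
    p <- c(rep(1e-9, 12), rep(1e-7, 8))
    exp12 <- make_ss(paste0("iv", 1:20), bp, rep(0.2, 20), rep(0.02, 20),
                     p = p)
    sel <- selectInstruments(exp12)
    expect_equal(nrow(sel), 12)
    expect_equal(attr(sel, "threshold"), 5e-8)
    # only 5 at genome-wide: fall back to suggestive and take all 20
    p2 <- c(rep(1e-9, 5), rep(1e-7, 15))
    exp5 <- make_ss(paste0("iv", 1:20), bp, rep(0.2, 20), rep(0.02, 20),
                    p = p2)
    sel2 <- selectInstruments(exp5)
    expect_equal(nrow(sel2), 20)
    expect_equal(attr(sel2, "threshold"), 5e-6)
    # nothing anywhere: hard error
    expN <- make_ss(paste0("iv", 1:5), bp[1:5], rep(0.01, 5), rep(0.02, 5),
                    p = rep(0.5, 5))
    expect_error(selectInstruments(expN), "fewer than 3")
})

test_that("greedy clumping honours the r2 and window rules", {
    ld <- simulateLDMatrix(2, 0.1, spacingBp = 1000000L)   # r2 = 0.01
    v <- ldVariants(ld)
    x <- make_ss(v$snp, v$bp, c(0.3, 0.2), c(0.02, 0.02),
                 p = c(1e-10, 1e-8))
    # r2 = 0.01 > 0.001 within the window: only the better p survives
    expect_equal(clumpVariants(x, ld)$snp, "rs1")
    # r2 below threshold: both kept
    ld2 <- simulateLDMatrix(2, 0.02, spacingBp = 1000000L) # r2 = 4e-4
    expect_equal(nrow(clumpVariants(x, ld2)), 2)
    # beyond the 10,000 kb window any r2 is irrelevant
    x2 <- x; x2$bp[2] <- x2$bp[1] + 1.5e7
    ld3 <- ld; ld3@variants$bp[2] <- x2$bp[2]
    expect_equal(nrow(clumpVariants(x2, ld3)), 2)
})

test_that("pair harmonization aligns outcome records to exposure alleles", {
    ex <- make_ss("rs1", 100, 0.2, 0.02); ex$eaf <- 0.3
    out <- make_ss("rs1", 100, 0.1, 0.05); out$eaf <- 0.7
    out$a1 <- "G"; out$a2 <- "A"          # swapped labels
    ins <- harmonizePair(ex, out)
    expect_equal(ins$beta_outcome, -0.1)
    expect_equal(ins$beta_exposure, 0.2)
    # aligned pair is unchanged
    out2 <- make_ss("rs1", 100, 0.1, 0.05); out2$eaf <- 0.3
    expect_equal(harmonizePair(ex, out2)$beta_outcome, 0.1)
    # palindromic with near-0.5 frequency is dropped
    ex3 <- make_ss("rs1", 100, 0.2, 0.02, a1 = "A", a2 = "T"); ex3$eaf <- 0.49
    out3 <- make_ss("rs1", 100, 0.1, 0.05, a1 = "A", a2 = "T"); out3$eaf <- 0.5
    expect_null(harmonizePair(ex3, out3))
})

test_that("estimators agree on consensus data and hand examples", {
    # hand IVW: betaX (0.1, 0.2), betaY (0.05, 0.10), se_out 0.01
    ins <- data.frame(snp = c("a", "b"), beta_exposure = c(0.1, 0.2),
                      se_exposure = c(0.01, 0.01),
                      beta_outcome = c(0.05, 0.10),
                      se_outcome = c(0.01, 0.01), p_exposure = 1e-10,
                      eaf = 0.3)
    expect_equal(mrIVW(ins)$beta, 0.5)
    # all ratio estimates equal: every estimator returns the consensus
    cons <- data.frame(snp = letters[1:5],
                       beta_exposure = c(0.1, 0.2, 0.3, 0.25, 0.15),
                       se_exposure = 0.01,
                       beta_outcome = 0.4 * c(0.1, 0.2, 0.3, 0.25, 0.15),
                       se_outcome = 0.01, p_exposure = 1e-10, eaf = 0.3)
    expect_equal(mrIVW(cons)$beta, 0.4)
    expect_equal(suppressWarnings(mrEgger(cons))$beta, 0.4)
    expect_equal(mrWeightedMedian(cons, nBoot = 10, seed = 1)$beta, 0.4)
    expect_equal(mrSimpleMode(cons, nBoot = 10, seed = 1)$beta, 0.4,
                 tolerance = 1e-6)
    expect_equal(mrWeightedMode(cons, nBoot = 10, seed = 1)$beta, 0.4,
                 tolerance = 1e-6)
    expect_equal(mrIVW(cons)$q, 0, tolerance = 1e-20)
})

test_that("IVW equals WLS through the origin and Egger nests it", {
    set.seed(91)
    mr <- generateMRPair(30, 0.25)
    ins <- harmonizeInstruments(mr$exposure, mr$outcome)
    fit <- mrIVW(ins)
    wls <- lm(beta_outcome ~ beta_exposure + 0, data = ins,
              weights = 1 / se_outcome^2)
    expect_equal(fit$beta, unname(coef(wls)), tolerance = 1e-12)
    # Egger with the intercept constrained to zero is exactly IVW
    expect_equal(fit$beta, unname(coef(wls)["beta_exposure"]),
                 tolerance = 1e-12)
    # invariances: instrument order and joint sign flips
    perm <- sample(nrow(ins))
    expect_equal(mrIVW(ins[perm, ])$beta, fit$beta)
    flip <- ins; flip$beta_exposure <- -flip$beta_exposure
    flip$beta_outcome <- -flip$beta_outcome
    expect_equal(mrIVW(flip)$beta, fit$beta)
})

test_that("heterogeneity Q decomposes and calibrates", {
    # perfectly proportional instruments: Q = 0
    cons <- data.frame(snp = letters[1:4], beta_exposure = c(0.1, 0.2, 0.3, 0.4),
                       se_exposure = 0.01, beta_outcome = 0.3 * c(0.1, 0.2, 0.3, 0.4),
                       se_outcome = 0.02, p_exposure = 1e-10, eaf = 0.3)
    het0 <- heterogeneityQ(cons)
    expect_equal(het0$q, 0, tolerance = 1e-20)
    # a gross outlier dominates the decomposition
    out1 <- cons
    out1$beta_outcome[2] <- out1$beta_outcome[2] + 0.5
    het1 <- heterogeneityQ(out1)
    expect_equal(names(which.max(het1$contributions)), "b")
    expect_gt(het1$contributions["b"] / het1$q, 0.75)
    # homogeneous simulated data: Q p-values uniform across seeds
    set.seed(92)
    ps <- replicate(200, {
        mr <- generateMRPair(20, 0.3)
        heterogeneityQ(harmonizeInstruments(mr$exposure, mr$outcome))$p
    })
    ks <- suppressWarnings(stats::ks.test(ps, "punif"))
    expect_gt(ks$p.value, 0.01)
})

test_that("outlier removal strips planted outliers and stops cleanly", {
    # homogeneous data: nothing removed
    set.seed(93)
    mr0 <- generateMRPair(20, 0.3)
    ins0 <- harmonizeInstruments(mr0$exposure, mr0$outcome)
    res0 <- removeOutliers(ins0)
    expect_equal(nrow(res0$removed), 0)
    expect_equal(nrow(res0$instruments), 20)
    expect_error(removeOutliers(ins0[1:3, ]), "at least 4")
    # a planted 10-se outlier is removed, and the estimate is closer to the
    # simulated effect in mean absolute error after removal
    hits <- 0L; e_before <- e_after <- numeric(40)
    for (s in 1:40) {
        mr <- generateMRPair(25, 0.3, pleiotropy = "outliers",
                             nOutliers = 1, seed = 1000 + s)
        ins <- harmonizeInstruments(mr$exposure, mr$outcome)
        res <- removeOutliers(ins)
        hits <- hits + (mr$outliers %in% res$removed$snp)
        e_before[s] <- abs(mrIVW(ins)$beta - 0.3)
        e_after[s] <- abs(mrIVW(res$instruments)$beta - 0.3)
    }
    expect_gte(hits / 40, 0.95)
    expect_lt(mean(e_after), mean(e_before))
})

test_that("bi-directional runs keep instrument sets disjoint", {
    set.seed(94)
    fwd <- generateMRPair(15, 0.3, seed = 1)
    rev <- generateMRPair(12, 0.0, seed = 2)
    rev$exposure$snp <- paste0("rev_", rev$exposure$snp)
    rev$outcome$snp <- paste0("rev_", rev$outcome$snp)
    ins_f <- harmonizeInstruments(fwd$exposure, fwd$outcome)
    ins_r <- harmonizeInstruments(rev$exposure, rev$outcome)
    expect_length(intersect(ins_f$snp, ins_r$snp), 0)
    res_f <- mrAll(ins_f, nBoot = 50, seed = 3)
    res_r <- mrAll(ins_r, nBoot = 50, seed = 3)
    expect_equal(nrow(res_f), 5)
    expect_setequal(res_f$method, c("IVW", "Egger", "weighted_median",
                                    "simple_mode", "weighted_mode"))
    # the null direction is not significant for IVW
    expect_gt(res_r$p[res_r$method == "IVW"], 0.001)
})
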