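# Fixture builders shared across the suite. Everything is generated in code;
# no files are stored.

make_ss <- function(snp, bp, beta, se, p = NULL, chr = "1",
                    a1 = "A", a2 = "G", eaf = 0.3, info = 1,
                    n_cas = 1000, n_con = 1000, n_studies = 2L) {
    n <- length(snp)
    if (is.null(p)) p <- 2 * pnorm(-abs(beta / se))
    data.frame(snp = snp, chr = rep_len(chr, n), bp = bp,
               a1 = rep_len(a1, n), a2 = rep_len(a2, n),
               eaf = rep_len(eaf, n), beta = beta, se = se, p = p,
               n_cas = rep_len(n_cas, n), n_con = rep_len(n_con, n),
               info = rep_len(info, n), n_studies = rep_len(n_studies, n),
               direction = NA_character_, stringsAsFactors = FALSE)
}

make_catalogue <- function(snp, bp, beta, eaf = 0.3, p = 1e-10, chr = "1") {
    n <- length(snp)
    data.frame(snp = snp, chr = rep_len(chr, n), bp = bp, a1 = "A",
               a2 = "G", beta_discovery = beta,
               eaf_discovery = rep_len(eaf, n),
               p_discovery = rep_len(p, n), source = "test",
               stringsAsFactors = FALSE)
}

# Individual-level logistic score-test power, the independent Monte-Carlo
# oracle for locusPower(): per replicate, genotypes ~ Binomial(2, f),
# disease risk follows the additive logistic model, and the 1-df score
# statistic is formed exactly.
mc_logistic_power <- function(beta, f, nCases, nControls, nRep = 3000,
                              chunk = 250) {
    n <- nCases + nControls
    phi <- nCases / n
    a <- qlogis(phi) - beta * 2 * f     # centre marginal prevalence at phi
    crit <- qchisq(0.95, 1)
    hits <- 0L
    done <- 0L
    while (done < nRep) {
        m <- min(chunk, nRep - done)
        g <- matrix(rbinom(m * n, 2L, f), nrow = m)
        y <- matrix(rbinom(m * n, 1L, plogis(a + beta * g)), nrow = m)
        ybar <- rowMeans(y)
        u <- rowSums(g * (y - ybar))
        v <- ybar * (1 - ybar) * rowSums((g - rowMeans(g))^2)
        hits <- hits + sum(u^2 / v > crit)
        done <- done + m
    }
    hits / nRep
}
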