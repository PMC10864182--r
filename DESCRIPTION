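Package: crossancestry
Title: Multi-Ancestry GWAS Meta-Analysis, Locus Transferability, Fine
    Mapping and Mendelian Randomization
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Statistical machinery for multi-ancestry genome-wide
    association studies of complex disease from summary statistics:
    harmonization, quality-control filters and effect-scale conversions
    for case-control summary statistics; inverse-variance-weighted
    fixed-effects meta-analysis with genomic-inflation diagnostics,
    LDSC-intercept correction of test statistics, locus definition and
    novelty classification; power-adjusted transferability (PAT) of
    discovery loci across ancestry groups with penalized significance
    thresholds; multi-ancestry Bayesian fine mapping with
    heterogeneity-informed priors, 99 percent credible sets and
    DENTIST-S/SLALOM summary-statistic quality control; and
    ancestry-stratified bi-directional two-sample Mendelian
    randomization with five estimators, heterogeneity tests and
    iterative outlier removal. A synthetic multi-ancestry
    summary-statistics generator with block linkage disequilibrium,
    Balding-Nichols allele-frequency divergence and controlled causal
    architectures supports calibration studies at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports: methods, stats, utils
Suggests: testthat (>= 3.0.0), metafor, jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
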