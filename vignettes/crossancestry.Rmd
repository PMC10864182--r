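---
title: "Multi-ancestry GWAS methods: meta-analysis, transferability, fine mapping and MR"
author: "crossancestry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-ancestry GWAS methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crossancestry)
```

# Scope and data model

`crossancestry` operates entirely on GWAS *summary statistics*: per-variant
log-odds effects, standard errors, p-values, effect-allele frequencies and
sample sizes, together with ancestry-matched LD reference matrices of signed
correlations r. A summary-statistics table is a plain `data.frame` with
columns `snp chr bp a1 a2 eaf beta se p n_cas n_con info n_studies
direction` (`a1` is the effect allele); on disk the canonical dialect is
tab-separated with upper-case headers and `"."` for missing values, and
alternative dialects are declared explicitly to `readSumstats()` rather than
sniffed. Coordinates are 1-based, windows inclusive on both ends, and all
"kb from lead" distances are `|pos − pos_lead|`. Extremely small p-values
are handled in log space (`log10P()` works from the normal log-tail), so
z-statistics beyond the double floor of p remain usable.

The central containers are S4 classes with validity checks: `LDMatrix`
(symmetric, unit diagonal, |r| ≤ 1, positive semi-definite within 1e−8),
`TransferSet`, `PATResult`, `FineMapLocus`, `PosteriorSet` and
`SlalomReport`.

# Harmonization and QC

Indels are recoded to `I`/`D` by allele length; positions carrying two or
more distinct indel patterns lose all their indel records, and equal-length
multi-base pairs are dropped as unorientable. Allele alignment recognises
label swaps (effect flips sign, frequency complements) and strand flips
(base complementation). For palindromic pairs (A/T, C/G) the labels carry
no orientation information at all, so the effect alleles are matched by
frequency — only when both frequencies fall clearly on the same side of 0.5
(both < 0.42 or both > 0.58); every other palindromic configuration is
excluded. The 0.42/0.58 band balances retention against the risk of silent
sign errors near 0.5.

The post-imputation filter keeps variants with info score ≥ 0.7 and
effective allele count `2·MAF·(1−MAF)·N·R² ≥ 50`. The small-study MAF ≥
0.05 rule engages when the effective half sample size
`2/(1/n_cases + 1/n_controls)` falls below 2,000 — the cutoff is a design
choice (the rule itself names no threshold) and is exposed as an argument.

# Fixed-effects meta-analysis and inflation

`ivwMeta()` pools per-study effects with weights `1/se²` and reports
Cochran's Q, `I² = max(0, (Q−(k−1))/Q)` and a METAL-style direction string.
λ is computed by the median method (median χ² over 0.4549364), which is
robust and conventional; `λ₁,₀₀₀` uses crude case/control counts, which
reproduces the printed worked value 1.001 from λ = 1.687 with
345,389/1,469,702. LDSC-intercept correction divides the χ² statistics by a
*supplied* intercept (equivalently scales se by √intercept) — intercept
estimation is out of scope by design. Locus aggregation merges leads
< 500 kb apart transitively (pairwise-only merging would leave
order-dependent results), takes the minimum-p member as the locus lead and
spans lead ± 250 kb. Conditional selection of independent signals is not
re-implemented: leads are taken as given, from simulation ground truth or
greedy distance clumping.

# Power-adjusted transferability

A discovery locus travels as a credible set: the lead plus every variant
with r² ≥ 0.8 within 50 kb whose discovery p is below 100·P_lead (the
p-filter is read against *discovery* p-values, since the sets are formed
before any target-group lookup). The target-group threshold is penalized
for the set size, `P < 10^(log₁₀0.05 − P_f·(N−1))`, and a locus is
transferable when some member passes it with a direction matching
discovery. The penalization factor is fitted by OLS of `−log10(min member
p)` on N across null-trait loci: only the log scale is dimensionally
consistent with the exponent `P_f·(N−1)` of the threshold, which is why the
regression is run on −log10(p) rather than raw p. Configured constants for
the four target groups (0.008341, 0.007378, 0.006847, 0.003147 for AFR,
EAS, SAS, HIS) are available via `defaultPenalizationFactors()`.

Per-locus power uses the additive 1-df test at α = 0.05 (not the penalized
threshold; a `alpha` argument exposes the alternative) with the asymptotic
logistic-score variance `2f(1−f)·(n_cases+n_controls)·φ(1−φ)` — verified in
the test suite against an individual-level logistic score-test Monte-Carlo
oracle. The PAT ratio divides observed transferable loci by the summed
powers; its 95% CI is a 1,000-replicate percentile bootstrap over loci,
resampling each locus's (call, power) pair jointly. Loci with no credible
set member in the target data are excluded from both sums.

# Multi-ancestry fine mapping

Each locus comprises all variants with r² > 0.1 to the lead in the
multi-ancestry LD reference. Per member, the five ancestry-group estimates
are pooled by fixed-effects IVW; I² across groups feeds the causal prior
`max(ε, 1−I²)` with floor ε = 0.01, normalized — the prior's monotone
direction (heterogeneous variants are less likely causal) is the method's
substance, the functional form is a documented stand-in and is
config-exposed. Posterior inclusion probabilities are proportional to the
pooled χ² times the prior (the literal proportionality reading); an
approximate-Bayes-factor weighting would be a natural sensitivity variant
but the χ²-linear form is the default and the one calibrated here. The 99%
credible set accumulates descending PIPs (ties broken by position) until
0.99. With a single ancestry group all I² are zero and the multi mode
reduces exactly to the single-ancestry comparator.

Because the χ²-linear posterior is invariant under proportional rescaling
of all χ², adding a second group with *identical* LD sharpens credible sets
only marginally. The real-data reduction in set sizes comes from LD
*diversity* — proxies that tag the causal variant in one ancestry fail to
tag it in another, so the causal variant's pooled χ² share rises. The
calibration study therefore pairs a high-LD group (AR-1 ρ = 0.9) with a
low-LD group (ρ = 0.5) and uses the averaged panel as the multi-ancestry
reference; under those conditions the median 99% set shrinks from 20
(single-ancestry) to 8 (multi-ancestry) while retaining ≥ 95% coverage of
the causal variant — the directional analogue of the reduction reported in
the motivating study.

SLALOM-style QC applies when the largest PIP exceeds 0.1: every variant
within 1 Mb of the lead (the minimum-p variant, which cannot be tested
against itself) is scored with DENTIST-S, `T = (z − r·z_lead)²/(1−r²)`
using *signed* r from the multi-ancestry panel; outliers need p < 1e−4 and
r² > 0.6, and a locus is robust when none exist. T is χ²₁ under a
consistent model; selection of the lead by minimum p inflates it only
mildly, which the null calibration budget (outlier rate ≤ 5e−4 against the
nominal 1e−4) absorbs.

# Two-sample Mendelian randomization

Instruments are genome-wide significant exposure variants, clumped at
r² > 0.001 within 10,000 kb; if fewer than 10 survive, selection falls back
to 5×10⁻⁶. Five estimators are provided: IVW (weighted regression through
the origin, weights `1/se_out²`, fixed-effect standard error), MR-Egger
(free intercept, after orienting exposure effects positive), the weighted
median of ratio estimates (standard error by 1,000-replicate parametric
bootstrap), and simple/weighted modes (kernel-smoothed ratio density,
bandwidth multiplier 1 by default, bootstrap standard errors). Egger with
its intercept constrained to zero is exactly IVW, which the tests assert.

The outlier step is a deterministic simplification of the residual-sum
global-test approach: while Cochran's Q over instruments rejects at 0.05
and more than three instruments remain, the instrument with the largest Q
contribution is removed, and every removal is recorded in an audit trail.
This keeps the desk-scale pipeline reproducible while exposing exactly what
was discarded. Sample-overlap exclusion between exposure and outcome data
is the caller's responsibility.

# The synthetic generator and what it does (not) show

`simulateZscores()` draws `z ~ MVN(Rλ, R)` per LD block with
`λ_j = β_j·√(2f_j(1−f_j)·n_eff_half)` and `se_j` the matching inverse — the
standard summary-statistic (RSS) model, consistent with the additive
logistic model downstream modules assume. Allele-frequency divergence
between groups follows a Balding–Nichols construction (group frequency ~
Beta around a shared ancestral frequency, drift F = 0.05–0.15, clamped to
[0.01, 0.99]). LD is AR-1 within blocks (`r = ρ^|i−j|`), positive
semi-definite by construction.

One deliberate asymmetry deserves note: the generator's standard-error
convention, `se = 1/√(2f(1−f)·n_eff_half)`, is optimistic by a factor of
√2 relative to the exact logistic-score variance used by `locusPower()`
(for any case/control split, `(n_cases+n_controls)·φ(1−φ)` equals half the
effective half sample size). Both conventions appear in the field; the
package keeps each where its module specifies it. The transferability
recovery study is therefore run in a regime where per-locus power is
essentially 1 (β = 0.12, ancestral frequencies in [0.2, 0.8], target
effective half size 20,000), so the convention gap cannot distort the PAT
ratio; with weak effects the power model is conservative and PAT ratios
would drift above the true sharing fraction.

Study conditions of the calibration designs (fixed once, shared by the
test suite and the acceptance script):

* **Transferability** — 40 loci of 5 variants (ρ = 0.6, so no proxy
  reaches the r² ≥ 0.8 membership bound and credible sets are the lead
  alone), discovery effective half size 50,000, target 20,000, F = 0.05,
  ≥ 200 seeds per sharing fraction τ ∈ {0, 0.3, 1}. Recovered mean PAT
  ratios sit within 0.02–0.05 of τ; under τ = 0 the observed rate matches
  the 0.025 false-call rate implied by the α = 0.05 threshold plus the
  sign-consistency clause.
* **Fine mapping** — 500 loci of 30 variants, groups at ρ = 0.9 and 0.5,
  shared β = 0.07, effective half size 20,000 per group.
* **DENTIST-S** — 300 null loci of 10 variants at ρ = 0.9 (β = 0.09, lead
  z ≈ 8); the planted-outlier arm flips the sign of the variant adjacent
  to the causal one (r² = 0.81 to it).
* **MR** — 50 instruments with exposure effects uniform on [0.1, 0.5],
  se_x = 0.02, se_y = 0.05, θ = 0.3; directional pleiotropy α = 0.05;
  outlier arm: one instrument shifted by 10 outcome standard errors.

What the generator does *not* emulate: individual-level genotypes and
covariate structure, realistic LD beyond block-AR-1 (no long-range or
inter-block LD), demographic history, X-chromosome dosage, selection-induced
winner's curse at realistic magnitudes (discovery effects are strong enough
that selection bias is negligible), or linkage between MR instruments.
Passing calibration here demonstrates internal consistency of the
implemented arithmetic and decision rules under the stated model — not
robustness to LD mismatch, phenotype heterogeneity or cryptic sample
overlap in real cohorts.

# Numerical choices and degenerate inputs

* PIP/prior normalization is exact to 1e−9 and enforced by class validity;
  an all-zero χ² locus yields uniform PIPs with a warning.
* A tiny ridge (1e−10) stabilises the block Cholesky at |ρ| near 1.
* `ivwMeta()` excludes non-positive standard errors with a warning and
  errors only when no usable study remains; single-group members take
  I² = 0 by convention.
* DENTIST-S skips variants in perfect LD with the lead (|r| = 1), where
  the statistic is undefined.
* `patRatio()` refuses an all-zero expected count (undefined ratio);
  unassessable loci (no member in the target panel) are excluded from both
  the observed and expected sums.
* Degenerate allele frequencies yield power 0 with a warning.
* The penalization-factor regression requires ≥ 10 null loci.

# Known limitations

The heterogeneity prior's exact published form is not restated in the
motivating methods text; the normalized `max(ε, 1−I²)` form implements its
monotone intent and is exchangeable via the `prior` argument. The
`n_eff_half` accounting of pooled cohorts reproduces the printed total only
to within rounding (559,331.6 vs 559,332, consistent with per-study
summation in the original accounting). Manual locus-zoom curation of
secondary signals is inherently non-algorithmic and is not emulated; loci
with multiple independent signals are simply excluded from fine mapping, as
in the motivating design.
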