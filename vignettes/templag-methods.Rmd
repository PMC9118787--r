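---
title: "Methods: temporal adiposity-microbiome analysis with templag"
author: "templag developers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: temporal adiposity-microbiome analysis with templag}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(templag)
```

# Overview

`templag` implements a longitudinal analysis chain for paired-visit cohorts
with shotgun-metagenomic species profiles and anthropometric/metabolic
phenotypes. The scientific question it serves is directional: does adiposity
precede changes in particular gut microbes, do those microbes precede changes
in adiposity, and do microbes carry part of the effect of adiposity on
insulin resistance? The chain is: quality control of relative-abundance
tables, confounder residualization, a two-wave cross-lagged panel model per
microbial feature, weight-change-pattern and repeated-measures association
models, causal mediation, and random-effects meta-analytic replication. A
synthetic cohort generator with known truth underpins all validation.

# The cross-lagged panel model

For one feature F and the adiposity measure (BMI or WC), both standardized
at baseline (subscript 1) and follow-up (subscript 2), the model is

$$BMI_2 = r_1\,BMI_1 + \rho_1\,F_1 + e_1,\qquad
  F_2 = \rho_2\,BMI_1 + r_2\,F_1 + e_2,$$

with the baseline synchronous correlation $r_3 = \mathrm{corr}(BMI_1, F_1)$.
$\rho_1$ asks whether the microbe precedes adiposity change; $\rho_2$ asks
the reverse, each net of the autoregressive "tracking" paths $r_1, r_2$.

**Preprocessing contract.** Baseline and follow-up values of the adiposity
measure are residualized (separate OLS regressions) on the eight baseline
confounders (age, sex, smoking, alcohol, education, income, physical
activity, total energy intake); feature log abundances additionally on the
Bristol stool score. Residuals are Z-scored (sample SD). The 4x4 correlation
matrix is then computed with the follow-up time interval partialled out of
every pair. We implement the partialling by residualizing the four Z-scored
columns on the interval and correlating the residuals; this is numerically
identical to first-order pairwise partial correlations on a shared third
variable and guarantees a positive-semidefinite matrix by construction
(`build_panel()` enforces the PSD check). An alternative reading — interval
as an extra covariate in the residualization regressions — is available via
`interval_mode = "covariate"`.

**Estimation.** Because both equations share the same two standardized
regressors, the maximum-likelihood path estimates have a closed form, e.g.
$\hat\rho_1 = (r_{F_1 BMI_2} - r_3 r_{BMI_1 BMI_2})/(1 - r_3^2)$, and equal
equation-by-equation OLS on any standardized dataset generating the same
correlation matrix (the likelihood factorizes into the exogenous block and
two conditional regressions with uncorrelated errors). Standard errors are
normal-theory OLS standard errors at the analysis n with a t reference on
n - 3 degrees of freedom; at n in the hundreds the difference from a z
reference or from information-matrix SEs is negligible, and the test suite
bounds the OLS agreement at 1e-8 and the agreement of the discrepancy
statistic with a numeric ML optimizer at 1e-6.

**Fit indices.** The default specification fixes the follow-up disturbance
covariance at zero, leaving one over-identifying degree of freedom so SRMR
and CFI are informative: the model-implied matrix equals the sample matrix
except the (BMI2, F2) entry, the ML discrepancy is
$T = (n-1)[\ln|\hat\Sigma| - \ln|S| + \mathrm{tr}(S\hat\Sigma^{-1}) - 4]$,
SRMR is the root mean square of the ten lower-triangle residuals, and CFI
uses the independence model (all off-diagonals zero, df = 6) as baseline.
Whether the original applications of this model freed that covariance is
not determinable from typical reports; `saturated = TRUE` frees it (paths
unchanged, T = SRMR = 0, CFI = 1).

**Screening.** `screen_features()` applies Benjamini-Hochberg step-up FDR
separately to the $\rho_1$ and $\rho_2$ families across features, at 0.25
by default — a deliberately liberal screen for the per-species pass, with
0.05 used everywhere downstream. BH ties share the q-value of their group.

# Downstream association models

* **Weight-change patterns** (`fit_pattern_model()`): WGOC BMI cut-offs
  (underweight < 18.5, normal [18.5, 24), overweight [24, 28), obesity >=
  28; the upper boundaries are half-open so the line is partitioned —
  the conventional statement "18.5-23.9 / 24-27.9" leaves (23.9, 24)
  undefined). Participants underweight at either visit are excluded;
  the remaining 2x2 cross of adiposity flags defines stable normal
  (reference), normal-to-adiposity, adiposity-to-normal, and stable
  adiposity. OLS of the Z-scored follow-up feature on pattern dummies,
  covariates, Bristol score, interval, and the baseline feature.
* **Microbe-phenotype models** (`fit_mixed_assoc()`): both visits stacked
  (two rows per participant), random intercept per participant, REML via
  `lme4`. HOMA-IR (= insulin x glucose / 22.5, the classic homeostasis
  model constant), fasting insulin, and fasting glucose are log-transformed
  (right-skewed); HbA1c is not. Phenotype and microbe are Z-scored, so
  coefficients are SD-per-SD. Inference is Wald-normal; with ~850
  observations the small-sample df correction is immaterial. Visit is not
  a fixed effect by default (`include_time` adds it).
* **Exposure models** (`fit_exposure_model()`): baseline weight group or a
  median-split dietary factor against follow-up phenotypes, adjusted for
  covariates, interval, and the baseline phenotype. Values equal to the
  median go to the "lower" group (documented, configurable by splitting on
  the user's own factor).
* **Collinearity** (`compute_vif()`): VIF = 1/(1 - R^2) per covariate;
  perfect collinearity reports `Inf` rather than failing.

# Mediation

`fit_mediation()` treats baseline overweight/obesity (BMI >= 24) as a binary
exposure, the follow-up log abundance as mediator, and a follow-up phenotype
as outcome, with baseline mediator adjusted in the mediator model and
baseline outcome in the outcome model, plus the confounders, Bristol score,
and interval in both. Point estimates are the product-of-coefficients
decomposition (ACME = alpha x b, ADE = c', total = sum; exact identity
checked to 1e-10 against independent OLS fits). Uncertainty is
quasi-Bayesian Monte Carlo — joint draws of each model's coefficients from
their estimated sampling normal — with percentile CIs and sign-based
two-sided p-values; an explicit seed is required and reruns are
bit-identical. The proportion mediated is reported on the signed scale
ACME/Total, both at the point estimates and as the median of draw-wise
ratios; the ratio CI is suppressed (flagged) when fewer than 95% of total
draws share one sign, where the ratio distribution is unstable. No
exposure-mediator interaction is included by default; `interaction = TRUE`
reports ACME under both exposure arms.

# Meta-analytic replication

`random_effects_meta()` uses the closed-form DerSimonian-Laird between-study
variance with inverse-variance weights — chosen over REML for determinism
and closed-form testability; both give identical decisions in the
concordant two-study cases that dominate here. With k = 2 the heterogeneity
test is chi-square on 1 df, without a Knapp-Hartung adjustment. A discovery
association is declared replicated only when p_meta < 0.05,
p_heterogeneity > 0.05, I^2 < 50%, and the directions agree — the direction
clause vetoes regardless of pooled significance. The replication cohort
design (`replication_regression()`) has the exposure at baseline only, so
the model is a prospective OLS of the follow-up feature on baseline BMI
with the reduced covariate set (age, sex, race, interval, baseline
feature).

# Abundance handling

Merged profiler tables are parsed with rank filtering (e.g. `"s__"` keeps
species rows and drops strain-resolved rows). Percent vs fraction mode is
auto-detected from per-sample sums and stored, so thresholds are always
interpreted on a declared scale. The species quality-control rule keeps
features with relative abundance >= 0.01% in at least 10% of samples; we
apply it jointly over both visits' samples (all 2n columns) by default,
since a per-visit filter could leave the two visits with different feature
sets. Zeros are replaced by 1e-5 (species) or 1e-9 (pathways) on the
fraction scale before natural log; the constants only make sense on one
scale, and fractions are the documented choice.

Alpha diversity (observed species, Shannon in nats so Pielou = H/ln S lands
exactly in [0, 1], Simpson as 1 - sum p^2) is computed on per-sample
renormalized relative abundances, by default pre-filter (configurable:
compute on the filtered table if preferred — reports rarely state which was
used). Bray-Curtis distances and classical-MDS principal coordinates carry
a fixed sign convention (largest-magnitude loading positive per axis) for
reproducibility; negative eigenvalues are reported but excluded from
coordinates.

# The synthetic cohort generator

`synthetic_truth()` + `generate_cohort()` define the stated world every
test runs in. Defaults mirror the discovery-cohort scale: 426 participants,
171 species, follow-up interval ~ Normal(3.15, 0.3) years, age ~
Normal(63.6, 5.4), 31.9% male, BMI mapped to mean 23.4, SD 3.1 kg/m^2, and
covariate marginals (smoking/alcohol prevalence by sex, education/income
distributions, physical activity, energy intake) matched to the cohort
summary scale. Bristol scores, not part of that summary, use a plausible
mode-4 distribution.

Design choices that make the generator a sharp validation instrument:

* **Confounding is injected additively on the latent scale before
  compositional rendering**, so OLS residualization is exactly correct in
  the generating model and any estimator bias is attributable to the
  estimator, not to the adjustment being misspecified.
* **Detection-limit zeros are generated by per-species thresholding**
  (values below the quantile implied by the detection probability become
  zero) — mirroring why zero replacement exists downstream; the
  replacement constant itself is deliberately never used by the generator.
* **Compositional closure** to 100% per sample. The designated feature's
  log relative abundance thus carries a small shared "log total" noise
  term; with the default feature log-SD of 2 (species span orders of
  magnitude) this attenuates cross-lag estimates by well under 0.01, which
  the recovery tests bound empirically.
* **Phenotypes** are generated on the log scale with a participant random
  intercept (default ICC 0.5, total noise SD 0.5 — consistent with an
  HOMA-IR median of 1.5 and upper-quartile near 2.2). Fasting insulin is
  back-derived from HOMA-IR and an independently drawn glucose so the
  homeostasis-model identity holds exactly in the data.
* **Clean mediation scenarios** set rho2 = r3 = 0 in the generating truth.
  Otherwise the BMI -> microbe cross-lag path, acting through the
  correlation between baseline BMI and the binary adiposity exposure,
  adds an exposure -> mediator channel beyond the injected alpha and the
  population ACME is no longer alpha x b. With those paths off, the
  injected (alpha, b, c') are exactly the population coefficients of the
  fitted mediator and outcome models, so coverage and
  proportion-mediated recovery are well-defined. The same interaction is
  real in the forward direction: a nonzero mediation alpha partially
  cancels or inflates apparent rho2 in the cross-lag screen, which is a
  property of the data-generating world, not a bug.

What the generator does **not** emulate: phylogenetic correlation among
background species, strain-level structure, covariate-dependent detection,
informative dropout, or measurement error in anthropometry. A green
recovery test therefore establishes estimator correctness under the stated
structural assumptions, not robustness to their violation.

The HMP-style replication generator (`generate_replication_cohort()`)
reuses the latent machinery with n = 43, ages uniform in 18-40, a race
column, ~1-year intervals, and BMI at baseline only.

`make_fixture_roster()` reproduces the documented exclusion scenario
deterministically: 505 paired participants of whom 37 miss BMI at a visit,
2 miss the interval, and 40 take diabetes medication (disjoint by default),
leaving the 426-participant analysis set.

# Numerical choices and degenerate inputs

* Residualization errors on rank-deficient covariate matrices and names
  the collinear columns; Z-scoring errors on constant vectors; partial
  correlation errors when a variable is collinear with the conditioning
  variable.
* `fit_crosslag()` errors on non-PSD input and on |r3| = 1; the PSD
  tolerance is -1e-10 on the smallest eigenvalue.
* BH FDR is the exact step-up rule (sort, cummin, cap at 1).
* Prevalence filtering uses `>=` on the abundance floor and
  `ceiling(min_prev x n)` on the sample count; an empty result warns
  rather than errors.
* Per-feature failures inside screens (e.g. a constant feature) warn and
  drop the feature from the FDR family instead of aborting the screen.
* All simulation entry points take explicit seeds and restore the caller's
  RNG state.

# Limitations

Only two-wave designs are supported (no multi-wave or random-intercept
cross-lagged models); confounder adjustment is linear; there is no
imputation (complete-case per model); mediation offers no sensitivity
analysis for sequential ignorability; and the pipeline emits plain TSV
tables rather than figures.
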