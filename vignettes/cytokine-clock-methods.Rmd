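---
title: "Methods: a cytokine clock and functional brain-network volumetrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a cytokine clock and functional brain-network volumetrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`cytoclock` implements an analysis chain that links circulating immune
proteins to age-related gray-matter atrophy: a physiological-age
predictor (the cytokine clock, *CyClo*) is extracted from a 24-marker
blood panel and then related, together with calendar age and sex, to
the TIV-normalized volumes of seven functional cortical networks.
This vignette is the package's own account of each model, its
assumptions, the tunable parameters, and the numerical choices.

## The synthetic cohort and what it emulates

Every stage is exercised on seeded synthetic cohorts with known ground
truth, generated by `sim_config()` / `generate_cohort()`. The generator
emulates the statistical structure of a longitudinal brain-aging cohort:

* **Subjects and visits.** 554 subjects by default, baseline ages from a
  truncated normal (mean 69 y, sd 9 y) on [47, 102]; visit counts
  `1 + Poisson(2)` truncated at 13 (mean about 3); consecutive visits
  separated by `1 + Exponential(mean 0.3)` years. Only "at least a year
  between visits" and the visit-count summary are known cohort facts;
  the gap law and the Poisson visit count are declared assumptions.
  Sex is coded female = 1, male = 0 (the analysis never depends on the
  coding direction; the convention is fixed here for reproducibility).
* **Cytokine panel.** Marker `j`'s log-level at a visit is
  `mu_j + gamma_j (age - 69) + s_j sex + b_batch + e`, with Gaussian
  noise of sd 0.8 log-units. Exactly 9 of the 24 markers carry nonzero
  age slopes (0.015-0.032 log-units/year, concentrated on vascular
  growth factors and core inflammatory mediators). These magnitudes
  were chosen once, by calibration: with 9 markers whose individual
  age correlations are of order 0.2-0.3, a pooled linear clock attains
  an age correlation near 0.5, the regime the analysis is designed for.
* **Latent inflammation score.** The per-visit score is the
  standardized combination `sum_j gamma_j (gamma_j (age - 69) + e_j)`
  over true markers - a deterministic (noise-free) function of the
  *realized* marker biology, with no extra randomness of its own. This
  matters: because the score shares the markers' residuals, a clock
  fitted on the markers can recover it, and volume effects attributed
  to the score are genuinely clock-linked rather than a hidden third
  variable.
* **Brain volumes.** Each network's TIV-fraction is
  `base_k + alpha_k (age - 69) + s_k sex + c_k latent + shared + noise`.
  The per-visit `shared` factor (sd 0.003) is common to all seven
  networks and makes them highly inter-correlated, as cortical volumes
  are; the age slopes are all negative with the somatomotor analogue
  steepest; the latent-score loadings are negative and concentrated on
  the default-mode, limbic and dorsal-attention analogues. Base
  fractions sum to about 0.25 of TIV with a non-network remainder of
  0.16, so total GMV/TIV sits near 0.41 and every network fraction
  stays safely positive. TIV is constant within subject.
* **Missingness.** Markers fall in two bands: the first 11 panel
  columns around 3% missing, the next 13 around 45% - the two-band
  structure of a panel in which some assays frequently fail QC. The
  masking probability is a logistic function of age only (an observed
  covariate), so the mechanism is MAR and imputation is well-posed.
* **Duplicates.** Assays report technical duplicates; the generator
  produces replicate pairs with log-normal noise (dispersion 0.08 by
  default, i.e. roughly an 8% assay CV), under which about 1% of
  entries exceed the CV 20 filter.

What the generator does **not** emulate: limit-of-detection censoring,
plate effects beyond an additive batch offset, non-normal marker
distributions, informative (MNAR) missingness, visit attrition
correlated with health, and any spatial structure in the volumes.
Passing tests therefore demonstrate correctness of the statistical
machinery under a clean MAR, linear-Gaussian data-generating process -
not robustness to the full messiness of real cohort data.

## Preprocessing

* **CV filter.** Each entry's duplicate pair is collapsed to its mean
  when `100 * sd / mean <= 20` (two-replicate sample sd, divisor 1),
  otherwise set missing; nonpositive means are treated as undetectable.
  A CV of exactly 20 is retained. The CV is computed on the raw
  concentration scale (assays report concentrations; computing it after
  the log transform would change the statistic's meaning).
* **Log transform.** Natural log of pg/mL; nonpositive observed values
  are an input error, named by entry.
* **Missingness screening.** Markers missing in more than 55% of
  samples are removed.
* **Batch correction.** Per marker, observed values are regressed on
  intercept, age, sex and sum-to-zero batch indicators; only the fitted
  batch component is subtracted, so age- and sex-attributable variation
  survives correction. Sum-to-zero coding makes the corrected values
  sit at the grand batch-average level. The operation is idempotent.
  A batch with no observed entries for a marker contributes no
  correction (coefficient taken as zero, with a warning). On complete
  data the result coincides with limma's `removeBatchEffect`, which the
  test suite uses as an independent reference; the in-package
  implementation exists because the panel has per-cell missingness.
* **Balancing weights.** Visit ages are binned (5-year bins by default;
  the width is a declared assumption, configurable) and each visit
  weighted `1 / (count in its bin)`, so age groups contribute equally
  to the imputation regressions and the clock fit rather than letting
  the crowded center of the age distribution dominate.

## Imputation: chained equations with weighted PMM

Missing entries are initialized by a weighted draw from the marker's
observed values. Then, for each of 5 sweeps, each incomplete marker in
turn is regressed (weighted least squares, balancing weights as
observation weights) on all other markers' current values plus sex; a
coefficient draw is taken from the estimated sampling distribution
`N(beta_hat, sigma2 (X'WX)^-1)`; predictions are formed for observed
rows (point estimate) and missing rows (perturbed draw); and each
missing entry receives the observed value of one of the `k = 5` donors
with the nearest predicted value, uniformly at random (ties among
equidistant donors break uniformly). Every imputed value is therefore a
member of the marker's observed support - the defining property of
predictive mean matching - and observed entries are never touched.

Donor count (5) and sweep count (5) follow the conventions of the
established chained-equations implementations; the perturbation scheme
is the standard normal approximation to the coefficient posterior.
All three are configurable via `impute_spec()`. Singular conditional
systems fall back to a tiny ridge. The ensemble runs M independent
chains on distinct substreams of one master seed; M = 500 matches the
original study design, while desk-scale analyses in this package use
M = 50, which is enough for stable selection frequencies at the
simulated effect sizes.

## The clock: grouped-CV weighted LASSO, pooled

For each completed panel, markers are centered and scaled (so
coefficients are comparable across markers), and age is regressed on
the panel by LASSO, minimizing

```
(1 / (2 sum w)) * sum_i w_i (age_i - b0 - x_i b)^2 + lambda * sum_j |b_j|
```

by cyclic coordinate descent with soft-thresholding (compiled code;
convergence when the largest coefficient change falls below 1e-7, at
most 1e5 sweeps; the intercept is unpenalized; weights are normalized
to mean 1 so lambda is comparable across cohorts). The grid is 100
log-spaced values from `lambda_max` - the smallest penalty that zeroes
every coefficient, computed in closed form - down to `1e-3 lambda_max`,
solved with warm starts. Solutions satisfy the KKT conditions, which
the test suite checks directly against an independent convex solver.

The penalty is chosen by **subject-grouped** K = 10 cross-validation:
subjects, not visits, are randomized to folds, so repeated measures of
one person never appear on both sides of a split - with longitudinal
data, ignoring this leaks identity and overstates accuracy. Two rules
are provided: `"1se"` (default; largest lambda within one standard
error of the minimum CV error) and `"min"`. Sex is not a clock
predictor by default (the clock is defined on the protein panel);
it can be added by passing it as a panel column if desired.

The M per-panel models are pooled into mean coefficients with standard
errors, per-marker selection frequencies, and a per-visit CyClo. The
pooling statistic is the **median** of the M predictions by default,
with the mean available (`pool = "mean"`): the two natural choices are
both implemented because either is defensible and they differ little at
moderate M; results in this package report the median.

A caution on reading selection frequencies: they vary over the M
imputations while the cohort draw stays fixed, so they quantify
imputation-robustness of selection, not sampling variability. A null
marker that happens to correlate with age in the one observed cohort
will be selected consistently across imputations; under the liberal
`"min"` rule such a marker can reach frequency near 1, while under the
sparser `"1se"` rule both it and the weakest true markers are
suppressed. Recovery experiments in the test suite run at the default
1se rule and interpret frequencies with this in mind.

**Propagation.** CyClo is carried to a same-subject visit lacking a
blood draw if a measured visit lies within ±3 years: the assigned value
is the source CyClo plus the elapsed time (a 2019 target served by a
2020 source gets the 2020 value minus one year). Nearest source wins;
exact ties break toward the earlier visit. Visits without a donor in
range stay unassigned.

## Volumetrics

Volumes (mL) are divided by the visit's TIV; a range check rejects
input that already looks normalized, so the transform cannot be applied
twice. Descriptive structure is summarized by a pairwise-complete
Pearson correlation matrix with two-sided t-test p-values
(pairwise-complete rather than listwise, so MRI-only visits still
contribute to descriptive statistics). Scatter summaries of GMV
against age use ordinary least squares per sex; a robust-regression
variant was considered and not asserted, since no tuning constants were
available to reproduce one faithfully.

## The mixed-model ladder

Four nested random-intercept models for the GMV fraction -
`~1`, `~age`, `~age+sex`, `~age+sex+cyclo`, each with `(1 | subject)` -
are fitted by **maximum likelihood** (not REML: ML keeps AIC/BIC and
likelihood-ratio tests valid across fixed-effect structures; the
estimation criterion was an open choice and ML is the one under which
the ladder's comparisons are coherent). The fixed effects and residual
variance are profiled out analytically given the variance ratio
`theta = sigma_u^2 / sigma^2`; `theta` is found by a coarse log-grid
bracket plus golden-section refinement on [0, 1e6] (tolerance 1e-9),
with per-subject rank-one identities making the cost linear in the
number of visits. `AIC = -2l + 2k`, `BIC = -2l + k log n`, with `k`
counting fixed coefficients plus two variance parameters. Successive
models are compared by chi-squared likelihood-ratio tests; per-
coefficient stars are Wald z-tests. Degenerate layouts are handled
explicitly: a rank-deficient design is an error (e.g. a clock column
identical to age), and a zero-within-variance layout drives the fit to
the theta search bound, where the likelihood of a one-way layout is
unbounded - the tests exercise a near-degenerate version instead.

## Canonical correlation analysis

With `X = (age, cyclo, sex)` standardized (sex enters as its 0/1 code,
standardized like any column) and `Y` the seven network fractions,
weights come from the SVD of `Rxx^{-1/2} Rxy Ryy^{-1/2}`; singular
values are the canonical correlations, and `s = min(p, q) = 3`
functions are returned. Inverse square roots use a symmetric
eigendecomposition; an eigenvalue below 1e-10 means a numerically
collinear set and is an error naming the offending set. Variates have
unit sample variance; within-set variates are uncorrelated. Signs are
fixed so the largest-magnitude X-side loading of each function is
positive, making weights reproducible across platforms. Plain
(unregularized) CCA is implemented; a regularized variant would need a
penalty parameter that nothing in the design specifies.

Sequential significance uses Bartlett's chi-squared,
`-(n - 1 - (p+q+1)/2) log Lambda_k` with
`Lambda_k = prod_{i>=k} (1 - rho_i^2)` on
`(p-k+1)(q-k+1)` degrees of freedom (21, 12, 5 here), and Rao's F
approximation, which reduces to the exact regression F test when the
remaining X-side dimension is 1. `n` is the number of complete rows
entering the fit. Redundancy per dimension is the mean squared own-set
loading times the canonical root; totals are sums over dimensions.

## Problem sizes and reproducibility

Desk-scale analyses and the acceptance script use 300 subjects and
M = 50 imputations; the test suite's recovery experiments use cohorts
of 120-500 subjects. These sizes are the package's chosen working
scale: large enough that selection frequencies, variance components and
canonical structure are stable, small enough to iterate on. One master
seed drives every stage through derived substreams, so changing M does
not perturb the simulated cohort, and identical configuration plus seed
reproduces byte-identical artifacts.

## Known limitations

* The clock is linear and Gaussian; no elastic-net sweep, nonlinear or
  survival-calibrated variants.
* Imputation assumes MAR given the panel and sex; MNAR mechanisms are
  out of scope.
* The LMM has a single random intercept - no random slopes, crossed
  effects, or heteroscedastic residuals.
* CCA significance relies on the classical approximations, not
  permutation.
* Synthetic volumes are linear in age; real atrophy trajectories bend.
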