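# cytoclock

Chronic low-grade inflammation rises with age ("inflammaging"), and
circulating immune proteins carry a readable trace of that process.
`cytoclock` implements an end-to-end analysis that (1) extracts a
**cytokine clock (CyClo)** — a physiological-age predictor built from a
24-marker panel of blood proteins — and (2) asks how calendar age, sex,
and the clock relate to age-related atrophy of seven functional
cortical networks (visual, somatomotor, dorsal attention, ventral
attention, limbic, frontoparietal, default mode), measured as
TIV-normalized gray-matter volumes.

The package is written for biostatisticians and aging researchers who
want the full chain as tested, seedable code: a synthetic longitudinal
cohort generator with known ground truth, assay preprocessing, multiple
imputation, the penalized clock, mixed-model inference, and canonical
correlation analysis.

## The statistical core

**Clock construction.** Marker log-levels are duplicate-collapsed
(entries with replicate CV > 20 are removed), log-transformed, screened
at 55% missingness, batch-corrected with age and sex protected in the
design, and weighted by `1/(age-bin count)` so all ages count equally.
The incomplete panel is multiply imputed by chained equations with
*weighted predictive mean matching* (M completed panels). On each
panel, age is regressed on the standardized markers with a weighted
LASSO,

    min  (1 / 2Σw) Σᵢ wᵢ (ageᵢ − β₀ − xᵢβ)²  +  λ Σⱼ |βⱼ| ,

λ chosen by subject-grouped 10-fold cross-validation (no subject ever
straddles a train/test split). The M models are pooled into mean
coefficients, selection frequencies, and a per-visit CyClo (median of
the M predictions), which is then propagated to a same-subject visit
without a blood draw when a measured visit lies within ±3 years
(shifted by the elapsed time).

**Brain volumetrics.** Volumes are expressed as fractions of total
intracranial volume. A four-model random-intercept ladder
`GMV ~ 1`, `~age`, `~age+sex`, `~age+sex+CyClo`, each with
`(1 | subject)`, is fitted by maximum likelihood and compared by
AIC/BIC and likelihood-ratio χ² tests. Canonical correlation analysis
between X = (age, CyClo, sex) and Y = (7 network fractions) yields
s = min(3, 7) = 3 canonical functions with standardized weights,
loadings, roots ρ², Bartlett χ² tests on (p−k+1)(q−k+1) = 21/12/5
degrees of freedom, Rao F approximations, and redundancy coefficients.

All of the statistical machinery — the coordinate-descent LASSO, the
chained-equation weighted-PMM imputer, the profiled-likelihood mixed
model, and the SVD-based CCA — is implemented in the package and
cross-checked in the test suite against independent references
(glmnet, lme4, limma, `stats::cancor`, and brute-force oracles).

## Worked example

```r
library(cytoclock)

cfg <- pipeline_config(sim = sim_config(n_subjects = 300), m = 50, seed = 1)
res <- run_pipeline(cfg, out_dir = "results/run1")
```

The pipeline logs each stage:

```
simulate: 879 visits, 300 subjects
preprocess: 740 blood visits, 24 markers kept (0 dropped), mean missingness 0.265
impute: M = 50 completed panels
clock: cyclo-age correlation 0.506 on measured visits
match: 718 MRI visits, overlap 604 measured -> 705 with propagation
ladder: best AIC model 4, best BIC model 2
cca: canonical correlations 0.85, 0.605, 0.538
```

Reading the output: the pooled clock tracks calendar age at r ≈ 0.51 on
740 measured visits — a *moderate* correlation by design, since a
physiological clock is not meant to reproduce the calendar. ±3-year
propagation raises the number of MRI visits with a clock value from 604
to 705. On the matched table, the model ladder prefers the full model
`age + sex + CyClo` by AIC (BIC, with its harsher penalty, stops at the
sparser model at this cohort size), and the CCA returns its three
canonical functions, whose weights, loadings, Bartlett/Rao tests and
redundancy coefficients are in `res$cca`, `res$tests`, `res$rao` and
`res$redundancy`, with everything serialized under `results/run1/`.

The same workflow is broken into narrative steps under `analysis/`
(`01_simulate.R` … `07_cca.R`, run from the repository root), each
writing its tables under `results/`.

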