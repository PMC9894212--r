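Package: cytoclock
Title: Cytokine Age Clocks and Functional Brain-Network Volumetrics for
    Longitudinal Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Constructs a cytokine clock (CyClo) - a physiological-age
    predictor built from a panel of 24 circulating immune proteins - and
    relates it to age-related atrophy of seven functional cortical
    networks.  Provides a seeded longitudinal cohort simulator with known
    ground truth; assay preprocessing (duplicate coefficient-of-variation
    filtering, log transformation, missingness screening, batch-effect
    removal, age-bin balancing weights); multiple imputation by chained
    equations with weighted predictive mean matching; per-imputation
    cross-validated weighted LASSO fits pooled into coefficients,
    selection frequencies and per-visit clock predictions with temporal
    propagation to neighbouring visits; TIV-normalised volumetrics; a
    random-intercept mixed-model ladder with AIC/BIC and likelihood-ratio
    comparisons; and canonical correlation analysis with Bartlett and
    Rao sequential significance tests and redundancy coefficients.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    glmnet,
    lme4,
    limma,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
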