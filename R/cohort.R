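#' Marker and network labels used throughout the package
#'
#' The 24 circulating immune proteins of the assay panel and the seven
#' functional cortical networks whose gray-matter volumes are analysed.
#'
#' @format Character vectors.
#' @name panel_labels
NULL

#' @rdname panel_labels
#' @export
cytokine_markers <- c(
  "TNF_l", "IFN_g", "IL_6", "IL_10", "MCP_1", "MCP_4", "IP_10", "eotaxin",
  "eotaxin_3", "VEGF", "VEGF_D", "VEGF_C", "PLGF", "bFGF", "VCAM_1",
  "ICAM_1", "Flt_1", "TIE2", "hs_CRP", "SAA", "MIP_1a", "MIP_1b", "TARC",
  "MDC"
)

#' @rdname panel_labels
#' @export
network_names <- c(
  "visual", "somatomotor", "dorsal_attention", "ventral_attention",
  "limbic", "frontoparietal", "default_mode"
)

# Markers whose log-levels truly drift with age in the default simulation,
# with slopes in log-units per year.  Growth/vascular factors and core
# inflammatory mediators carry the signal, mirroring the biology an
# inflammaging panel is designed around.
default_true_slopes <- c(
  TNF_l = 0.022, IL_6 = 0.028, MCP_1 = 0.018, IP_10 = 0.024,
  eotaxin = 0.016, VEGF = 0.032, VEGF_D = 0.028, PLGF = 0.026,
  VCAM_1 = 0.015
)

#' Simulation configuration for a synthetic longitudinal cohort
#'
#' Bundles and validates every magnitude the cohort generator uses.  The
#' defaults emulate an observational brain-aging cohort: 554 subjects aged
#' 47--102 (mean 69), about three visits each at least a year apart, a
#' 24-marker cytokine panel of which 9 markers are age-associated, four
#' assay batches, 11 markers with low (<5%) and 13 with high (40--55%)
#' missingness, and seven highly inter-correlated functional-network
#' volumes that decline with age.
#'
#' @param n_subjects Number of subjects.
#' @param age_range Admissible baseline age range in years (within 40--110).
#' @param age_mean,age_sd Location/scale of the truncated-normal baseline
#'   age distribution, years.
#' @param mean_visits Mean number of visits per subject (minimum one).
#' @param max_visits Upper truncation for the per-subject visit count.
#' @param visit_gap_min Minimum gap between consecutive visits, years.
#' @param visit_gap_mean_extra Mean of the exponential excess gap beyond
#'   `visit_gap_min`, years.
#' @param female_frac Proportion of female subjects (sex coded female = 1,
#'   male = 0).
#' @param markers Marker labels (panel columns).
#' @param age_slopes Named vector of true age slopes, log-units per year;
#'   markers absent from the vector have slope zero.  The named markers
#'   are the true support set.
#' @param marker_mu Baseline log-concentration per marker at age 69
#'   (log pg/mL); recycled if scalar.
#' @param sex_effects Per-marker additive sex effect, log-units (female
#'   minus male); recycled if scalar.
#' @param marker_noise_sd Residual sd of a marker log-level, log-units.
#' @param n_batches Number of assay batches.
#' @param batch_magnitudes Additive per-batch offset applied to every
#'   marker, log-units; length `n_batches`.
#' @param n_low_missing,n_high_missing How many markers fall in the
#'   low/high missingness bands (low band = first `n_low_missing` panel
#'   columns).
#' @param missing_low_frac,missing_high_frac Target missing fraction per
#'   band, in `[0, 1)`.
#' @param duplicate_cv_sd Dispersion (sd of log replicate noise) used by
#'   [inject_duplicate_noise()].
#' @param network_base Baseline TIV-fraction of each of the 7 networks.
#' @param network_age_slopes Per-network TIV-fraction change per year.
#' @param network_sex_effects Per-network additive sex effect (fraction).
#' @param network_clock_loadings Per-network loading on the latent
#'   inflammation score (fraction per latent sd); negative loadings mean
#'   higher inflammation, smaller volume.
#' @param shared_factor_sd Sd of the per-visit factor shared by all seven
#'   networks (fraction); drives their high pairwise correlation.
#' @param network_noise_sd Per-network residual sd (fraction).
#' @param gmv_extra_base,gmv_extra_age_slope,gmv_extra_noise_sd Baseline,
#'   age slope and noise of the gray matter outside the seven networks
#'   (fractions), so that total GMV exceeds every single network.
#' @param tiv_mean_male,tiv_mean_female,tiv_sd Total intracranial volume
#'   distribution, mL; TIV is constant within subject.
#' @param seed Integer master seed.
#'
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 554L,
                       age_range = c(47, 102),
                       age_mean = 69, age_sd = 9,
                       mean_visits = 3, max_visits = 13L,
                       visit_gap_min = 1, visit_gap_mean_extra = 0.3,
                       female_frac = 308 / 554,
                       markers = cytokine_markers,
                       age_slopes = default_true_slopes,
                       marker_mu = NULL,
                       sex_effects = NULL,
                       marker_noise_sd = 0.8,
                       n_batches = 4L,
                       batch_magnitudes = c(0.15, -0.10, 0.05, -0.10),
                       n_low_missing = 11L, n_high_missing = 13L,
                       missing_low_frac = 0.03, missing_high_frac = 0.45,
                       duplicate_cv_sd = 0.08,
                       network_base = c(0.040, 0.048, 0.024, 0.024,
                                        0.020, 0.040, 0.056),
                       network_age_slopes = -c(1.2, 2.5, 1.5, 1.4,
                                               1.0, 1.3, 1.6) * 1e-4,
                       network_sex_effects = c(-8, 2, 2, 6, 2, 10, 2) * 1e-4,
                       network_clock_loadings = -c(0, 0, 10, 0, 15, 0, 20) * 1e-4,
                       shared_factor_sd = 0.003,
                       network_noise_sd = 8e-4,
                       gmv_extra_base = 0.16,
                       gmv_extra_age_slope = -4e-4,
                       gmv_extra_noise_sd = 1e-3,
                       tiv_mean_male = 1500, tiv_mean_female = 1350,
                       tiv_sd = 100,
                       seed = 20221202L) {
  p <- length(markers)
  if (anyDuplicated(markers)) stop("marker labels must be unique")
  if (length(age_range) != 2L || age_range[1] >= age_range[2] ||
      age_range[1] < 40 || age_range[2] > 110)
    stop("age_range must be increasing and within [40, 110]")
  for (nm in c("n_subjects", "mean_visits", "max_visits", "n_batches"))
    if (get(nm) < 1) stop(nm, " must be positive")
  if (!all(names(age_slopes) %in% markers))
    stop("age_slopes names must be a subset of markers")
  if (missing_low_frac < 0 || missing_low_frac >= 1 ||
      missing_high_frac < 0 || missing_high_frac >= 1)
    stop("missing fractions must lie in [0, 1)")
  if (n_low_missing + n_high_missing > p)
    stop("n_low_missing + n_high_missing exceeds the number of markers")
  if (length(batch_magnitudes) != n_batches)
    stop("batch_magnitudes must have length n_batches")
  if (duplicate_cv_sd < 0) stop("duplicate_cv_sd must be nonnegative")
  for (nm in c("network_base", "network_age_slopes", "network_sex_effects",
               "network_clock_loadings"))
    if (length(get(nm)) != 7L) stop(nm, " must have length 7")

  if (is.null(marker_mu)) {
    # deterministic spread of plausible baseline log pg/mL levels
    marker_mu <- setNames(1.5 + 0.35 * (seq_len(p) %% 7), markers)
  } else marker_mu <- setNames(rep_len(marker_mu, p), markers)
  if (is.null(sex_effects)) {
    sex_effects <- setNames(rep_len(c(0.10, -0.05, 0.02), p), markers)
  } else sex_effects <- setNames(rep_len(sex_effects, p), markers)

  slopes <- setNames(numeric(p), markers)
  slopes[names(age_slopes)] <- age_slopes

  structure(list(
    n_subjects = as.integer(n_subjects), age_range = age_range,
    age_mean = age_mean, age_sd = age_sd,
    mean_visits = mean_visits, max_visits = as.integer(max_visits),
    visit_gap_min = visit_gap_min,
    visit_gap_mean_extra = visit_gap_mean_extra,
    female_frac = female_frac,
    markers = markers, age_slopes = slopes,
    true_markers = names(age_slopes)[age_slopes != 0],
    marker_mu = marker_mu, sex_effects = sex_effects,
    marker_noise_sd = marker_noise_sd,
    n_batches = as.integer(n_batches), batch_magnitudes = batch_magnitudes,
    n_low_missing = as.integer(n_low_missing),
    n_high_missing = as.integer(n_high_missing),
    missing_low_frac = missing_low_frac,
    missing_high_frac = missing_high_frac,
    duplicate_cv_sd = duplicate_cv_sd,
    network_base = setNames(network_base, network_names),
    network_age_slopes = setNames(network_age_slopes, network_names),
    network_sex_effects = setNames(network_sex_effects, network_names),
    network_clock_loadings = setNames(network_clock_loadings, network_names),
    shared_factor_sd = shared_factor_sd,
    network_noise_sd = network_noise_sd,
    gmv_extra_base = gmv_extra_base,
    gmv_extra_age_slope = gmv_extra_age_slope,
    gmv_extra_noise_sd = gmv_extra_noise_sd,
    tiv_mean_male = tiv_mean_male, tiv_mean_female = tiv_mean_female,
    tiv_sd = tiv_sd,
    seed = as.integer(seed)
  ), class = "sim_config")
}

rtruncnorm1 <- function(n, mean, sd, lower, upper) {
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need)) {
    draw <- rnorm(length(need), mean, sd)
    ok <- draw >= lower & draw <= upper
    out[need[ok]] <- draw[ok]
    need <- need[!ok]
  }
  out
}

#' Generate a synthetic longitudinal cohort with known ground truth
#'
#' Draws subjects, visit schedules, a complete log-scale cytokine panel,
#' TIV-scaled brain volumes, and a truth record for recovery tests.  The
#' log-level of marker j at visit i is
#' `mu_j + gamma_j (age_i - 69) + s_j sex_i + b_batch(i) + e_ij` with
#' Gaussian noise `e_ij`; exactly the configured support has nonzero
#' `gamma_j`.  The per-visit latent inflammation score is the
#' standardized linear combination `sum_j gamma_j (gamma_j (age-69) + e_ij)`
#' over true markers: a deterministic function of the realized marker
#' biology (no extra noise added), so a marker-based clock can recover it.
#' Each network TIV-fraction is
#' `base_k + alpha_k (age-69) + s_k sex + c_k latent + shared_i + noise`,
#' all networks sharing the common per-visit factor.
#'
#' @param config A [sim_config()].
#' @return A list of class `cohort_sim` with elements `visits` (data frame:
#'   `visit_id`, `subject_id`, `visit_time`, `age`, `sex`, `batch`),
#'   `panel` (complete visits x markers matrix of natural-log pg/mL),
#'   `volumes` (data frame of raw mL volumes: `tiv`, `gmv`, seven
#'   networks), and `truth` (slopes, support, latent score, noise-free
#'   panel, network coefficients, batch offsets).
#' @export
generate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  ns <- config$n_subjects
  sex_subj <- rbinom(ns, 1L, config$female_frac)
  age0 <- rtruncnorm1(ns, config$age_mean, config$age_sd,
                      config$age_range[1], config$age_range[2])
  nv <- pmin(1L + rpois(ns, max(config$mean_visits - 1, 0)),
             config$max_visits)

  subj <- rep(seq_len(ns), nv)
  n <- length(subj)
  gap <- config$visit_gap_min + rexp(n, 1 / config$visit_gap_mean_extra)
  first <- !duplicated(subj)
  gap[first] <- 0
  tvis <- stats::ave(gap, subj, FUN = cumsum)

  visits <- data.frame(
    visit_id = sprintf("V%04d", seq_len(n)),
    subject_id = sprintf("S%03d", subj),
    visit_time = round(runif(ns, 0, 3)[subj] + tvis, 4),
    age = age0[subj] + tvis,
    sex = sex_subj[subj],
    batch = sample.int(config$n_batches, n, replace = TRUE),
    stringsAsFactors = FALSE
  )

  p <- length(config$markers)
  agec <- visits$age - 69
  signal <- outer(rep(1, n), config$marker_mu) +
    outer(agec, config$age_slopes) +
    outer(visits$sex, config$sex_effects)
  noise <- matrix(rnorm(n * p, 0, config$marker_noise_sd), n, p)
  panel <- signal + config$batch_magnitudes[visits$batch] + noise
  dimnames(panel) <- list(visits$visit_id, config$markers)
  dimnames(noise) <- dimnames(panel)

  tm <- config$true_markers
  g <- config$age_slopes[tm]
  latent_raw <- drop((outer(agec, g) + noise[, tm, drop = FALSE]) %*% g)
  lsd <- sd(latent_raw)
  latent <- if (n > 1 && lsd > 0) (latent_raw - mean(latent_raw)) / lsd
            else latent_raw * 0

  tiv_subj <- rnorm(ns,
                    ifelse(sex_subj == 1, config$tiv_mean_female,
                           config$tiv_mean_male),
                    config$tiv_sd)
  tiv_subj <- pmax(tiv_subj, 900)
  tiv <- tiv_subj[subj]
  shared <- rnorm(n, 0, config$shared_factor_sd)
  frac <- outer(rep(1, n), config$network_base) +
    outer(agec, config$network_age_slopes) +
    outer(visits$sex, config$network_sex_effects) +
    outer(latent, config$network_clock_loadings) +
    shared +
    matrix(rnorm(n * 7, 0, config$network_noise_sd), n, 7)
  colnames(frac) <- network_names
  gmv_frac <- rowSums(frac) + config$gmv_extra_base +
    config$gmv_extra_age_slope * agec +
    rnorm(n, 0, config$gmv_extra_noise_sd)

  volumes <- data.frame(visit_id = visits$visit_id,
                        tiv = tiv, gmv = gmv_frac * tiv,
                        frac * tiv, stringsAsFactors = FALSE)

  truth <- list(
    age_slopes = config$age_slopes,
    support = tm,
    latent = setNames(latent, visits$visit_id),
    noise_free_panel = signal + config$batch_magnitudes[visits$batch],
    batch_offsets = config$batch_magnitudes,
    network_age_slopes = config$network_age_slopes,
    network_sex_effects = config$network_sex_effects,
    network_clock_loadings = config$network_clock_loadings
  )

  structure(list(visits = visits, panel = panel, volumes = volumes,
                 truth = truth, config = config),
            class = "cohort_sim")
}

#' @export
print.cohort_sim <- function(x, ...) {
  cat(sprintf(
    "Synthetic cohort: %d subjects, %d visits, %d markers, seed %d\n",
    length(unique(x$visits$subject_id)), nrow(x$visits),
    ncol(x$panel), x$config$seed))
  invisible(x)
}

#' Inject missing-at-random entries into a cytokine panel
#'
#' Masks entries marker by marker so that each marker's missing fraction
#' sits near its configured band (`missing_low_frac` for the first
#' `n_low_missing` panel columns, `missing_high_frac` for the next
#' `n_high_missing`; any remaining markers stay complete).  The masking
#' probability depends on age only (an observed covariate), never on the
#' value being hidden, so the mechanism is MAR.  Observed values are
#' never altered.
#'
#' @param panel Visits x markers matrix (`NA` = missing).
#' @param visits Visit table aligned to `panel` rows (supplies `age`).
#' @param config A [sim_config()].
#' @param seed Seed for the masking draws; defaults to `config$seed + 1`.
#' @return The panel with additional `NA` entries.
#' @export
inject_missingness <- function(panel, visits, config, seed = NULL) {
  stopifnot(nrow(panel) == nrow(visits))
  if (config$missing_low_frac >= 1 || config$missing_high_frac >= 1)
    stop("missing fractions must be below 1")
  set.seed(if (is.null(seed)) config$seed + 1L else seed)
  p <- ncol(panel)
  frac <- c(rep(config$missing_low_frac, config$n_low_missing),
            rep(config$missing_high_frac, config$n_high_missing),
            rep(0, p - config$n_low_missing - config$n_high_missing))
  zage <- as.vector(scale(visits$age))
  if (any(!is.finite(zage))) zage <- rep(0, nrow(panel))
  for (j in seq_len(p)) {
    f <- frac[j]
    if (f <= 0) next
    # intercept solving mean masking probability = f under the age tilt
    a <- uniroot(function(a) mean(plogis(a + 0.5 * zage)) - f,
                 c(-30, 30))$root
    hit <- rbinom(nrow(panel), 1L, plogis(a + 0.5 * zage)) == 1L
    panel[hit, j] <- NA_real_
  }
  panel
}

#' Simulate duplicate assay measurements with multiplicative noise
#'
#' Expands a complete raw-scale (pg/mL) panel into the two technical
#' replicates an electrochemiluminescence assay reports, with
#' log-normal multiplicative noise of dispersion `cv_sd`, so the
#' downstream coefficient-of-variation filter can be exercised.
#'
#' @param panel_raw Complete visits x markers matrix of raw
#'   concentrations (all entries positive).
#' @param cv_sd Sd of the log replicate noise (roughly the assay CV as a
#'   proportion); must be nonnegative.
#' @param seed Integer seed.
#' @return A list of class `duplicate_panel` with matrices `rep1`, `rep2`.
#' @export
inject_duplicate_noise <- function(panel_raw, cv_sd, seed = 1L) {
  if (cv_sd < 0) stop("cv_sd must be nonnegative")
  if (anyNA(panel_raw) || any(panel_raw <= 0))
    stop("panel_raw must be complete and strictly positive")
  set.seed(seed)
  n <- length(panel_raw)
  e1 <- matrix(rnorm(n, 0, cv_sd), nrow(panel_raw))
  e2 <- matrix(rnorm(n, 0, cv_sd), nrow(panel_raw))
  r1 <- panel_raw * exp(e1)
  r2 <- panel_raw * exp(e2)
  dimnames(r1) <- dimnames(r2) <- dimnames(panel_raw)
  structure(list(rep1 = r1, rep2 = r2), class = "duplicate_panel")
}

#' Per-marker missingness report
#'
#' @param panel Visits x markers matrix with `NA` for missing entries.
#' @return Named vector of per-marker missing fractions.
#' @export
marker_missingness <- function(panel) colMeans(is.na(panel))
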