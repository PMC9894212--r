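#' Configuration for a full pipeline run
#'
#' Collects every stage parameter: the cohort simulation settings, the
#' preprocessing thresholds, the imputation ensemble size, the clock
#' cross-validation settings, the propagation range, and the master seed
#' from which all stage substreams are derived (so changing, say, the
#' number of imputations does not perturb the simulated cohort).
#'
#' @param sim A [sim_config()] describing the cohort to simulate.
#' @param m Number of imputations M.
#' @param n_sweeps,n_donors Chained-equation settings, see
#'   [impute_spec()].
#' @param folds CV folds K for the clock.
#' @param rule Penalty rule, `"1se"` or `"min"`.
#' @param pool Pooling statistic, `"median"` or `"mean"`.
#' @param bin_width Age-bin width for balancing weights, years.
#' @param cv_threshold Duplicate CV retention threshold, percent.
#' @param missing_threshold Marker-removal missingness threshold.
#' @param max_gap Clock propagation range, years.
#' @param blood_frac,mri_frac Fraction of visits carrying a blood draw /
#'   an MRI scan (emulates the partial overlap that propagation exists
#'   to repair).
#' @param seed Master seed.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(), m = 50L,
                            n_sweeps = 5L, n_donors = 5L,
                            folds = 10L, rule = "1se",
                            pool = "median", bin_width = 5,
                            cv_threshold = 20, missing_threshold = 0.55,
                            max_gap = 3, blood_frac = 0.85,
                            mri_frac = 0.80, seed = 1L) {
  stopifnot(inherits(sim, "sim_config"), m >= 1, folds >= 2,
            max_gap > 0, blood_frac > 0, blood_frac <= 1,
            mri_frac > 0, mri_frac <= 1)
  structure(list(sim = sim, m = as.integer(m),
                 n_sweeps = as.integer(n_sweeps),
                 n_donors = as.integer(n_donors),
                 folds = as.integer(folds), rule = rule, pool = pool,
                 bin_width = bin_width, cv_threshold = cv_threshold,
                 missing_threshold = missing_threshold, max_gap = max_gap,
                 blood_frac = blood_frac, mri_frac = mri_frac,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Match visits carrying both an MRI volume and a clock value
#'
#' Inner join of the visits that have a volume row and a (measured or
#' propagated) clock value, with a count report of the overlap before
#' and after propagation.
#'
#' @param visits Visit table.
#' @param cyclo_table Output of [propagate_cyclo()] aligned to `visits`.
#' @param volumes Volume table whose `visit_id`s mark MRI-carrying visits.
#' @return List with the matched `table` (visit covariates + cyclo +
#'   volumes) and counts `n_mri`, `n_before` (measured overlap only),
#'   `n_after`.
#' @export
match_visits <- function(visits, cyclo_table, volumes) {
  stopifnot(all(volumes$visit_id %in% visits$visit_id))
  idx <- match(volumes$visit_id, visits$visit_id)
  ct <- cyclo_table[match(volumes$visit_id, cyclo_table$visit_id), ]
  measured <- !is.na(ct$cyclo) & ct$source == "measured"
  assigned <- !is.na(ct$cyclo)
  if (!any(assigned)) stop("no visit has both a volume and a clock value")
  tab <- cbind(visits[idx, c("visit_id", "subject_id", "visit_time",
                             "age", "sex")],
               cyclo = ct$cyclo, cyclo_source = ct$source,
               volumes[setdiff(names(volumes), "visit_id")])
  rownames(tab) <- NULL
  list(table = tab[assigned, ], n_mri = nrow(volumes),
       n_before = sum(measured), n_after = sum(assigned))
}

# Pearson correlation that degrades to NA (not a warning) when either
# side is constant, as can happen in very small or fully-shrunk runs.
safe_cor <- function(x, y) {
  if (sd(x) == 0 || sd(y) == 0) return(NA_real_)
  cor(x, y)
}

write_json_artifact <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = 10,
                       pretty = TRUE)
}

#' Run the full analysis pipeline on a simulated cohort
#'
#' Simulate -> duplicate assay + CV filter -> log transform -> MAR
#' missingness -> marker screening -> batch removal -> balancing weights
#' -> weighted-PMM imputation ensemble -> pooled LASSO clock ->
#' propagation -> visit matching -> TIV normalization + correlation
#' matrix -> mixed-model ladder -> canonical correlation analysis.
#' Every stage artifact is written to `out_dir` as a delimited table or
#' JSON document, with a manifest of content hashes; identical config and
#' seed reproduce identical artifacts.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if missing).
#' @param quiet Suppress stage log lines.
#' @return Invisibly, a list with the main in-memory results (`cohort`,
#'   `panel`, `weights`, `clock`, `cyclo`, `matched`, `cor`, `ladder`,
#'   `cca`, `tests`, `redundancy`, `summary`).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = tempfile(),
                         quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- derive_seeds(config$seed, 6L, tag = 1L)
  say <- function(...) if (!quiet) message(sprintf(...))

  # -- simulate ------------------------------------------------------
  sim <- config$sim
  sim$seed <- seeds[1]
  cohort <- generate_cohort(sim)
  n <- nrow(cohort$visits)
  say("simulate: %d visits, %d subjects", n,
      length(unique(cohort$visits$subject_id)))

  set.seed(seeds[2])
  has_blood <- runif(n) < config$blood_frac
  has_mri <- runif(n) < config$mri_frac
  keep <- has_blood | has_mri
  visits <- cohort$visits[keep, ]
  has_blood <- has_blood[keep]; has_mri <- has_mri[keep]
  panel0 <- cohort$panel[keep, , drop = FALSE]
  volumes <- cohort$volumes[keep, ][has_mri, ]

  # -- preprocess ----------------------------------------------------
  bvis <- visits[has_blood, ]
  dups <- inject_duplicate_noise(exp(panel0[has_blood, , drop = FALSE]),
                                 sim$duplicate_cv_sd, seed = seeds[3])
  raw <- collapse_duplicates_cv_filter(dups, config$cv_threshold)
  panel <- log_transform(raw)
  panel <- inject_missingness(panel, bvis, sim, seed = seeds[4])
  screened <- drop_high_missingness_markers(panel, config$missing_threshold)
  panel <- screened$panel
  panel <- remove_batch_effects(panel, bvis$batch, bvis$age, bvis$sex)
  weights <- compute_balancing_weights(bvis$age, config$bin_width)
  say("preprocess: %d blood visits, %d markers kept (%d dropped), mean missingness %.3f",
      nrow(panel), ncol(panel), length(screened$dropped),
      mean(marker_missingness(panel)))

  # -- impute --------------------------------------------------------
  ens <- generate_ensemble(panel, bvis$sex, weights,
                           impute_spec(config$m, config$n_sweeps,
                                       config$n_donors, seed = seeds[5]))
  say("impute: M = %d completed panels", config$m)

  # -- clock ---------------------------------------------------------
  clock <- fit_clock_ensemble(ens, bvis$age, bvis$subject_id, weights,
                              K = config$folds, rule = config$rule,
                              pool = config$pool, seed = seeds[6])
  cyclo_all <- rep(NA_real_, nrow(visits))
  cyclo_all[has_blood] <- clock$cyclo
  cyclo_tab <- propagate_cyclo(cyclo_all, visits, config$max_gap)
  say("clock: cyclo-age correlation %.3f on measured visits",
      safe_cor(clock$cyclo, bvis$age))

  # -- volumetrics + matching ---------------------------------------
  volumes <- normalize_to_tiv(volumes)
  matched <- match_visits(visits, cyclo_tab, volumes)
  say("match: %d MRI visits, overlap %d measured -> %d with propagation",
      matched$n_mri, matched$n_before, matched$n_after)
  tab <- matched$table
  frac_cols <- paste0(network_names, "_frac")
  cor_mat <- correlation_matrix(tab[, c("age", "cyclo", "sex", frac_cols)])

  # -- mixed-model ladder -------------------------------------------
  ladder <- build_model_ladder(tab)
  say("ladder: best AIC model %d, best BIC model %d", ladder$best_aic,
      ladder$best_bic)

  # -- canonical correlation analysis -------------------------------
  cc_rows <- complete.cases(tab[, c("age", "cyclo", "sex", frac_cols)])
  cca <- fit_cca(tab[cc_rows, c("age", "cyclo", "sex")],
                 tab[cc_rows, frac_cols])
  tests <- bartlett_sequential_test(cca$cor, cca$n, cca$p, cca$q)
  rao <- rao_f_test(cca$cor, cca$n, cca$p, cca$q)
  red <- redundancy(cca)
  say("cca: canonical correlations %s",
      paste(round(cca$cor, 3), collapse = ", "))

  # -- artifacts -----------------------------------------------------
  summary <- list(
    n_subjects = length(unique(visits$subject_id)),
    n_visits = nrow(visits),
    n_blood = sum(has_blood), n_mri = matched$n_mri,
    n_matched_before = matched$n_before,
    n_matched_after = matched$n_after,
    markers_dropped = screened$dropped,
    selection_frequency = as.list(round(clock$selection_frequency, 6)),
    mean_beta = as.list(round(clock$mean_beta, 6)),
    cyclo_age_correlation = round(safe_cor(clock$cyclo, bvis$age), 6),
    ladder = list(AIC = round(unname(ladder$table[, "AIC"]), 4),
                  BIC = round(unname(ladder$table[, "BIC"]), 4),
                  best_aic = ladder$best_aic, best_bic = ladder$best_bic,
                  lrt_m4_vs_m3 = as.list(round(ladder$lrt["m4_vs_m3", ], 6))),
    cca = list(cor = round(cca$cor, 6), roots = round(cca$roots, 6),
               bartlett_df = tests$df,
               bartlett_p = round(tests$p_value, 8),
               rao_p = round(rao$p_value, 8),
               xweights = as.data.frame(round(cca$xweights, 6)),
               yweights = as.data.frame(round(cca$yweights, 6)),
               redundancy_x_given_y = round(red$total_x_given_y, 6),
               redundancy_y_given_x = round(red$total_y_given_x, 6)),
    seed = config$seed
  )

  wcsv <- function(d, f) write.csv(d, file.path(out_dir, f),
                                   row.names = FALSE)
  wcsv(visits, "visits.csv")
  wcsv(data.frame(visit_id = bvis$visit_id, round(panel, 8)), "panel.csv")
  wcsv(data.frame(marker = colnames(panel),
                  missing_frac = round(marker_missingness(panel), 6)),
       "missingness_report.csv")
  wcsv(data.frame(visit_id = bvis$visit_id, weight = weights$w),
       "weights.csv")
  wcsv(cyclo_tab, "cyclo.csv")
  wcsv(data.frame(visit_id = tab$visit_id[cc_rows]), "cca_rows.csv")
  wcsv(round(volumes[sapply(volumes, is.numeric)], 8), "volumes.csv")
  wcsv(data.frame(variable = rownames(cor_mat$r), round(cor_mat$r, 6)),
       "correlation_matrix.csv")
  write_json_artifact(summary, file.path(out_dir, "summary.json"))
  write_json_artifact(list(seed = config$seed, substreams = seeds,
                           m = config$m, folds = config$folds,
                           rule = config$rule, pool = config$pool),
                      file.path(out_dir, "run_manifest.json"))
  files <- setdiff(list.files(out_dir), "manifest.json")
  write_json_artifact(
    lapply(setNames(files, files),
           function(f) unname(tools::md5sum(file.path(out_dir, f)))),
    file.path(out_dir, "manifest.json"))

  invisible(list(cohort = cohort, visits = visits, panel = panel,
                 weights = weights, ensemble = ens, clock = clock,
                 cyclo = cyclo_tab, matched = matched, cor = cor_mat,
                 ladder = ladder, cca = cca, tests = tests, rao = rao,
                 redundancy = red, summary = summary, out_dir = out_dir))
}
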