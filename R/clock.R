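#' Fit the cytokine clock over an imputation ensemble and pool it
#'
#' Each completed panel is standardized and fitted with a subject-grouped
#' cross-validated weighted LASSO of age on marker log-levels; the M
#' per-imputation models are pooled into mean coefficients with standard
#' errors, per-marker selection frequencies (fraction of models in which
#' the marker kept a nonzero coefficient), and a per-visit clock value
#' (CyClo, in years) obtained by reducing the M predictions with the
#' pooling statistic.
#'
#' @param ensemble An [generate_ensemble()] result, or a plain list of
#'   completed visits x markers matrices.
#' @param ages Response: age in years per visit.
#' @param groups Subject identifier per visit (grouped CV folds).
#' @param w Balancing weights per visit.
#' @param K CV folds (default 10).
#' @param rule Penalty rule, `"1se"` (default) or `"min"`.
#' @param pool Pooling statistic for the per-visit prediction: `"median"`
#'   (default) or `"mean"`.
#' @param seed Seed controlling fold randomization per imputation.
#' @return A list of class `pooled_clock`: `mean_beta`, `se_beta`,
#'   `selection_frequency`, `lambda` (per imputation), per-visit `cyclo`,
#'   the full `beta` matrix (markers x M) and `predictions` (visits x M).
#' @export
fit_clock_ensemble <- function(ensemble, ages, groups, w = NULL,
                               K = 10L, rule = "1se",
                               pool = c("median", "mean"), seed = 1L) {
  pool <- match.arg(pool)
  panels <- if (inherits(ensemble, "imputed_ensemble")) ensemble$panels
            else ensemble
  M <- length(panels)
  seeds <- derive_seeds(seed, M, tag = 11L)
  p <- ncol(panels[[1]])
  beta <- matrix(NA_real_, p, M, dimnames = list(colnames(panels[[1]]), NULL))
  lambda <- numeric(M)
  pred <- matrix(NA_real_, nrow(panels[[1]]), M)
  for (m in seq_len(M)) {
    std <- standardize_columns(panels[[m]])
    sel <- grouped_cv_select_lambda(std$x, ages, groups, w, K = K,
                                    rule = rule, seed = seeds[m])
    fit <- lasso_fit(std$x, ages, sel$lambda_sel, w)
    beta[, m] <- fit$coefficients
    lambda[m] <- sel$lambda_sel
    pred[, m] <- predict(fit, std$x)
  }
  cyclo <- apply(pred, 1, if (pool == "median") stats::median else mean)
  structure(list(
    mean_beta = rowMeans(beta),
    se_beta = if (M > 1) apply(beta, 1, sd) / sqrt(M)
              else setNames(numeric(p), rownames(beta)),
    selection_frequency = rowMeans(beta != 0),
    lambda = lambda, beta = beta, predictions = pred,
    cyclo = setNames(cyclo, rownames(panels[[1]])),
    pool = pool, rule = rule, K = K, seed = seed
  ), class = "pooled_clock")
}

#' @export
print.pooled_clock <- function(x, ...) {
  cat(sprintf(
    "Pooled cytokine clock: %d markers, M = %d imputations, pool = %s\n",
    length(x$mean_beta), ncol(x$beta), x$pool))
  sel <- sort(x$selection_frequency, decreasing = TRUE)
  cat("Selection frequency (top 10):\n")
  print(round(head(sel, 10), 3))
  invisible(x)
}

#' Propagate clock values to nearby visits of the same subject
#'
#' A visit without a measured clock value borrows it from the same
#' subject's nearest-in-time measured visit within `max_gap` years: the
#' assigned value is `cyclo_source + (t_target - t_source)`, i.e. the
#' source prediction shifted by the elapsed time (a 2019 target served by
#' a 2020 source gets the 2020 value minus one year).  Ties in distance
#' break toward the earlier source visit.  Visits with no donor in range
#' stay unassigned.
#'
#' @param cyclo Named or positional vector of clock values per visit
#'   (`NA` where not measured), aligned to `visits` rows.
#' @param visits Visit table with `subject_id` and `visit_time`.
#' @param max_gap Propagation range in years (> 0; default 3).
#' @return Data frame with per-visit `cyclo`, `source`
#'   (`"measured"`/`"propagated"`/`NA`) and signed `gap` in years
#'   (target minus source time; 0 for measured entries).
#' @export
propagate_cyclo <- function(cyclo, visits, max_gap = 3) {
  if (max_gap <= 0) stop("max_gap must be positive")
  n <- nrow(visits)
  stopifnot(length(cyclo) == n)
  out <- data.frame(visit_id = visits$visit_id,
                    subject_id = visits$subject_id,
                    cyclo = as.numeric(cyclo),
                    source = ifelse(is.na(cyclo), NA_character_, "measured"),
                    gap = ifelse(is.na(cyclo), NA_real_, 0),
                    stringsAsFactors = FALSE)
  for (s in unique(visits$subject_id[is.na(cyclo)])) {
    rows <- which(visits$subject_id == s)
    meas <- rows[!is.na(cyclo[rows])]
    if (!length(meas)) next
    for (i in rows[is.na(cyclo[rows])]) {
      dt <- visits$visit_time[i] - visits$visit_time[meas]
      ok <- abs(dt) <= max_gap
      if (!any(ok)) next
      cand <- meas[ok]; dtc <- dt[ok]
      pick <- order(abs(dtc), visits$visit_time[cand])[1]
      out$cyclo[i] <- cyclo[cand[pick]] + dtc[pick]
      out$source[i] <- "propagated"
      out$gap[i] <- dtc[pick]
    }
  }
  out
}
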