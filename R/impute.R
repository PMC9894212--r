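#' Specification of the weighted-PMM imputation ensemble
#'
#' @param n_imputations Number of completed panels M (>= 1); the study
#'   design runs 500, desk-scale analyses typically 50.
#' @param n_sweeps Chained-equation sweeps per imputation (default 5).
#' @param n_donors Donor pool size k for predictive mean matching
#'   (default 5).
#' @param seed Integer master seed; each imputation runs on its own
#'   substream.
#' @return A list of class `impute_spec`.
#' @export
impute_spec <- function(n_imputations = 500L, n_sweeps = 5L,
                        n_donors = 5L, seed = 1L) {
  if (n_imputations < 1L) stop("n_imputations must be >= 1")
  if (n_donors < 1L) stop("n_donors must be >= 1")
  if (n_sweeps < 1L) stop("n_sweeps must be >= 1")
  structure(list(n_imputations = as.integer(n_imputations),
                 n_sweeps = as.integer(n_sweeps),
                 n_donors = as.integer(n_donors),
                 seed = as.integer(seed)),
            class = "impute_spec")
}

# Weighted least squares with a ridge fallback for singular systems.
# Returns the point estimate, a perturbed coefficient draw from the
# estimated sampling distribution N(beta_hat, sigma2 (X'WX)^-1), and a
# flag recording whether the fallback was taken.
wls_draw <- function(X, y, w) {
  XtW <- t(X * w)
  A <- XtW %*% X
  b <- XtW %*% y
  ridge <- FALSE
  R <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(R)) {
    ridge <- TRUE
    A <- A + diag(1e-8 * mean(diag(A)) + 1e-12, ncol(A))
    R <- chol(A)
  }
  beta <- backsolve(R, forwardsolve(t(R), b))
  res <- y - drop(X %*% beta)
  df <- length(y) - ncol(X)
  sigma2 <- if (df > 0) sum(w * res^2) / df else 0
  pert <- beta
  if (sigma2 > 0) {
    z <- rnorm(ncol(X))
    pert <- beta + sqrt(sigma2) * backsolve(R, z)
  }
  list(beta = drop(beta), pert = drop(pert), ridge = ridge)
}

# PMM donor matching: for each missing-row prediction, pick uniformly at
# random among the k observed rows with nearest predicted value (ties
# among equidistant donors broken uniformly via a random jitter on the
# ranking only).  The k nearest neighbours of a value lie within k sorted
# positions of its insertion point, so only a window of 2k candidates
# around it needs ranking.
pmm_match <- function(pred_obs, obs_values, pred_mis, k) {
  n <- length(pred_obs)
  k <- min(k, n)
  ord <- order(pred_obs)
  po <- pred_obs[ord]
  ov <- obs_values[ord]
  m <- length(pred_mis)
  win <- min(2L * k, n)
  lo <- pmax(pmin(findInterval(pred_mis, po) - k + 1L, n - win + 1L), 1L)
  idx <- rep(lo, each = win) + seq_len(win) - 1L       # m x win candidates
  D <- abs(matrix(po[idx], win, m) - rep(pred_mis, each = win))
  out <- numeric(m)
  for (r in seq_len(m)) {
    o <- order(D[, r], runif(win))
    out[r] <- ov[lo[r] + o[sample.int(k, 1L)] - 1L]
  }
  out
}

#' One chained-equation sweep set with weighted predictive mean matching
#'
#' Missing entries are initialised by a weighted draw from the observed
#' values of the same marker.  Then, for each sweep and each incomplete
#' marker in turn: a weighted least-squares regression of the observed
#' target on all other (current) marker values plus sex is fitted with
#' the balancing weights as observation weights; coefficients are
#' perturbed by a draw from their estimated sampling distribution;
#' predictions are formed for observed rows (point estimate) and missing
#' rows (perturbed draw); and each missing entry receives the observed
#' value of one of the `k` donors with nearest predicted value.  Every
#' imputed value is therefore a member of the marker's observed support.
#'
#' @param panel Visits x markers log-scale matrix with `NA` for missing.
#' @param sex Per-visit sex code, used as an always-complete predictor.
#' @param weights Per-visit balancing weights (a `balancing_weights`
#'   object or a positive numeric vector).
#' @param spec An [impute_spec()] (supplies sweeps and donor count).
#' @param seed Seed for this chain.
#' @return A completed matrix.
#' @export
weighted_pmm_impute_once <- function(panel, sex, weights,
                                     spec = impute_spec(), seed = spec$seed) {
  w <- if (inherits(weights, "balancing_weights")) weights$w else weights
  stopifnot(length(w) == nrow(panel), all(w > 0),
            length(sex) == nrow(panel))
  miss <- is.na(panel)
  if (!any(miss)) return(panel)
  k <- spec$n_donors
  if (any(colSums(!miss) < k))
    stop("every marker needs at least k observed entries")
  set.seed(seed)

  filled <- panel
  for (j in which(colSums(miss) > 0)) {
    obs <- !miss[, j]
    filled[!obs, j] <- sample(panel[obs, j], sum(!obs), replace = TRUE,
                              prob = w[obs])
  }
  for (sweep in seq_len(spec$n_sweeps)) {
    for (j in which(colSums(miss) > 0)) {
      obs <- !miss[, j]
      X <- cbind(1, filled[, -j, drop = FALSE], sex)
      fit <- wls_draw(X[obs, , drop = FALSE], panel[obs, j], w[obs])
      pred_obs <- drop(X[obs, , drop = FALSE] %*% fit$beta)
      pred_mis <- drop(X[!obs, , drop = FALSE] %*% fit$pert)
      filled[!obs, j] <- pmm_match(pred_obs, panel[obs, j], pred_mis, k)
    }
  }
  filled
}

#' Generate an ensemble of completed cytokine panels
#'
#' Runs `M` independent chained-equation imputations on distinct
#' substreams of the master seed.
#'
#' @inheritParams weighted_pmm_impute_once
#' @param spec An [impute_spec()].
#' @return A list of class `imputed_ensemble`: `panels` (list of M
#'   completed matrices) and `provenance` (seeds, sweeps, donors).
#' @export
generate_ensemble <- function(panel, sex, weights, spec = impute_spec()) {
  seeds <- derive_seeds(spec$seed, spec$n_imputations, tag = 3L)
  panels <- lapply(seeds, function(s)
    weighted_pmm_impute_once(panel, sex, weights, spec, seed = s))
  structure(list(panels = panels,
                 provenance = list(seed = spec$seed, substream_seeds = seeds,
                                   n_sweeps = spec$n_sweeps,
                                   n_donors = spec$n_donors)),
            class = "imputed_ensemble")
}

#' @export
print.imputed_ensemble <- function(x, ...) {
  cat(sprintf("Imputed ensemble: M = %d panels of %d x %d\n",
              length(x$panels), nrow(x$panels[[1]]), ncol(x$panels[[1]])))
  invisible(x)
}
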