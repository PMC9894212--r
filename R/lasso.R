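#' Center and scale the columns of a predictor matrix
#'
#' Columns are centered to mean 0 and scaled to sd 1 (divisor n - 1), and
#' the transform is stored so it can be re-applied to new data at
#' prediction time.  Standardizing in advance makes the penalized
#' coefficients comparable across markers.
#'
#' @param x Numeric matrix.
#' @return List with the standardized matrix `x`, and the `centers` and
#'   `scales` used.
#' @export
standardize_columns <- function(x) {
  centers <- colMeans(x)
  scales <- apply(x, 2, sd)
  zero <- which(scales <= 0 | !is.finite(scales))
  if (length(zero))
    stop("zero-variance column: ", paste(colnames(x)[zero], collapse = ", "))
  list(x = sweep(sweep(x, 2, centers), 2, scales, "/"),
       centers = centers, scales = scales)
}

#' Apply a stored standardization transform
#'
#' @param x New matrix with the same columns.
#' @param std A list with `centers` and `scales` from
#'   [standardize_columns()].
#' @return Standardized matrix.
#' @export
apply_standardization <- function(x, std) {
  sweep(sweep(x, 2, std$centers), 2, std$scales, "/")
}

normalize_weights <- function(w, n) {
  if (inherits(w, "balancing_weights")) w <- w$w
  if (is.null(w)) w <- rep(1, n)
  stopifnot(length(w) == n, all(w > 0))
  w / mean(w)
}

#' Smallest penalty that zeroes every LASSO coefficient
#'
#' `max_j |sum_i w_i x_ij (y_i - ybar_w)| / sum_i w_i` for weights
#' normalized to mean one.
#'
#' @param x Standardized predictor matrix.
#' @param y Response.
#' @param w Observation weights (default unit).
#' @return The scalar `lambda_max`.
#' @export
lambda_max <- function(x, y, w = NULL) {
  w <- normalize_weights(w, length(y))
  yc <- y - weighted.mean(y, w)
  max(abs(drop(crossprod(x, w * yc))) / sum(w))
}

default_lambda_grid <- function(lmax, n_lambda = 100L, min_ratio = 1e-3) {
  if (lmax <= 0) lmax <- 1e-3
  exp(seq(log(lmax), log(lmax * min_ratio), length.out = n_lambda))
}

#' Weighted LASSO fit by cyclic coordinate descent
#'
#' Minimizes `(1 / (2 sum w)) sum_i w_i (y_i - b0 - x_i b)^2 +
#' lambda sum_j |b_j|` with an unpenalized intercept, by cyclic
#' coordinate descent with soft-thresholding.  `lambda` may be a
#' decreasing grid, in which case the solution path is computed with
#' warm starts.
#'
#' @param x Standardized predictor matrix.
#' @param y Response (years of age in the clock application).
#' @param lambda Penalty (scalar or decreasing grid).
#' @param w Observation weights; normalized to mean one before fitting so
#'   the penalty scale is comparable across cohorts.
#' @param tol Convergence tolerance on the maximum coefficient change
#'   (default 1e-7).
#' @param maxit Maximum coordinate-descent sweeps per lambda.
#' @return For scalar `lambda`, a list of class `clock_model` with
#'   `intercept`, `coefficients`, `lambda`; for a grid, the same with
#'   matrix `coefficients` (markers x lambdas).
#' @export
lasso_fit <- function(x, y, lambda, w = NULL, tol = 1e-7, maxit = 1e5) {
  if (any(lambda < 0)) stop("lambda must be nonnegative")
  if (is.unsorted(rev(lambda))) stop("lambda grid must be decreasing")
  w <- normalize_weights(w, length(y))
  fit <- lasso_cd_path(as.matrix(x), as.numeric(y), w,
                       as.numeric(lambda), tol, as.integer(maxit))
  rownames(fit$beta) <- colnames(x)
  out <- list(intercept = fit$beta0, coefficients = fit$beta,
              lambda = lambda, iters = fit$iters)
  if (length(lambda) == 1L) {
    out$intercept <- fit$beta0[1]
    out$coefficients <- setNames(fit$beta[, 1], colnames(x))
  }
  structure(out, class = "clock_model")
}

#' Objective value of the weighted LASSO problem
#'
#' @param x,y,w As in [lasso_fit()] (weights normalized to mean one).
#' @param beta0,beta Candidate intercept and coefficients.
#' @param lambda Penalty.
#' @return The penalized objective value.
#' @export
lasso_objective <- function(x, y, beta0, beta, lambda, w = NULL) {
  w <- normalize_weights(w, length(y))
  r <- y - beta0 - drop(as.matrix(x) %*% beta)
  sum(w * r^2) / (2 * sum(w)) + lambda * sum(abs(beta))
}

#' Karush-Kuhn-Tucker residuals of a LASSO solution
#'
#' At an exact solution the weighted gradient `(1/W) sum_i w_i x_ij r_i`
#' equals `lambda * sign(beta_j)` for active coefficients and lies within
#' `[-lambda, lambda]` for zero ones.  Returns the worst violation.
#'
#' @inheritParams lasso_objective
#' @return Maximum KKT violation (0 at an exact optimum).
#' @export
lasso_kkt_residual <- function(x, y, beta0, beta, lambda, w = NULL) {
  w <- normalize_weights(w, length(y))
  r <- y - beta0 - drop(as.matrix(x) %*% beta)
  g <- drop(crossprod(as.matrix(x), w * r)) / sum(w)
  active <- beta != 0
  viol <- pmax(abs(g) - lambda, 0)
  viol[active] <- abs(g[active] - lambda * sign(beta[active]))
  max(c(viol, abs(sum(w * r) / sum(w))))
}

#' Predict from a single-lambda clock model
#'
#' @param object A `clock_model` fitted at one lambda.
#' @param x Standardized predictor matrix.
#' @param ... Unused.
#' @return Predicted response per row.
#' @export
predict.clock_model <- function(object, x, ...) {
  object$intercept + drop(as.matrix(x) %*% object$coefficients)
}

#' Subject-grouped cross-validation for the LASSO penalty
#'
#' Subjects (not visits) are randomized to K folds, so repeated measures
#' of one subject never straddle the train/test split.  Per lambda, the
#' weighted mean squared prediction error across held-out folds is
#' averaged, with a standard error across folds.  Rule `"1se"` picks the
#' largest lambda whose CV error is within one standard error of the
#' minimum; rule `"min"` picks the minimizer.
#'
#' @param x Standardized predictor matrix.
#' @param y Response.
#' @param groups Subject identifier per row.
#' @param w Observation weights.
#' @param K Number of folds (default 10).
#' @param rule `"1se"` (default) or `"min"`.
#' @param lambda Optional decreasing grid; by default 100 log-spaced
#'   values from `lambda_max` down to `1e-3 * lambda_max`.
#' @param seed Optional seed for the fold assignment.
#' @return List with `lambda_sel`, the `rule`, and the `cv_curve`
#'   (data frame: lambda, mean weighted MSE, its SE, nonzero count).
#' @export
grouped_cv_select_lambda <- function(x, y, groups, w = NULL, K = 10L,
                                     rule = c("1se", "min"), lambda = NULL,
                                     seed = NULL) {
  rule <- match.arg(rule)
  w <- normalize_weights(w, length(y))
  subj <- unique(groups)
  if (K > length(subj)) stop("K exceeds the number of distinct subjects")
  if (!is.null(seed)) set.seed(seed)
  fold_of_subj <- setNames(sample(rep_len(seq_len(K), length(subj))), subj)
  folds <- fold_of_subj[as.character(groups)]
  if (is.null(lambda)) lambda <- default_lambda_grid(lambda_max(x, y, w))

  mse <- matrix(NA_real_, K, length(lambda))
  for (k in seq_len(K)) {
    tr <- folds != k
    fit <- lasso_fit(x[tr, , drop = FALSE], y[tr], lambda, w[tr])
    pred <- matrix(fit$intercept, sum(!tr), length(lambda), byrow = TRUE) +
      x[!tr, , drop = FALSE] %*% fit$coefficients
    err <- (y[!tr] - pred)^2
    mse[k, ] <- colSums(w[!tr] * err) / sum(w[!tr])
  }
  cvm <- colMeans(mse)
  cvse <- apply(mse, 2, sd) / sqrt(K)
  i_min <- which.min(cvm)
  i_sel <- if (rule == "min") i_min else
    min(which(cvm <= cvm[i_min] + cvse[i_min]))  # grid is decreasing
  full <- lasso_fit(x, y, lambda, w)
  list(lambda_sel = lambda[i_sel], rule = rule,
       lambda_min = lambda[i_min], folds = folds,
       cv_curve = data.frame(lambda = lambda, cvm = cvm, cvse = cvse,
                             nonzero = colSums(full$coefficients != 0)))
}
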