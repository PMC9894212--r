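# Profiled ML machinery for the random-intercept model
#   y = X beta + Z u + e,  u ~ N(0, sigma_u^2 I),  e ~ N(0, sigma^2 I)
# with Z the subject indicator matrix.  For a given variance ratio
# theta = sigma_u^2 / sigma^2 the GLS solution and the residual variance
# are available in closed form through per-subject rank-one downdates
# (V_i^{-1} = I - theta/(1 + theta n_i) J), so the likelihood only needs
# a one-dimensional search over theta.

lmm_profile_parts <- function(y, X, subj_index) {
  parts <- lapply(subj_index, function(idx) {
    Xi <- X[idx, , drop = FALSE]
    yi <- y[idx]
    list(n = length(idx),
         XtX = crossprod(Xi), Xty = crossprod(Xi, yi),
         yty = sum(yi^2), X1 = colSums(Xi), y1 = sum(yi))
  })
  parts
}

lmm_profile_loglik <- function(theta, parts, n, pcol, want_fit = FALSE) {
  A <- matrix(0, pcol, pcol); b <- numeric(pcol)
  q <- 0; logdet <- 0
  for (pt in parts) {
    ci <- theta / (1 + theta * pt$n)
    A <- A + pt$XtX - ci * tcrossprod(pt$X1)
    b <- b + drop(pt$Xty) - ci * pt$X1 * pt$y1
    q <- q + pt$yty - ci * pt$y1^2
    logdet <- logdet + log1p(theta * pt$n)
  }
  R <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(R)) return(if (want_fit) NULL else -Inf)
  beta <- backsolve(R, forwardsolve(t(R), b))
  rss <- max(q - sum(b * beta), .Machine$double.eps)
  sigma2 <- rss / n
  ll <- -n / 2 * log(2 * pi * sigma2) - logdet / 2 - n / 2
  if (!want_fit) return(ll)
  Ainv <- chol2inv(R)
  list(loglik = ll, beta = drop(beta), sigma2 = sigma2,
       vcov = sigma2 * Ainv, logdet = logdet)
}

#' Fit a random-intercept linear mixed model by maximum likelihood
#'
#' Maximum (not restricted) likelihood of
#' `y = X beta + Z u + e` with a per-subject random intercept.  The fixed
#' effects and the residual variance are profiled out analytically given
#' the variance ratio `theta = sigma_u^2 / sigma^2`; `theta` is found by
#' a coarse log-grid bracket followed by golden-section refinement on
#' `[0, 1e6]` (tolerance 1e-9).  ML is used throughout so that AIC/BIC
#' and likelihood-ratio tests across fixed-effect structures are valid.
#'
#' @param y Response vector.
#' @param X Fixed-effect design matrix (full column rank; include the
#'   intercept column).
#' @param subjects Grouping factor/identifier per row (>= 2 subjects).
#' @return A list of class `lmm_fit`: `beta`, `se`, `z`, `p` (Wald),
#'   `sigma2_u`, `sigma2`, `theta`, `loglik`, `kparams`
#'   (fixed coefficients + 2 variance parameters), `n`, `AIC`, `BIC`.
#' @export
fit_random_intercept <- function(y, X, subjects) {
  X <- as.matrix(X)
  n <- length(y)
  stopifnot(nrow(X) == n, length(subjects) == n)
  if (length(unique(subjects)) < 2L) stop("need at least 2 subjects")
  if (qr(X)$rank < ncol(X))
    stop("fixed-effect design is rank deficient (collinear columns)")
  subj_index <- split(seq_len(n), as.character(subjects))
  parts <- lmm_profile_parts(y, X, subj_index)
  obj <- function(th) lmm_profile_loglik(th, parts, n, ncol(X))

  grid <- c(0, 10^seq(-4, 6, by = 0.5))
  ll_grid <- vapply(grid, obj, numeric(1))
  if (all(!is.finite(ll_grid))) stop("non-finite likelihood over theta grid")
  i <- which.max(ll_grid)
  lower <- grid[max(i - 1L, 1L)]
  upper <- min(grid[min(i + 1L, length(grid))], 1e6)
  opt <- optimize(obj, c(lower, upper), maximum = TRUE, tol = 1e-9)
  theta <- if (opt$objective >= ll_grid[i]) opt$maximum else grid[i]
  if (obj(0) >= obj(theta)) theta <- 0

  fit <- lmm_profile_loglik(theta, parts, n, ncol(X), want_fit = TRUE)
  se <- sqrt(diag(fit$vcov))
  z <- fit$beta / se
  k <- ncol(X) + 2L
  structure(list(
    beta = setNames(fit$beta, colnames(X)), se = setNames(se, colnames(X)),
    z = z, p = 2 * pnorm(abs(z), lower.tail = FALSE),
    sigma2_u = theta * fit$sigma2, sigma2 = fit$sigma2, theta = theta,
    loglik = fit$loglik, kparams = k, n = n,
    AIC = -2 * fit$loglik + 2 * k,
    BIC = -2 * fit$loglik + k * log(n),
    terms = colnames(X)
  ), class = "lmm_fit")
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat(sprintf(
    "Random-intercept LMM (ML): n = %d, logLik = %.3f, AIC = %.1f, BIC = %.1f\n",
    x$n, x$loglik, x$AIC, x$BIC))
  print(data.frame(beta = x$beta, se = x$se, z = x$z, p = signif(x$p, 3)))
  cat(sprintf("sigma2_u = %.4g, sigma2 = %.4g\n", x$sigma2_u, x$sigma2))
  invisible(x)
}

#' Information criteria of a fitted mixed model
#'
#' `AIC = -2 logLik + 2 k` and `BIC = -2 logLik + k log(n)` with `k`
#' counting the fixed coefficients plus the two variance parameters.
#'
#' @param fit An `lmm_fit` (any list with `loglik`, `kparams`, `n` works).
#' @return Named vector with `AIC` and `BIC`.
#' @export
information_criteria <- function(fit) {
  c(AIC = -2 * fit$loglik + 2 * fit$kparams,
    BIC = -2 * fit$loglik + fit$kparams * log(fit$n))
}

#' Likelihood-ratio test between nested ML mixed-model fits
#'
#' @param reduced,full `lmm_fit` objects on the same rows, with the
#'   reduced fixed effects nested in the full ones.
#' @return Named vector: `chisq` (floored at 0), `df` (difference in
#'   fixed-effect counts), `p` (upper chi-squared tail).
#' @export
lrt_compare <- function(reduced, full) {
  if (reduced$n != full$n)
    stop("models were fitted on different row sets")
  if (!all(reduced$terms %in% full$terms))
    stop("designs are not nested")
  chisq <- max(0, 2 * (full$loglik - reduced$loglik))
  df <- length(full$terms) - length(reduced$terms)
  p <- if (df == 0) (if (chisq <= 1e-8) 1 else 0)
       else pchisq(chisq, df, lower.tail = FALSE)
  c(chisq = chisq, df = df, p = p)
}

stars_for <- function(p) {
  cut(p, c(-Inf, 0.001, 0.01, 0.05, Inf),
      labels = c("***", "**", "*", ""), right = TRUE)
}

#' Fit the four-model random-intercept ladder for GMV
#'
#' Fits `gmv_frac ~ 1`, `~ age`, `~ age + sex`, `~ age + sex + cyclo`,
#' each with a per-subject random intercept, on the common complete-case
#' row set; reports AIC/BIC, Wald significance stars per coefficient, and
#' the likelihood-ratio test between successive models.
#'
#' @param data Data frame with columns `gmv_frac`, `age`, `sex`, `cyclo`,
#'   `subject_id`.
#' @return A list of class `model_ladder`: `fits` (the four `lmm_fit`s),
#'   `table` (AIC/BIC and stars per model), `lrt` (successive tests),
#'   `best_aic`, `best_bic` (1-based model index).
#' @export
build_model_ladder <- function(data) {
  need <- c("gmv_frac", "age", "sex", "cyclo", "subject_id")
  stopifnot(all(need %in% names(data)))
  cc <- complete.cases(data[need])
  d <- data[cc, need]
  y <- d$gmv_frac
  designs <- list(
    null = cbind(`(Intercept)` = rep(1, nrow(d))),
    age = cbind(`(Intercept)` = 1, age = d$age),
    age_sex = cbind(`(Intercept)` = 1, age = d$age, sex = d$sex),
    age_sex_cyclo = cbind(`(Intercept)` = 1, age = d$age, sex = d$sex,
                          cyclo = d$cyclo)
  )
  fits <- lapply(designs, function(X) fit_random_intercept(y, X, d$subject_id))
  ic <- t(vapply(fits, information_criteria, numeric(2)))
  lrt <- t(vapply(seq_len(3), function(i)
    lrt_compare(fits[[i]], fits[[i + 1]]), numeric(3)))
  rownames(lrt) <- c("m2_vs_m1", "m3_vs_m2", "m4_vs_m3")
  stars <- lapply(fits, function(f) setNames(as.character(stars_for(f$p)),
                                             f$terms))
  structure(list(fits = fits, table = ic, lrt = lrt, stars = stars,
                 n = nrow(d),
                 best_aic = unname(which.min(ic[, "AIC"])),
                 best_bic = unname(which.min(ic[, "BIC"]))),
            class = "model_ladder")
}

#' @export
print.model_ladder <- function(x, ...) {
  cat(sprintf("Model ladder on %d visits (random intercept per subject)\n",
              x$n))
  tab <- data.frame(model = rownames(x$table), round(x$table, 1))
  print(tab, row.names = FALSE)
  cat(sprintf("Best AIC: model %d; best BIC: model %d\n",
              x$best_aic, x$best_bic))
  cat("Successive likelihood-ratio tests:\n")
  print(round(x$lrt, 4))
  invisible(x)
}
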