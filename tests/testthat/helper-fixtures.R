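# Shared in-code fixtures and independent oracles for the test suite.

# Small cohort used by several module tests.
small_cohort <- function(n_subjects = 120, seed = 11, ...) {
  generate_cohort(sim_config(n_subjects = n_subjects, seed = seed, ...))
}

# Independent LASSO oracle: minimize the identical objective by smooth
# bound-constrained optimization over the split beta = beta+ - beta-
# (the L1 term becomes linear), with an unpenalized intercept.
oracle_lasso <- function(x, y, lambda, w = NULL) {
  x <- as.matrix(x)
  n <- nrow(x); p <- ncol(x)
  if (is.null(w)) w <- rep(1, n)
  w <- w / mean(w)
  W <- sum(w)
  fn <- function(par) {
    b0 <- par[1]; bp <- par[2:(p + 1)]; bm <- par[(p + 2):(2 * p + 1)]
    r <- y - b0 - drop(x %*% (bp - bm))
    sum(w * r^2) / (2 * W) + lambda * sum(bp + bm)
  }
  gr <- function(par) {
    b0 <- par[1]; bp <- par[2:(p + 1)]; bm <- par[(p + 2):(2 * p + 1)]
    r <- y - b0 - drop(x %*% (bp - bm))
    g <- -drop(crossprod(x, w * r)) / W
    c(-sum(w * r) / W, g + lambda, -g + lambda)
  }
  fit <- optim(rep(0, 2 * p + 1), fn, gr, method = "L-BFGS-B",
               lower = c(-Inf, rep(0, 2 * p)),
               control = list(maxit = 2000, factr = 10))
  list(value = fit$value,
       beta0 = fit$par[1],
       beta = fit$par[2:(p + 1)] - fit$par[(p + 2):(2 * p + 1)])
}

# Independent first-canonical-correlation oracle by alternating least
# squares: regress the current Y-side variate on X, then the X-side
# variate on Y, until the correlation stabilizes.
oracle_cca_rho1 <- function(X, Y, iters = 2000, tol = 1e-13) {
  X <- scale(as.matrix(X)); Y <- scale(as.matrix(Y))
  v <- Y[, 1]
  rho_old <- 0
  for (i in seq_len(iters)) {
    u <- drop(X %*% qr.solve(X, v))
    v <- drop(Y %*% qr.solve(Y, u))
    rho <- abs(cor(u, v))
    if (abs(rho - rho_old) < tol) break
    rho_old <- rho
  }
  abs(cor(u, v))
}

# Brute-force multivariate-normal log-likelihood of a random-intercept
# model at given parameters, building the full n x n covariance.
oracle_lmm_loglik <- function(y, X, subjects, beta, sigma2_u, sigma2) {
  n <- length(y)
  Z <- outer(as.character(subjects), unique(as.character(subjects)), "==")
  Sigma <- sigma2 * diag(n) + sigma2_u * tcrossprod(Z)
  r <- y - drop(as.matrix(X) %*% beta)
  ch <- chol(Sigma)
  -0.5 * (n * log(2 * pi) + 2 * sum(log(diag(ch))) +
            sum(backsolve(ch, r, transpose = TRUE)^2))
}

# Simulate a random-intercept dataset with known parameters.
simulate_lmm <- function(n_subj, n_per, beta, sigma_u, sigma, seed) {
  set.seed(seed)
  subj <- rep(seq_len(n_subj), each = n_per)
  x <- rnorm(n_subj * n_per)
  X <- cbind(1, x)
  u <- rnorm(n_subj, 0, sigma_u)
  y <- drop(X %*% beta) + u[subj] + rnorm(length(subj), 0, sigma)
  list(y = y, X = X, subjects = subj)
}
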