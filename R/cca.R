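sym_inv_sqrt <- function(R, label, floor = 1e-10) {
  e <- eigen(R, symmetric = TRUE)
  if (any(e$values < floor))
    stop("rank-deficient (near-collinear) variable set: ", label)
  e$vectors %*% diag(1 / sqrt(e$values), length(e$values)) %*% t(e$vectors)
}

#' Canonical correlation analysis between two variable sets
#'
#' Columns of both sets are standardized; the canonical weights are
#' obtained from the singular value decomposition of
#' `Rxx^{-1/2} Rxy Ryy^{-1/2}`, the singular values being the canonical
#' correlations.  Variates have unit sample variance and within-set
#' variates of different order are uncorrelated.  Signs are fixed so the
#' largest-magnitude X-side loading of each function is positive, making
#' weights and loadings reproducible.
#'
#' @param X n x p matrix/data frame (e.g. age, clock, sex).
#' @param Y n x q matrix/data frame (e.g. the 7 network volume fractions).
#' @return A list of class `cca_result`: `xweights` (p x s), `yweights`
#'   (q x s) on standardized variables, `cor` (canonical correlations,
#'   descending), `roots` (their squares), scores `U`, `V` (n x s), the
#'   loadings `xloadings`, `yloadings`, and `n`, `p`, `q`,
#'   `s = min(p, q)`.
#' @export
fit_cca <- function(X, Y) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X); p <- ncol(X); q <- ncol(Y)
  stopifnot(nrow(Y) == n)
  if (n <= p + q) stop("need more rows than total variables")
  Xs <- standardize_columns(X)$x
  Ys <- standardize_columns(Y)$x
  Rxx <- cor(Xs); Ryy <- cor(Ys); Rxy <- cor(Xs, Ys)
  Kx <- sym_inv_sqrt(Rxx, "X"); Ky <- sym_inv_sqrt(Ryy, "Y")
  sv <- svd(Kx %*% Rxy %*% Ky)
  s <- min(p, q)
  a <- Kx %*% sv$u[, seq_len(s), drop = FALSE]
  b <- Ky %*% sv$v[, seq_len(s), drop = FALSE]
  rho <- pmin(pmax(sv$d[seq_len(s)], 0), 1)
  U <- Xs %*% a
  V <- Ys %*% b
  xload <- cor(Xs, U)
  for (k in seq_len(s)) {              # sign convention
    j <- which.max(abs(xload[, k]))
    if (xload[j, k] < 0) {
      a[, k] <- -a[, k]; b[, k] <- -b[, k]
      U[, k] <- -U[, k]; V[, k] <- -V[, k]
    }
  }
  xload <- cor(Xs, U); yload <- cor(Ys, V)
  dimnames(a) <- list(colnames(X), paste0("F", seq_len(s)))
  dimnames(b) <- list(colnames(Y), paste0("F", seq_len(s)))
  dimnames(xload) <- dimnames(a); dimnames(yload) <- dimnames(b)
  structure(list(xweights = a, yweights = b, cor = rho, roots = rho^2,
                 U = U, V = V, xloadings = xload, yloadings = yload,
                 n = n, p = p, q = q, s = s),
            class = "cca_result")
}

#' Canonical loadings (structure correlations)
#'
#' Correlation of each observed variable with the canonical variates of
#' its own set; interpretable like factor loadings.
#'
#' @param result A `cca_result`.
#' @param X,Y Optional data on which to compute the correlations;
#'   defaults to the stored variate scores versus the training data
#'   loadings held in the result.
#' @return List with matrices `x` (p x s) and `y` (q x s).
#' @export
canonical_loadings <- function(result, X = NULL, Y = NULL) {
  if (is.null(X) && is.null(Y))
    return(list(x = result$xloadings, y = result$yloadings))
  list(x = cor(as.matrix(X), result$U), y = cor(as.matrix(Y), result$V))
}

#' Degrees of freedom of the k-th sequential Bartlett test
#'
#' `(p - k + 1) (q - k + 1)`; with p = 3 aging factors and q = 7 networks
#' this gives 21, 12 and 5 for the three canonical functions.
#'
#' @param p,q Set sizes.
#' @param k Starting dimension, `1 <= k <= min(p, q)`.
#' @return Integer degrees of freedom.
#' @export
bartlett_df <- function(p, q, k) {
  if (k < 1 || k > min(p, q)) stop("k out of range")
  as.integer((p - k + 1) * (q - k + 1))
}

#' Maximum number of canonical functions
#'
#' @param p,q Set sizes (>= 1).
#' @return `min(p, q)`.
#' @export
max_functions <- function(p, q) {
  stopifnot(p >= 1, q >= 1)
  min(p, q)
}

#' Shared variance (canonical root) of a canonical correlation
#'
#' @param rho Canonical correlation in `[0, 1]`.
#' @return `rho^2`.
#' @export
shared_variance <- function(rho) {
  if (any(rho < 0 | rho > 1)) stop("rho must lie in [0, 1]")
  rho^2
}

#' Bartlett's sequential chi-squared tests of canonical dimensions
#'
#' Test k asks whether dimensions k..s are jointly null:
#' `Lambda_k = prod_{i >= k} (1 - rho_i^2)`,
#' `chisq_k = -(n - 1 - (p + q + 1)/2) log Lambda_k`, with
#' `df_k = (p - k + 1)(q - k + 1)`.
#'
#' @param rho Canonical correlations, descending, in `[0, 1)` (a value of
#'   1 yields an infinite statistic, reported with a warning).
#' @param n Number of complete rows entering the fit.
#' @param p,q Set sizes.
#' @return Data frame of class `dimension_tests` with `k`, `lambda`,
#'   `statistic`, `df`, `p_value`.
#' @export
bartlett_sequential_test <- function(rho, n, p, q) {
  s <- length(rho)
  if (is.unsorted(rev(rho))) stop("rho must be descending")
  if (n <= p + q) stop("n must exceed p + q")
  if (any(rho >= 1)) warning("a canonical correlation of 1 gives an infinite statistic")
  mult <- n - 1 - (p + q + 1) / 2
  out <- data.frame(k = seq_len(s))
  out$lambda <- rev(cumprod(rev(1 - rho^2)))
  out$statistic <- -mult * log(out$lambda)
  out$df <- vapply(out$k, function(k) bartlett_df(p, q, k), integer(1))
  out$p_value <- pchisq(out$statistic, out$df, lower.tail = FALSE)
  class(out) <- c("dimension_tests", class(out))
  out
}

#' Rao's F approximation for the sequential dimension tests
#'
#' For each starting dimension k with `p_k = p - k + 1`,
#' `q_k = q - k + 1`: `m = n - 1 - (p_k + q_k + 1)/2`,
#' `t = sqrt((p_k^2 q_k^2 - 4) / (p_k^2 + q_k^2 - 5))` (1 when the
#' denominator is nonpositive), `df1 = p_k q_k`,
#' `df2 = m t - p_k q_k / 2 + 1`, and
#' `F = ((1 - Lambda^{1/t}) / Lambda^{1/t}) (df2 / df1)`.
#' With `p_k = 1` this reduces to the exact F test of a squared multiple
#' correlation.
#'
#' @inheritParams bartlett_sequential_test
#' @return Data frame with `k`, `lambda`, `statistic` (F), `df1`, `df2`,
#'   `p_value`.
#' @export
rao_f_test <- function(rho, n, p, q) {
  s <- length(rho)
  if (is.unsorted(rev(rho))) stop("rho must be descending")
  if (n <= p + q) stop("n must exceed p + q")
  lambda <- rev(cumprod(rev(1 - rho^2)))
  out <- data.frame(k = seq_len(s), lambda = lambda, statistic = NA_real_,
                    df1 = NA_real_, df2 = NA_real_, p_value = NA_real_)
  for (k in seq_len(s)) {
    pk <- p - k + 1; qk <- q - k + 1
    m <- n - 1 - (pk + qk + 1) / 2
    tt <- if (pk^2 + qk^2 - 5 > 0) sqrt((pk^2 * qk^2 - 4) / (pk^2 + qk^2 - 5))
          else 1
    df1 <- pk * qk
    df2 <- m * tt - pk * qk / 2 + 1
    if (df2 <= 0) stop("denominator df nonpositive; a larger n is needed")
    lt <- lambda[k]^(1 / tt)
    Fk <- ((1 - lt) / lt) * (df2 / df1)
    out$statistic[k] <- Fk
    out$df1[k] <- df1; out$df2[k] <- df2
    out$p_value[k] <- pf(Fk, df1, df2, lower.tail = FALSE)
  }
  out
}

#' Redundancy coefficients of a canonical correlation analysis
#'
#' Per dimension, the redundancy of Y given X is the mean squared Y-side
#' loading times the canonical root (and symmetrically for X given Y);
#' totals are sums over dimensions.  Redundancy is asymmetric and reads
#' as the average fraction of one set's observed variance explained by
#' the other set's variate.
#'
#' @param result A `cca_result`.
#' @return List with per-dimension vectors `x_given_y`, `y_given_x` and
#'   scalars `total_x_given_y`, `total_y_given_x`.
#' @export
redundancy <- function(result) {
  xg <- colMeans(result$xloadings^2) * result$roots
  yg <- colMeans(result$yloadings^2) * result$roots
  list(x_given_y = xg, y_given_x = yg,
       total_x_given_y = sum(xg), total_y_given_x = sum(yg))
}

#' @export
print.cca_result <- function(x, digits = 3, ...) {
  cat(sprintf("Canonical correlation analysis: n = %d, p = %d, q = %d\n",
              x$n, x$p, x$q))
  cat("Canonical correlations:", paste(round(x$cor, digits), collapse = ", "),
      "\nCanonical roots:      ",
      paste(round(x$roots, digits), collapse = ", "), "\n")
  invisible(x)
}

#' Per-function report of a canonical correlation analysis
#'
#' A text table per canonical function listing weights and loadings of
#' both sets, the canonical correlation and root, and the sequential
#' Bartlett test.
#'
#' @param result A `cca_result`.
#' @param tests Optional `dimension_tests` from
#'   [bartlett_sequential_test()].
#' @return Invisibly, a list of per-function data frames.
#' @export
cca_report <- function(result, tests = NULL) {
  if (is.null(tests))
    tests <- bartlett_sequential_test(result$cor, result$n, result$p,
                                      result$q)
  reports <- lapply(seq_len(result$s), function(k) {
    data.frame(
      variable = c(rownames(result$xweights), rownames(result$yweights)),
      set = rep(c("X", "Y"), c(result$p, result$q)),
      weight = c(result$xweights[, k], result$yweights[, k]),
      loading = c(result$xloadings[, k], result$yloadings[, k]))
  })
  for (k in seq_len(result$s)) {
    cat(sprintf(
      "\nFunction %d: rho = %.3f, rho^2 = %.3f, df = %d, p = %.3g\n",
      k, result$cor[k], result$roots[k], tests$df[k], tests$p_value[k]))
    print(transform(reports[[k]], weight = round(weight, 3),
                    loading = round(loading, 3)), row.names = FALSE)
  }
  invisible(reports)
}
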