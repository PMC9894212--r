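test_that("canonical correlation reduces to known special cases", {
  set.seed(1)
  x <- rnorm(40); y <- 0.6 * x + rnorm(40)
  # p = q = 1: the absolute Pearson correlation
  cc <- fit_cca(cbind(x = x), cbind(y = y))
  expect_equal(cc$cor[1], abs(cor(x, y)), tolerance = 1e-12)
  # q = 1, p = 3: the multiple correlation coefficient
  X <- matrix(rnorm(150), 50, 3)
  yv <- drop(X %*% c(1, -0.5, 0.2)) + rnorm(50)
  cc2 <- fit_cca(X, cbind(y = yv))
  R2 <- summary(lm(yv ~ X))$r.squared
  expect_equal(cc2$cor[1]^2, R2, tolerance = 1e-10)
  expect_equal(cc2$s, 1)
})

test_that("canonical correlations match independent oracles", {
  set.seed(2)
  n <- 80
  X <- matrix(rnorm(n * 3), n, 3)
  Y <- matrix(rnorm(n * 7), n, 7)
  Y[, 1] <- Y[, 1] + X[, 1]
  cc <- fit_cca(X, Y)
  expect_equal(cc$s, 3)
  # base-R cancor as a fully independent implementation
  ref <- cancor(scale(X), scale(Y))
  expect_equal(cc$cor, ref$cor[1:3], tolerance = 1e-8)
  # alternating-least-squares oracle for the leading correlation
  expect_equal(cc$cor[1], oracle_cca_rho1(X, Y), tolerance = 1e-6)
})

test_that("variates are unit-variance, orthogonal, and sign-stable", {
  set.seed(3)
  X <- matrix(rnorm(200 * 3), 200, 3)
  Y <- matrix(rnorm(200 * 5), 200, 5)
  cc <- fit_cca(X, Y)
  expect_equal(apply(cc$U, 2, var), rep(1, 3), tolerance = 1e-8)
  expect_equal(apply(cc$V, 2, var), rep(1, 3), tolerance = 1e-8)
  cu <- cor(cc$U); cv <- cor(cc$V)
  expect_lt(max(abs(cu[upper.tri(cu)])), 1e-8)
  expect_lt(max(abs(cv[upper.tri(cv)])), 1e-8)
  expect_lte(cc$cor[1], 1)
  expect_gte(min(cc$cor), 0)
  expect_true(all(diff(cc$cor) <= 1e-12))   # descending
  # the largest-magnitude X loading of every function is positive
  for (k in 1:3)
    expect_gt(cc$xloadings[which.max(abs(cc$xloadings[, k])), k], 0)
})

test_that("canonical correlations are invariant under within-set affine maps", {
  set.seed(4)
  X <- matrix(rnorm(60 * 3), 60, 3)
  Y <- matrix(rnorm(60 * 4), 60, 4)
  cc <- fit_cca(X, Y)
  A <- matrix(rnorm(9), 3) + 3 * diag(3)
  B <- matrix(rnorm(16), 4) + 3 * diag(4)
  cc2 <- fit_cca(X %*% A + 5, Y %*% B - 2)
  expect_equal(cc$cor, cc2$cor, tolerance = 1e-8)
  # rank deficiency is named
  expect_error(fit_cca(cbind(X, X[, 1]), Y), "near-collinear.*X")
})

test_that("loadings behave like structure correlations", {
  set.seed(5)
  x <- rnorm(30); Y <- matrix(rnorm(90), 30, 3)
  cc <- fit_cca(cbind(x = x), Y)
  expect_equal(abs(cc$xloadings[1, 1]), 1, tolerance = 1e-12)
  # orthonormal (centered) X: loadings coincide with weights
  Xc <- scale(matrix(rnorm(200 * 3), 200, 3), scale = FALSE)
  Xo <- qr.Q(qr(Xc)) * sqrt(199)
  cco <- fit_cca(Xo, matrix(rnorm(200 * 4), 200, 4))
  expect_equal(cco$xloadings, cco$xweights, tolerance = 1e-8)
  expect_true(all(abs(cc$yloadings) <= 1 + 1e-12))
  ld <- canonical_loadings(cc)
  expect_equal(ld$x, cc$xloadings)
})

test_that("Bartlett test dimensions and statistics follow the sequential formulas", {
  expect_equal(bartlett_df(3, 7, 1), 21L)
  expect_equal(bartlett_df(3, 7, 2), 12L)
  expect_equal(bartlett_df(3, 7, 3), 5L)
  expect_equal(bartlett_df(1, 1, 1), 1L)
  expect_error(bartlett_df(3, 7, 4), "out of range")

  # hand-multiplied Wilks lambda for rho = (0.59, 0.38, 0.1)
  bt <- bartlett_sequential_test(c(0.59, 0.38, 0.1), n = 547, p = 3, q = 7)
  expect_equal(bt$lambda[1], 0.552188, tolerance = 1e-4)
  expect_equal(bt$statistic[1], -(547 - 1 - 11 / 2) * log(bt$lambda[1]),
               tolerance = 1e-10)
  expect_equal(bt$df, c(21L, 12L, 5L))
  expect_true(all(diff(bt$lambda) >= 0))

  # all-null case
  bt0 <- bartlett_sequential_test(c(0, 0), n = 100, p = 2, q = 5)
  expect_equal(bt0$lambda, c(1, 1))
  expect_equal(bt0$statistic, c(0, 0))
  expect_equal(bt0$p_value, c(1, 1))
  expect_warning(bartlett_sequential_test(c(1, 0), 50, 2, 3), "infinite")
})

test_that("Rao's F reduces to the classical regression F when p_k = 1", {
  set.seed(6)
  Y <- matrix(rnorm(120), 40, 3)
  x <- drop(Y %*% c(0.5, -0.3, 0)) + rnorm(40)
  cc <- fit_cca(cbind(x = x), Y)
  rao <- rao_f_test(cc$cor, n = 40, p = 1, q = 3)
  ref <- summary(lm(scale(x) ~ scale(Y)))
  expect_equal(rao$statistic[1], unname(ref$fstatistic[1]),
               tolerance = 1e-8)
  expect_equal(rao$df1[1], 3)
  expect_equal(rao$df2[1], 36)
  # large-n agreement with the Bartlett chi-squared p-values
  rho <- c(0.45, 0.3, 0.15)
  pb <- bartlett_sequential_test(rho, 1000, 3, 7)$p_value
  pr <- rao_f_test(rho, 1000, 3, 7)$p_value
  expect_lt(max(abs(pb - pr)), 0.01)
  # all-null case: F = 0, p = 1
  null_f <- rao_f_test(c(0, 0), n = 50, p = 2, q = 4)
  expect_equal(null_f$statistic, c(0, 0))
  expect_equal(null_f$p_value, c(1, 1))
})

test_that("redundancy coefficients are bounded by the roots and exact on identical sets", {
  set.seed(7)
  X <- matrix(rnorm(50 * 3), 50, 3)
  Y <- matrix(rnorm(50 * 4), 50, 4)
  cc <- fit_cca(X, Y)
  red <- redundancy(cc)
  expect_true(all(red$y_given_x <= cc$roots + 1e-12))
  expect_true(all(red$x_given_y <= cc$roots + 1e-12))
  # identical sets: all variance of Y is reproduced by X's variates
  ccI <- fit_cca(X, X + matrix(rnorm(150, 0, 1e-8), 50, 3))
  expect_equal(redundancy(ccI)$total_y_given_x, 1, tolerance = 1e-4)
  # zero correlation contributes zero redundancy
  expect_equal(unname(red$y_given_x * (cc$roots == 0)), rep(0, 3))
  expect_equal(shared_variance(0.59), 0.3481)
  expect_equal(round(shared_variance(c(0.59, 0.38, 0.1)), 2),
               c(0.35, 0.14, 0.01))
  expect_error(shared_variance(1.2), "\\[0, 1\\]")
  expect_equal(max_functions(3, 7), 3)
  expect_equal(max_functions(1, 5), 1)
  expect_equal(max_functions(4, 4), 4)
})

test_that("the age-dominated canonical function loads on the somatomotor analogue", {
  ch <- small_cohort(n_subjects = 300, seed = 71)
  vols <- normalize_to_tiv(ch$volumes)
  X <- cbind(age = ch$visits$age, cyclo = ch$truth$latent,
             sex = ch$visits$sex)
  Y <- as.matrix(vols[paste0(network_names, "_frac")])
  colnames(Y) <- network_names
  cc <- fit_cca(X, Y)
  k_age <- which.max(abs(cc$xloadings["age", ]))
  expect_equal(rownames(cc$yloadings)[which.max(abs(cc$yloadings[, k_age]))],
               "somatomotor")
})
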