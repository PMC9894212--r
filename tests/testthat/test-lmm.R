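test_that("the profiled likelihood at theta = 0 is the OLS Gaussian likelihood", {
  sim <- simulate_lmm(20, 3, beta = c(1, 2), sigma_u = 1, sigma = 1,
                      seed = 1)
  parts <- cytoclock:::lmm_profile_parts(sim$y, sim$X,
                                         split(seq_along(sim$y),
                                               sim$subjects))
  ll0 <- cytoclock:::lmm_profile_loglik(0, parts, length(sim$y),
                                        ncol(sim$X))
  ref <- logLik(lm(sim$y ~ sim$X - 1))
  expect_equal(ll0, as.numeric(ref), tolerance = 1e-8)
})

test_that("near-identical within-subject replicates load the variance on the intercept", {
  # balanced one-way layout with tiny within-subject spread: the ML
  # solution puts essentially all variance on the random intercept
  # (closed form: sigma_u^2 = between-mean variance with divisor m)
  y <- c(1, 1.001, 0.999, 3, 3.001, 2.999)
  fit <- fit_random_intercept(y, matrix(1, 6, 1), rep(c("a", "b"), each = 3))
  expect_lt(fit$sigma2, 1e-4)
  expect_equal(fit$sigma2_u, 1, tolerance = 0.01)
  expect_equal(unname(fit$beta), 2, tolerance = 1e-6)
})

test_that("the full-covariance multivariate-normal oracle matches the profiled likelihood", {
  sim <- simulate_lmm(10, 3, beta = c(2, -1), sigma_u = 1.5, sigma = 0.7,
                      seed = 4)   # 30 rows
  fit <- fit_random_intercept(sim$y, sim$X, sim$subjects)
  oracle <- oracle_lmm_loglik(sim$y, sim$X, sim$subjects, fit$beta,
                              fit$sigma2_u, fit$sigma2)
  expect_equal(fit$loglik, oracle, tolerance = 1e-8)
})

test_that("estimates agree with lme4 maximum likelihood", {
  skip_if_not_installed("lme4")
  sim <- simulate_lmm(60, 4, beta = c(1, 0.5), sigma_u = 2, sigma = 1,
                      seed = 8)
  fit <- fit_random_intercept(sim$y, sim$X, sim$subjects)
  d <- data.frame(y = sim$y, x = sim$X[, 2], subj = sim$subjects)
  ref <- lme4::lmer(y ~ x + (1 | subj), data = d, REML = FALSE)
  expect_equal(fit$loglik, as.numeric(logLik(ref)), tolerance = 1e-6)
  expect_equal(unname(fit$beta), unname(lme4::fixef(ref)),
               tolerance = 1e-5)
  vc <- as.data.frame(lme4::VarCorr(ref))
  expect_equal(fit$sigma2_u, vc$vcov[1], tolerance = 1e-4)
  expect_equal(fit$sigma2, vc$vcov[2], tolerance = 1e-4)
})

test_that("the likelihood shifts by the Jacobian under rescaling of the response", {
  sim <- simulate_lmm(25, 3, beta = c(1, 1), sigma_u = 1, sigma = 0.5,
                      seed = 10)
  f1 <- fit_random_intercept(sim$y, sim$X, sim$subjects)
  a <- 0.01
  f2 <- fit_random_intercept(a * sim$y, sim$X, sim$subjects)
  expect_equal(f2$loglik, f1$loglik - length(sim$y) * log(a),
               tolerance = 1e-6)
  expect_equal(f2$theta, f1$theta, tolerance = 1e-3)
})

test_that("information criteria follow their definitions and ordering", {
  stub <- list(loglik = 0, kparams = 3, n = exp(2))
  ic <- information_criteria(stub)
  expect_equal(unname(ic), c(6, 6))
  better <- list(loglik = 2, kparams = 3, n = exp(2))
  expect_true(all(information_criteria(better) < ic))
  # a pure-noise covariate usually worsens AIC
  worse <- 0L
  for (s in 1:10) {
    sim <- simulate_lmm(40, 3, beta = c(1, 0.5), sigma_u = 1, sigma = 1,
                        seed = 100 + s)
    set.seed(s)
    X2 <- cbind(sim$X, noise = rnorm(length(sim$y)))
    a1 <- fit_random_intercept(sim$y, sim$X, sim$subjects)$AIC
    a2 <- fit_random_intercept(sim$y, X2, sim$subjects)$AIC
    worse <- worse + (a2 > a1)
  }
  expect_gte(worse, 6)
})

test_that("likelihood-ratio comparison is guarded and exact in edge cases", {
  sim <- simulate_lmm(30, 3, beta = c(1, 2), sigma_u = 1, sigma = 1,
                      seed = 12)
  f_full <- fit_random_intercept(sim$y, sim$X, sim$subjects)
  out <- lrt_compare(f_full, f_full)
  expect_equal(unname(out), c(0, 0, 1))
  f_null <- fit_random_intercept(sim$y, sim$X[, 1, drop = FALSE],
                                 sim$subjects)
  lrt <- lrt_compare(f_null, f_full)
  expect_gte(lrt["chisq"], 0)
  expect_equal(unname(lrt["df"]), 1)
  colnames(sim$X) <- c("(Intercept)", "x")
  f2 <- fit_random_intercept(sim$y, sim$X, sim$subjects)
  Xz <- cbind(`(Intercept)` = sim$X[, 1], z = rnorm(length(sim$y)))
  fz <- fit_random_intercept(sim$y, Xz, sim$subjects)
  expect_error(lrt_compare(fz, f2), "not nested")
})

test_that("the ladder recovers the generative model and flags collinearity", {
  ch <- small_cohort(n_subjects = 250, seed = 61)
  vols <- normalize_to_tiv(ch$volumes)
  d <- data.frame(gmv_frac = vols$gmv_frac, age = ch$visits$age,
                  sex = ch$visits$sex,
                  cyclo = ch$truth$latent,       # the true clock-linked signal
                  subject_id = ch$visits$subject_id)
  lad <- build_model_ladder(d)
  expect_equal(lad$best_aic, 4)
  expect_lt(lad$lrt["m4_vs_m3", "p"], 0.001)
  expect_true(all(diff(vapply(lad$fits, function(f) f$loglik,
                              numeric(1))) >= -1e-8))
  d$cyclo <- d$age
  expect_error(build_model_ladder(d), "rank deficient")
})

test_that("a null cohort prefers the intercept-only model by BIC", {
  wins <- 0L
  for (s in 1:5) {
    cfg <- sim_config(n_subjects = 120,
                      age_slopes = c(TNF_l = 0)[0],
                      network_age_slopes = rep(0, 7),
                      network_sex_effects = rep(0, 7),
                      network_clock_loadings = rep(0, 7),
                      gmv_extra_age_slope = 0, seed = 700 + s)
    ch <- generate_cohort(cfg)
    vols <- normalize_to_tiv(ch$volumes)
    set.seed(s)
    d <- data.frame(gmv_frac = vols$gmv_frac, age = ch$visits$age,
                    sex = ch$visits$sex, cyclo = rnorm(nrow(vols)),
                    subject_id = ch$visits$subject_id)
    wins <- wins + (build_model_ladder(d)$best_bic == 1)
  }
  expect_gte(wins, 3)
})
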