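test_that("duplicate collapse applies the CV<=20 retention rule", {
  dups <- list(rep1 = matrix(c(10, 5, 10), 1), rep2 = matrix(c(10, 15, 11), 1))
  out <- collapse_duplicates_cv_filter(dups, cv_threshold = 20)
  # identical replicates: CV 0, value kept
  expect_equal(out[1, 1], 10)
  # (5, 15): sd 7.0711, mean 10, CV 70.7 -> removed
  expect_equal(replicate_cv(5, 15), 70.71068, tolerance = 1e-6)
  expect_true(is.na(out[1, 2]))
  # (10, 11): CV 6.73 -> retained mean 10.5
  expect_equal(replicate_cv(10, 11), 6.734350, tolerance = 1e-6)
  expect_equal(out[1, 3], 10.5)
  # boundary: CV exactly at the threshold is retained
  r2 <- 10 * (1 + sqrt(2) / 10) / (1 - sqrt(2) / 10)  # makes CV exactly 20
  expect_equal(replicate_cv(10, r2), 20, tolerance = 1e-12)
  kept <- collapse_duplicates_cv_filter(
    list(rep1 = matrix(10), rep2 = matrix(r2)), 20)
  expect_false(is.na(kept[1, 1]))
  # nonpositive replicate mean -> entry missing
  neg <- collapse_duplicates_cv_filter(
    list(rep1 = matrix(-3), rep2 = matrix(1)), 20)
  expect_true(is.na(neg[1, 1]))
})

test_that("the CV statistic is scale invariant", {
  set.seed(42)
  r1 <- rexp(50) + 0.1; r2 <- r1 * exp(rnorm(50, 0, 0.2))
  for (c_ in c(0.25, 3, 1000))
    expect_equal(replicate_cv(r1, r2), replicate_cv(c_ * r1, c_ * r2),
                 tolerance = 1e-12)
})

test_that("log transform is exact, guarded, and invertible", {
  m <- matrix(c(1, exp(1), NA, 4), 2, dimnames = list(NULL, c("a", "b")))
  lt <- log_transform(m)
  expect_equal(unname(lt[1, 1]), 0)
  expect_equal(unname(lt[2, 1]), 1)
  expect_true(is.na(lt[1, 2]))
  expect_equal(exp(lt), m)
  m[2, 2] <- -1
  expect_error(log_transform(m), "nonpositive observed value")
})

test_that("markers above the missingness threshold are dropped, order kept", {
  pan <- matrix(rnorm(30), 10, 3, dimnames = list(NULL, c("m1", "m2", "m3")))
  pan[1, 1] <- NA          # 10%
  pan[1:5, 2] <- NA        # 50%
  pan[1:7, 3] <- NA        # 70%
  out <- drop_high_missingness_markers(pan, 0.55)
  expect_identical(colnames(out$panel), c("m1", "m2"))
  expect_identical(out$dropped, "m3")
  complete <- drop_high_missingness_markers(matrix(1:10, 5), 0.55)
  expect_length(complete$dropped, 0)
  allna <- matrix(NA_real_, 5, 2)
  expect_error(drop_high_missingness_markers(allna, 0.5), "all markers")
})

test_that("batch removal equalizes a pure two-group offset exactly", {
  n <- 40
  batches <- rep(1:2, each = n / 2)
  delta <- 0.7
  y <- rep(c(0, delta), each = n / 2)
  pan <- matrix(y, n, 1, dimnames = list(NULL, "m"))
  out <- remove_batch_effects(pan, batches, age = rep(1, n), sex = rep(0, n))
  expect_equal(mean(out[batches == 1, 1]), mean(out[batches == 2, 1]),
               tolerance = 1e-10)
})

test_that("batch removal preserves covariate-driven structure and is idempotent", {
  set.seed(7)
  n <- 120
  age <- runif(n, 50, 90); sex <- rbinom(n, 1, 0.5)
  batches <- sample(1:3, n, replace = TRUE)
  # pure age signal, no batch offset: correction must be a no-op
  pan <- matrix(0.03 * age, n, 1, dimnames = list(NULL, "m"))
  out <- remove_batch_effects(pan, batches, age, sex)
  expect_equal(out, pan, tolerance = 1e-10)
  # with true offsets: idempotent, and missing entries stay missing
  pan2 <- cbind(m1 = 0.02 * age + 0.3 * sex + rnorm(n, 0, 0.2) +
                  c(-0.4, 0.1, 0.3)[batches])
  pan2[c(3, 11), 1] <- NA
  once <- remove_batch_effects(pan2, batches, age, sex)
  twice <- remove_batch_effects(once, batches, age, sex)
  expect_equal(once, twice, tolerance = 1e-8)
  expect_identical(is.na(once), is.na(pan2))
  # single batch: unchanged
  expect_identical(remove_batch_effects(pan2, rep(1, n), age, sex), pan2)
})

test_that("batch removal agrees with the limma reference on complete data", {
  skip_if_not_installed("limma")
  ch <- small_cohort(n_subjects = 60, seed = 31)
  v <- ch$visits
  ours <- remove_batch_effects(ch$panel, v$batch, v$age, v$sex)
  ref <- t(limma::removeBatchEffect(t(ch$panel), batch = factor(v$batch),
                                    design = cbind(1, v$age, v$sex)))
  expect_equal(unname(ours), unname(ref), tolerance = 1e-8)
})

test_that("balancing weights are 1 over the age-bin count", {
  bw <- compute_balancing_weights(c(50, 50, 50, 50, 80), bin_width = 5)
  expect_equal(bw$w, c(0.25, 0.25, 0.25, 0.25, 1))
  one_bin <- compute_balancing_weights(rep(65, 7) + runif(7), bin_width = 10)
  expect_equal(one_bin$w, rep(1 / 7, 7))
  # sum of weights equals the number of nonempty bins (algebraic identity)
  set.seed(3)
  for (i in 1:5) {
    ages <- runif(200, 47, 102)
    bw <- compute_balancing_weights(ages, 5)
    expect_equal(sum(bw$w), sum(bw$bin_counts > 0))
  }
  # permutation equivariance
  ages <- runif(50, 50, 90)
  perm <- sample(50)
  expect_equal(compute_balancing_weights(ages, 5)$w[perm],
               compute_balancing_weights(ages[perm], 5)$w)
  expect_error(compute_balancing_weights(numeric(0)), "nonempty")
  expect_error(compute_balancing_weights(ages, 0), "positive")
})
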