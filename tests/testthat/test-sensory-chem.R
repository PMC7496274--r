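test_that("preprocessing does the log arithmetic and centers per trial", {
  tab <- data.frame(genotype_id = c("a", "b", "c", "d"),
                    trial = c("T1", "T1", "T2", "T2"),
                    cmp = c(4, 16, 2, 8), stringsAsFactors = FALSE)
  pre <- preprocess_profiles(tab, compounds = "cmp")
  # log2 then per-trial centering: T1 values 2,4 -> -1, +1
  expect_equal(pre$cmp, c(-1, 1, -1, 1))
  expect_lt(max(abs(tapply(pre$cmp, pre$trial, mean))), 1e-12)
  expect_error(preprocess_profiles(
    data.frame(trial = "T1", cmp = -1), compounds = "cmp"), "negative")
})

test_that("zeros are replaced by half the minimum positive value", {
  tab <- data.frame(trial = "T1", cmp = c(0, 2, 8))
  pre <- preprocess_profiles(tab, compounds = "cmp")
  # zero -> 1; log2 values 0, 1, 3 centered by mean 4/3
  expect_equal(pre$cmp, c(0, 1, 3) - 4 / 3)
})

test_that("a planted multiplicative batch factor is removed exactly", {
  fx <- hd_fixture()
  arch <- trait_architecture(
    list(trait_spec("PHET", type = "metabolite", baseline = 4,
                    cross_background_sd = 0.5, residual_sd = 0.4)),
    trial_factors = c(T1 = 1, T2 = 3))
  tt <- simulate_traits(fx$pop, arch, seed = 61, replicates = 2)
  pre <- preprocess_profiles(tt, compounds = "PHET")
  per_trial_mean <- tapply(pre$PHET, pre$trial, mean)
  expect_lt(max(abs(per_trial_mean)), 1e-12)
  # identical underlying genetic values: cross-trial difference per
  # genotype reflects only the residual draws, not the factor of 3
  wide <- split(pre$PHET, pre$trial)
  expect_lt(abs(mean(wide$T1 - wide$T2)), 0.2)
  # trial centering is idempotent on already-centered log-scale data
  pre2 <- preprocess_profiles(pre, compounds = "PHET",
                              log_transform = FALSE)
  expect_equal(pre2$PHET, pre$PHET, tolerance = 1e-12)
})

test_that("PCA summary reproduces the data and matches the eigen oracle", {
  set.seed(62)
  x <- matrix(rnorm(30 * 6), 30, 6)
  ps <- pca_summary(x)
  expect_equal(sum(ps$var_explained), 1, tolerance = 1e-12)
  expect_equal(unname(crossprod(ps$loadings)), diag(6), tolerance = 1e-10)
  rec <- ps$scores %*% t(ps$loadings) +
    matrix(ps$center, 30, 6, byrow = TRUE)
  expect_lt(max(abs(rec - x)), 1e-8)
  # eigen oracle on the covariance matrix
  ev <- eigen(cov(x), symmetric = TRUE)$values
  expect_equal(ps$var_explained, ev / sum(ev), tolerance = 1e-10)
  # rank-1 input: first component carries everything
  r1 <- pca_summary(outer(rnorm(15), rnorm(4)))
  expect_equal(r1$var_explained[1], 1, tolerance = 1e-12)
  expect_error(pca_summary(matrix(1, 5, 3)), "constant")
})

test_that("PCA mean-imputes missing cells per column", {
  x <- matrix(rnorm(20 * 4), 20, 4)
  x[3, 2] <- NA
  ps <- pca_summary(x)
  expect_true(all(is.finite(ps$scores)))
})

test_that("a perfect predictor ranks first with a positive sign", {
  set.seed(63)
  X <- matrix(rnorm(60 * 5), 60, 5,
              dimnames = list(NULL, paste0("c", 1:5)))
  rf <- rf_sensory_model(X[, 3], X, n_trees = 100, n_permutations = 20,
                         seed = 2)
  expect_equal(rf$importance$compound[1], "c3")
  expect_equal(rf$importance$sign[rf$importance$compound == "c3"], "+")
  expect_gt(rf$var_explained, 0.5)
})

test_that("an inverted driver gets a negative sign and seeds reproduce exactly", {
  set.seed(64)
  X <- matrix(2^rnorm(60 * 4, 4), 60, 4,
              dimnames = list(NULL, paste0("c", 1:4)))
  y <- -log2(X[, 2]) + rnorm(60, 0, 0.1)
  rf <- rf_sensory_model(y, log2(X), n_trees = 100, n_permutations = 20,
                         seed = 5)
  expect_equal(rf$importance$compound[1], "c2")
  expect_equal(rf$importance$sign[rf$importance$compound == "c2"], "-")
  rf2 <- rf_sensory_model(y, log2(X), n_trees = 100, n_permutations = 20,
                          seed = 5)
  expect_identical(rf$importance, rf2$importance)
  expect_error(rf_sensory_model(rep(1, 60), log2(X)), "constant")
  expect_error(rf_sensory_model(y[1:20], log2(X)[1:20, ]), "n >= 30")
})

test_that("importance of independent compounds concentrates near zero", {
  # Null-compound standardized importances are centered at zero but are
  # not N(0,1) (tree correlation inflates the nominal z scale), so the
  # concentration check is relative to the signal compound.
  set.seed(65)
  X <- matrix(rnorm(80 * 6), 80, 6,
              dimnames = list(NULL, paste0("c", 1:6)))
  y <- X[, 1] + rnorm(80, 0, 0.5)
  signal_first <- 0
  null_means <- numeric(10)
  for (s in 1:10) {
    rf <- rf_sensory_model(y, X, n_trees = 150, n_permutations = 50,
                           seed = 70 + s)
    imp <- rf$importance
    if (imp$compound[1] == "c1") signal_first <- signal_first + 1
    null_imp <- imp$importance[imp$compound != "c1"]
    null_means[s] <- mean(null_imp)
    expect_lt(max(abs(null_imp)),
              imp$importance[imp$compound == "c1"] / 2)
  }
  expect_equal(signal_first, 10)
  expect_lt(abs(mean(null_means)), 1.5)
})
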