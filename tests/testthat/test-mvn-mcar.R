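test_that("EM recovers sample moments on complete data", {
  set.seed(71)
  y <- MASS::mvrnorm(150, c(1, -2, 0), matrix(c(2, .5, .2, .5, 1, .1,
                                                .2, .1, 1.5), 3))
  fit <- mvn_em(y)
  expect_equal(fit$mu, colMeans(y), tolerance = 1e-10,
               ignore_attr = TRUE)
  ml_cov <- cov(y) * (nrow(y) - 1) / nrow(y)
  expect_equal(fit$sigma, ml_cov, tolerance = 1e-8, ignore_attr = TRUE)
  expect_true(fit$converged)
})

test_that("EM solution dominates the available-case starting moments", {
  set.seed(72)
  y <- MASS::mvrnorm(200, rep(0, 4), diag(4) + 0.4)
  y[sample(length(y), 150)] <- NA
  fit <- mvn_em(y)
  mu0 <- colMeans(y, na.rm = TRUE)
  s0 <- diag(apply(y, 2, var, na.rm = TRUE))
  expect_gt(fit$loglik, fadesame:::mvn_obs_loglik(y, mu0, s0))
})

test_that("Little's statistic vanishes when pattern means equal ML means", {
  y <- rbind(c(1, 1), c(-1, -1), c(1, -1), c(-1, 1),
             c(0, NA), c(0, NA),
             c(NA, 0), c(NA, 0))
  res <- little_mcar_test(y)
  expect_lt(res$statistic, 1e-8)
  expect_identical(res$df, 2L + 1L + 1L - 2L)
  expect_gt(res$p.value, 0.99)
})

test_that("complete data is rejected as inapplicable", {
  expect_error(little_mcar_test(matrix(rnorm(40), 20, 2)), "inapplicable")
})

test_that("rows with nothing observed are dropped with a warning", {
  y <- matrix(rnorm(40), 20, 2)
  y[1, ] <- NA
  y[3, 1] <- NA
  expect_warning(res <- little_mcar_test(y), "no observed values")
  expect_identical(res$n, 19L)
})

test_that("MCAR data passes and strong MAR data fails the test (small MC)", {
  set.seed(73)
  p_mcar <- replicate(25, {
    prof <- random_profiles(372, seed = sample.int(1e7, 1))
    d <- inject_mcar(prof, 30 / 372, seed = sample.int(1e7, 1))
    suppressWarnings(little_mcar_test(d[, leq_cols]))$p.value
  })
  expect_gt(mean(p_mcar > 0.05), 0.8)

  set.seed(74)
  p_mar <- replicate(25, {
    cfg <- sim_config()
    pts <- simulate_participants(cfg, sample.int(1e7, 1))
    r <- generate_leq_responses(pts, sample.int(1e7, 1))
    d <- inject_mar(r, seed = sample.int(1e7, 1))
    suppressWarnings(little_mcar_test(d[, leq_cols]))$p.value
  })
  expect_gt(mean(p_mar < 0.05), 0.5)
})
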