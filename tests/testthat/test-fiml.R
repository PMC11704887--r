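test_that("FIML equals closed-form least squares on complete data", {
  set.seed(81)
  d <- tibble::tibble(x1 = rnorm(120), x2 = rnorm(120))
  d$y <- 1 + 0.7 * d$x1 - 0.4 * d$x2 + rnorm(120)
  f <- fiml_regression(d, "y", c("x1", "x2"), scale = FALSE)
  ols <- coef(lm(y ~ x1 + x2, d))
  expect_equal(f$coefficients$estimate, unname(ols), tolerance = 1e-6)
  expect_identical(f$n_complete, 120L)
})

test_that("an exact linear relation gives B = 2 and beta = 1", {
  d <- tibble::tibble(x = seq(-2, 2, length.out = 50))
  d$y <- 2 * d$x
  f <- fiml_regression(d, "y", "x", scale = FALSE, se = FALSE)
  expect_equal(f$coefficients$estimate, c(0, 2), tolerance = 1e-8)
  expect_equal(f$coefficients$beta[2], 1, tolerance = 1e-8)
  expect_lt(abs(f$residual_variance), 1e-10)
})

test_that("standardized betas are invariant to affine input rescaling", {
  set.seed(82)
  d <- tibble::tibble(x = rnorm(150), y = 0.4 * rnorm(150))
  d$y <- 0.5 * d$x + rnorm(150)
  d$x[1:40] <- NA
  f1 <- fiml_regression(d, "y", "x", scale = TRUE, se = FALSE)
  d2 <- dplyr::mutate(d, x = 100 + 7 * x, y = -3 + 0.1 * y)
  f2 <- fiml_regression(d2, "y", "x", scale = TRUE, se = FALSE)
  expect_equal(f2$coefficients$estimate[2], f1$coefficients$estimate[2],
               tolerance = 1e-6)
})

test_that("FIML approaches complete-case OLS as missingness vanishes", {
  set.seed(83)
  d <- tibble::tibble(x = rnorm(300))
  d$y <- 0.3 * d$x + rnorm(300)
  d$x[1:2] <- NA
  f <- fiml_regression(d, "y", "x", scale = FALSE, se = FALSE)
  ols <- unname(coef(lm(y ~ x, d)))
  expect_lt(abs(f$coefficients$estimate[2] - ols[2]), 0.01)
  expect_lt(abs(f$coefficients$estimate[1] - ols[1]), 0.02)
})

test_that("degenerate inputs are rejected informatively", {
  d <- tibble::tibble(x = c(NA, NA, NA), y = c(1, 2, 3))
  expect_error(fiml_regression(d, "y", "x"), "entirely missing")
  expect_error(fiml_regression(tibble::tibble(y = 1:5), "y", "x"), "not found")
  d2 <- tibble::tibble(x = rep(1, 10), y = rnorm(10))
  expect_error(fiml_regression(d2, "y", "x"), "Zero-variance")
})

test_that("duplicating every row keeps beta and shrinks SE by sqrt(2)", {
  set.seed(84)
  d <- tibble::tibble(x = rnorm(200))
  d$y <- 0.3 * d$x + rnorm(200)
  d$x[1:50] <- NA
  f1 <- fiml_regression(d, "y", "x", scale = TRUE)
  f2 <- fiml_regression(dplyr::bind_rows(d, d), "y", "x", scale = TRUE)
  expect_equal(f2$coefficients$estimate[2], f1$coefficients$estimate[2],
               tolerance = 1e-3)
  expect_equal(f2$coefficients$std.error[2],
               f1$coefficients$std.error[2] / sqrt(2), tolerance = 0.02)
})

test_that("tidy and glance expose the coefficient table and fit summary", {
  set.seed(85)
  d <- tibble::tibble(x = rnorm(60), y = rnorm(60))
  f <- fiml_regression(d, "y", "x")
  td <- tidy(f)
  expect_identical(td$term, c("(Intercept)", "x"))
  expect_true(all(td$p.value >= 0 & td$p.value <= 1))
  g <- glance(f)
  expect_identical(g$n, 60L)
  expect_true(g$converged)
})
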