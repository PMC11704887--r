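test_that("least squares on an orthonormal design reads off the outcome", {
  set.seed(91)
  q <- qr.Q(qr(matrix(rnorm(60 * 3), 60, 3)))
  d <- tibble::as_tibble(as.data.frame(q))
  names(d) <- c("a", "b", "c")
  d$y <- d$a
  fit <- ols_fit(d, "y", c("a", "b", "c"))
  expect_equal(unname(coef(fit)), c(0, 1, 0, 0), tolerance = 1e-10)
})

test_that("OLS agrees with FIML on complete data and nests monotonically", {
  set.seed(92)
  d <- tibble::tibble(x1 = rnorm(100), x2 = rnorm(100))
  d$y <- 0.5 * d$x1 + rnorm(100)
  fit <- ols_fit(d, "y", c("x1", "x2"))
  fiml <- fiml_regression(d, "y", c("x1", "x2"), scale = FALSE, se = FALSE)
  expect_equal(unname(coef(fit)), fiml$coefficients$estimate, tolerance = 1e-6)

  rss1 <- sum(resid(ols_fit(d, "y", "x1"))^2)
  rss2 <- sum(resid(fit)^2)
  expect_lte(rss2, rss1)

  d$dup <- d$x1
  expect_error(ols_fit(d, "y", c("x1", "dup")), "collinear")
})

test_that("interaction F-test behaves at the null, under power and degenerately", {
  set.seed(93)
  one_group <- tibble::tibble(x = rnorm(80), g = "A")
  one_group$y <- 0.5 * one_group$x + rnorm(80)
  twin <- dplyr::bind_rows(one_group,
                           dplyr::mutate(one_group, g = "B"))
  res <- interaction_ftest(twin, "g", "x", "y")
  expect_lt(res$statistic, 1e-8)
  expect_identical(res$df1, 2L)

  # distinct slopes, low noise: detected
  da <- tibble::tibble(x = rnorm(200), g = "A")
  da$y <- 0 * da$x + 0.3 * rnorm(200)
  db <- tibble::tibble(x = rnorm(200), g = "B")
  db$y <- 0.5 * db$x + 0.3 * rnorm(200)
  expect_lt(interaction_ftest(dplyr::bind_rows(da, db), "g", "x", "y")$p.value,
            0.001)

  # three-group version carries 4 added parameters
  dc <- tibble::tibble(x = rnorm(50), g = "C")
  dc$y <- rnorm(50)
  expect_identical(interaction_ftest(dplyr::bind_rows(da, db, dc),
                                     "g", "x", "y")$df1, 4L)

  tiny <- dplyr::bind_rows(da, tibble::tibble(x = 1, g = "B", y = 1))
  expect_error(interaction_ftest(tiny, "g", "x", "y"), "too few")
})

test_that("identical generative slopes reject at roughly the nominal rate", {
  set.seed(94)
  rej <- replicate(100, {
    d <- tibble::tibble(x = rnorm(150),
                        g = sample(c("A", "B", "C"), 150, replace = TRUE))
    d$y <- 0.3 * d$x + rnorm(150)
    interaction_ftest(d, "g", "x", "y")$p.value < 0.05
  })
  expect_gt(mean(rej), 0.005)
  expect_lt(mean(rej), 0.12)
})

test_that("VIF matches closed forms and flags degeneracy", {
  # centered, exactly orthogonal contrast columns
  orth <- tibble::tibble(a = rep(c(1, -1), 40),
                         b = rep(c(1, 1, -1, -1), 20))
  expect_equal(vif_report(orth)$vif, c(1, 1), tolerance = 1e-10)

  # exact sample correlation 0.8 by construction
  set.seed(95)
  x1 <- scale(rnorm(80))[, 1]
  e <- scale(resid(lm(rnorm(80) ~ x1)))[, 1]
  d <- tibble::tibble(a = x1, b = 0.8 * x1 + sqrt(1 - 0.64) * e)
  expect_equal(vif_report(d)$vif, rep(1 / (1 - 0.64), 2), tolerance = 1e-8)

  dup <- tibble::tibble(a = rnorm(30))
  dup$b <- dup$a
  w <- capture_warnings(v <- vif_report(dup))
  expect_true(any(grepl("collinearity", w)))
  expect_true(all(!is.finite(v$vif)))
})

test_that("VIF agrees with the car package on a joint design", {
  set.seed(96)
  d <- tibble::tibble(x1 = rnorm(120), x2 = rnorm(120), x3 = rnorm(120))
  d$x2 <- 0.6 * d$x1 + 0.8 * d$x2
  d$y <- d$x1 + rnorm(120)
  ours <- vif_report(d, c("x1", "x2", "x3"))$vif
  theirs <- unname(car::vif(lm(y ~ x1 + x2 + x3, d)))
  expect_equal(ours, theirs, tolerance = 1e-8)
})
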