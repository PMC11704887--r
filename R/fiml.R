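#' Linear regression by full-information maximum likelihood
#'
#' Fits a linear regression of `outcome` on `predictors` when some
#' entries of the data are missing, without discarding incomplete rows.
#' The variables are treated as jointly multivariate normal; the joint
#' mean and covariance are estimated by EM from the observed entries
#' ([mvn_em()]), and the regression coefficients are the ones implied by
#' the fitted joint moments,
#' \eqn{B = \Sigma_{xx}^{-1}\Sigma_{xy}}. Standard errors come from the
#' observed information (numerical Hessian of the observed-data
#' log-likelihood in the joint moments, delta method for the regression
#' parametrisation), and p-values use the normal (z) reference, as is
#' conventional for FIML software.
#'
#' With `scale = TRUE` every variable is standardised in advance using
#' available-case means and SDs, so the reported coefficients are
#' standardized betas. With `scale = FALSE` raw-scale coefficients are
#' reported and the standardized beta is derived as
#' `B * sd(x) / sd(y)` from available-case SDs.
#'
#' On complete data the estimates coincide with ordinary least squares
#' (up to the ML vs. OLS variance denominator, which does not affect
#' coefficients).
#'
#' @param data Data frame containing the variables.
#' @param outcome Name of the outcome column.
#' @param predictors Character vector of predictor column names.
#' @param scale If `TRUE` (default), standardise all variables before
#'   fitting so coefficients are standardized betas.
#' @param se If `FALSE`, skip the (comparatively costly) observed-
#'   information standard errors; estimates only.
#' @param max_iter,tol Passed to [mvn_em()].
#' @return An object of class `fiml_result` with a coefficient table
#'   (`term`, `estimate`, `std.error`, `statistic`, `p.value`, `beta`),
#'   residual variance, log-likelihood, sample sizes and convergence
#'   information. Use [tidy()] / [glance()] to extract tibbles.
#' @examples
#' set.seed(1)
#' d <- tibble::tibble(x = rnorm(100), y = 0.5 * x + rnorm(100))
#' d$x[1:20] <- NA
#' fiml_regression(d, "y", "x")
#' @export
fiml_regression <- function(data, outcome, predictors, scale = TRUE,
                            se = TRUE, max_iter = 10000L, tol = 1e-10) {
  vars <- c(outcome, predictors)
  missing_cols <- setdiff(vars, colnames(data))
  if (length(missing_cols) > 0) {
    abort(paste("Columns not found:", paste(missing_cols, collapse = ", ")))
  }
  y <- as.matrix(as.data.frame(data)[, vars, drop = FALSE])
  if (!is.numeric(y)) abort("All model variables must be numeric.")
  all_na <- colSums(!is.na(y)) == 0L
  if (any(all_na)) {
    abort(paste("Column(s) entirely missing:",
                paste(vars[all_na], collapse = ", ")))
  }

  sds_raw <- apply(y, 2L, sd, na.rm = TRUE)
  if (any(sds_raw == 0 | !is.finite(sds_raw))) {
    abort(paste("Zero-variance column(s):",
                paste(vars[sds_raw == 0 | !is.finite(sds_raw)], collapse = ", ")))
  }
  if (scale) y <- base::scale(y)

  fit <- mvn_em(y, max_iter = max_iter, tol = tol)
  if (!fit$converged) {
    warn(sprintf("EM did not converge within %d iterations.", max_iter))
  }
  k <- length(predictors)
  iy <- 1L
  ix <- seq_len(k) + 1L
  sxx <- fit$sigma[ix, ix, drop = FALSE]
  sxy <- fit$sigma[ix, iy]
  b <- drop(solve(sxx, sxy))
  b0 <- fit$mu[iy] - sum(fit$mu[ix] * b)
  sigma2 <- drop(fit$sigma[iy, iy] - sum(sxy * b))
  est <- c(b0, b)
  beta <- if (scale) b else b * sds_raw[ix] / sds_raw[iy]

  se_vec <- rep(NA_real_, k + 1L)
  if (se) {
    se_vec <- fiml_delta_se(y, fit)
  }
  zstat <- est / se_vec
  tab <- tibble(
    term = c("(Intercept)", predictors),
    estimate = unname(est),
    std.error = unname(se_vec),
    statistic = unname(zstat),
    p.value = unname(2 * pnorm(-abs(zstat))),
    beta = unname(c(NA_real_, beta))
  )
  structure(
    list(coefficients = tab, outcome = outcome, predictors = predictors,
         scaled = scale, residual_variance = sigma2,
         mu = fit$mu, sigma = fit$sigma,
         loglik = fit$loglik, converged = fit$converged,
         iterations = fit$iterations, n = fit$n,
         n_complete = sum(complete.cases(y))),
    class = "fiml_result"
  )
}

# Observed-information SEs for (intercept, slopes) by the delta method:
# numerical Hessian of the observed-data log-likelihood in
# theta = (mu, vech(Sigma)) at the MLE, then the Jacobian of the
# regression parametrisation.
fiml_delta_se <- function(y, fit) {
  k_all <- ncol(y)
  keep <- rowSums(!is.na(y)) > 0L
  y <- y[keep, , drop = FALSE]
  lt <- which(lower.tri(matrix(0, k_all, k_all), diag = TRUE))
  pack <- function(mu, sigma) c(mu, sigma[lt])
  unpack <- function(theta) {
    mu <- theta[seq_len(k_all)]
    s <- matrix(0, k_all, k_all)
    s[lt] <- theta[-seq_len(k_all)]
    s <- s + t(s) - diag(diag(s))
    list(mu = mu, sigma = s)
  }
  # Pre-group rows by missingness pattern once; the numerical Hessian
  # evaluates the likelihood a few hundred times.
  obs <- !is.na(y)
  pat_key <- apply(obs, 1L, function(r) paste(as.integer(r), collapse = ""))
  groups <- lapply(split(seq_len(nrow(y)), pat_key), function(rows) {
    o <- which(obs[rows[1L], ])
    list(o = o, yo = y[rows, o, drop = FALSE], n = length(rows))
  })
  negll <- function(theta) {
    p <- unpack(theta)
    ll <- 0
    for (g in groups) {
      ch <- tryCatch(chol(p$sigma[g$o, g$o, drop = FALSE]),
                     error = function(e) NULL)
      if (is.null(ch)) return(Inf)
      z <- backsolve(ch, t(sweep(g$yo, 2L, p$mu[g$o])), transpose = TRUE)
      ll <- ll - 0.5 * (g$n * (length(g$o) * log(2 * pi) +
                                 2 * sum(log(diag(ch)))) + sum(z^2))
    }
    -ll
  }
  reg_par <- function(theta) {
    p <- unpack(theta)
    ix <- seq_len(k_all)[-1L]
    b <- drop(solve(p$sigma[ix, ix, drop = FALSE], p$sigma[ix, 1L]))
    c(p$mu[1L] - sum(p$mu[ix] * b), b)
  }
  theta <- pack(fit$mu, fit$sigma)
  h <- pracma::hessian(negll, theta)
  vcov_theta <- tryCatch(solve(h), error = function(e) NULL)
  if (is.null(vcov_theta)) return(rep(NA_real_, k_all))
  j <- pracma::jacobian(reg_par, theta)
  v <- j %*% vcov_theta %*% t(j)
  d <- diag(v)
  d[d < 0] <- NA_real_
  sqrt(d)
}

#' @export
print.fiml_result <- function(x, digits = 4, ...) {
  cat(sprintf("FIML regression: %s ~ %s%s\n", x$outcome,
              paste(x$predictors, collapse = " + "),
              if (x$scaled) "  (standardized variables)" else ""))
  print(as.data.frame(x$coefficients), digits = digits, row.names = FALSE)
  cat(sprintf("n = %d (%d complete), logLik = %.3f, %s in %d iterations\n",
              x$n, x$n_complete, x$loglik,
              if (x$converged) "converged" else "NOT converged",
              x$iterations))
  invisible(x)
}

#' @export
tidy.fiml_result <- function(x, ...) x$coefficients

#' @export
glance.fiml_result <- function(x, ...) {
  tibble(n = x$n, n_complete = x$n_complete, logLik = x$loglik,
         residual_variance = x$residual_variance,
         converged = x$converged, iterations = x$iterations)
}
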