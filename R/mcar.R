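#' Little's test of missing completely at random
#'
#' Tests whether the missingness in a numeric data matrix is compatible
#' with the missing-completely-at-random (MCAR) assumption by comparing
#' each missingness pattern's observed-variable means against the
#' maximum-likelihood estimates from all data. The statistic is
#' \deqn{d^2 = \sum_p n_p\, (\bar y_p - \hat\mu_{[p]})^\top
#'   \hat\Sigma_{[p]}^{-1} (\bar y_p - \hat\mu_{[p]}),}
#' where the sum runs over missingness patterns, \eqn{[p]} restricts to
#' the variables observed in pattern \eqn{p}, and \eqn{\hat\mu,
#' \hat\Sigma} are the EM maximum-likelihood moments. Under MCAR and
#' joint normality, \eqn{d^2} is asymptotically chi-square with
#' \eqn{\sum_p k_p - k} degrees of freedom.
#'
#' A non-significant result (large p) is consistent with MCAR; a small p
#' indicates the pattern means drift with missingness, as under
#' missing-at-random or worse.
#'
#' @param data A data frame or numeric matrix with `NA` for missing
#'   entries; non-numeric columns are rejected.
#' @param max_iter,tol Passed to [mvn_em()].
#' @return An object of class `mcar_result`: a list with `statistic`,
#'   `df`, `p.value`, `n_patterns`, `n` and `k`.
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(600), 200, 3)
#' x[sample(length(x), 60)] <- NA
#' little_mcar_test(x)
#' @export
little_mcar_test <- function(data, max_iter = 10000L, tol = 1e-10) {
  y <- as.matrix(data)
  if (!is.numeric(y)) abort("All columns must be numeric.")
  fit <- mvn_em(y, max_iter = max_iter, tol = tol)
  pats <- fit$patterns
  if (length(pats) < 2L) {
    abort(paste("Only one missingness pattern present (complete data);",
                "Little's test is inapplicable (df = 0)."))
  }
  k <- ncol(y)
  d2 <- 0
  for (i in seq_along(pats)) {
    p <- pats[[i]]
    o <- p$obs_idx
    dev <- p$ybar - fit$mu[o]
    ch <- tryCatch(chol(fit$sigma[o, o, drop = FALSE]), error = function(e) NULL)
    if (is.null(ch)) {
      abort(sprintf("Singular covariance block for missingness pattern %d.", i))
    }
    z <- backsolve(ch, dev, transpose = TRUE)
    d2 <- d2 + p$n * sum(z^2)
  }
  df <- sum(vapply(pats, function(p) length(p$obs_idx), integer(1))) - k
  structure(
    list(statistic = d2, df = df,
         p.value = pchisq(d2, df, lower.tail = FALSE),
         n_patterns = length(pats), n = fit$n, k = k),
    class = "mcar_result"
  )
}

#' @export
print.mcar_result <- function(x, ...) {
  cat("Little's MCAR test\n")
  cat(sprintf("  chi-square = %.2f, df = %d, p = %.3f\n",
              x$statistic, x$df, x$p.value))
  cat(sprintf("  %d missingness patterns over %d rows, %d variables\n",
              x$n_patterns, x$n, x$k))
  invisible(x)
}

#' @export
glance.mcar_result <- function(x, ...) {
  tibble(statistic = x$statistic, df = x$df, p.value = x$p.value,
         n_patterns = x$n_patterns, n = x$n)
}
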