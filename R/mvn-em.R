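#' Maximum-likelihood mean and covariance of incomplete multivariate data
#'
#' Estimates the mean vector and covariance matrix of a jointly normal
#' random vector from a data matrix with missing entries, by
#' expectation-maximisation over the missingness patterns. This is the
#' common engine behind [little_mcar_test()] and [fiml_regression()]:
#' both need the observed-data maximum-likelihood moments rather than
#' complete-case or pairwise estimates.
#'
#' Rows with no observed value at all are dropped with a warning. The
#' covariance returned is the ML estimate (denominator `n`, not `n - 1`).
#'
#' @param y Numeric matrix or data frame, `n` rows by `k` variables,
#'   with `NA` for missing entries.
#' @param max_iter Maximum EM iterations.
#' @param tol Convergence tolerance on the relative change of the
#'   observed-data log-likelihood.
#' @return A list with components `mu` (length-`k` mean), `sigma`
#'   (`k x k` ML covariance), `loglik` (observed-data log-likelihood at
#'   the solution), `converged`, `iterations`, `n` (rows used), and
#'   `patterns` (a list describing each missingness pattern: the
#'   observed-variable index set, row indices and per-pattern mean of
#'   the observed variables).
#' @export
mvn_em <- function(y, max_iter = 10000L, tol = 1e-10) {
  y <- as.matrix(y)
  if (!is.numeric(y)) abort("`y` must be a numeric matrix.")
  k <- ncol(y)
  all_miss <- rowSums(!is.na(y)) == 0L
  if (any(all_miss)) {
    warn(sprintf("Dropping %d row(s) with no observed values.", sum(all_miss)))
    y <- y[!all_miss, , drop = FALSE]
  }
  n <- nrow(y)
  if (n < 2L) abort("Need at least two rows with observed values.")

  obs <- !is.na(y)
  pat_key <- apply(obs, 1L, function(r) paste(as.integer(r), collapse = ""))
  pat_rows <- split(seq_len(n), pat_key)
  patterns <- lapply(pat_rows, function(rows) {
    o <- which(obs[rows[1L], ])
    list(obs_idx = o, rows = rows, n = length(rows),
         ybar = colMeans(y[rows, o, drop = FALSE]))
  })

  # Start from available-case means and variances (diagonal covariance);
  # EM then monotonically improves the observed-data likelihood.
  mu <- colMeans(y, na.rm = TRUE)
  v <- apply(y, 2L, var, na.rm = TRUE)
  v[!is.finite(v) | v <= 0] <- 1
  sigma <- diag(v, k)

  loglik <- -Inf
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    s1 <- numeric(k)
    s2 <- matrix(0, k, k)
    ll <- 0
    for (p in patterns) {
      o <- p$obs_idx
      m <- setdiff(seq_len(k), o)
      yo <- y[p$rows, o, drop = FALSE]
      soo <- sigma[o, o, drop = FALSE]
      ch <- tryCatch(chol(soo), error = function(e) NULL)
      if (is.null(ch)) {
        abort("Observed-block covariance became singular during EM.")
      }
      ctr <- sweep(yo, 2L, mu[o])
      z <- backsolve(ch, t(ctr), transpose = TRUE)   # k_o x n_p
      ll <- ll - 0.5 * (p$n * (length(o) * log(2 * pi) +
                                 2 * sum(log(diag(ch)))) + sum(z^2))
      if (length(m) == 0L) {
        s1[o] <- s1[o] + colSums(yo)
        s2[o, o] <- s2[o, o] + crossprod(yo)
      } else {
        a <- sigma[m, o, drop = FALSE] %*% chol2inv(ch)   # regression of mis on obs
        em <- matrix(mu[m], p$n, length(m), byrow = TRUE) + ctr %*% t(a)
        cmm <- sigma[m, m, drop = FALSE] - a %*% sigma[o, m, drop = FALSE]
        yfull <- matrix(0, p$n, k)
        yfull[, o] <- yo
        yfull[, m] <- em
        s1 <- s1 + colSums(yfull)
        s2 <- s2 + crossprod(yfull)
        s2[m, m] <- s2[m, m] + p$n * cmm
      }
    }
    mu_new <- s1 / n
    sigma_new <- s2 / n - tcrossprod(mu_new)
    sigma_new <- (sigma_new + t(sigma_new)) / 2
    rel <- abs(ll - loglik) / (abs(ll) + .Machine$double.eps)
    mu <- mu_new
    sigma <- sigma_new
    if (is.finite(loglik) && rel < tol) {
      converged <- TRUE
      loglik <- ll
      break
    }
    loglik <- ll
  }
  names(mu) <- colnames(y)
  dimnames(sigma) <- list(colnames(y), colnames(y))
  list(mu = mu, sigma = sigma, loglik = loglik, converged = converged,
       iterations = iter, n = n, patterns = patterns)
}

#' Observed-data log-likelihood of incomplete data under a fixed MVN
#'
#' Evaluates the multivariate-normal observed-data log-likelihood of an
#' incomplete matrix at given moments, summing each row's marginal
#' density over its observed variables. Used for standard-error
#' computation via the observed information.
#'
#' @param y Numeric matrix with `NA`s (rows with no observed values must
#'   already be removed).
#' @param mu Mean vector.
#' @param sigma Covariance matrix (must be positive definite on every
#'   observed block).
#' @return The scalar log-likelihood (`-Inf` if some observed block is
#'   not positive definite).
#' @keywords internal
mvn_obs_loglik <- function(y, mu, sigma) {
  obs <- !is.na(y)
  pat_key <- apply(obs, 1L, function(r) paste(as.integer(r), collapse = ""))
  ll <- 0
  for (rows in split(seq_len(nrow(y)), pat_key)) {
    o <- which(obs[rows[1L], ])
    ch <- tryCatch(chol(sigma[o, o, drop = FALSE]), error = function(e) NULL)
    if (is.null(ch)) return(-Inf)
    ctr <- sweep(y[rows, o, drop = FALSE], 2L, mu[o])
    z <- backsolve(ch, t(ctr), transpose = TRUE)
    ll <- ll - 0.5 * (length(rows) * (length(o) * log(2 * pi) +
                                        2 * sum(log(diag(ch)))) + sum(z^2))
  }
  ll
}
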