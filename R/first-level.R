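#' Design specification for the encoding-task GLM
#'
#' Fixes the modelling choices of the first-level analysis: canonical
#' double-gamma HRF (peak 6 s, undershoot 16 s, no derivatives), one
#' regressor pooling the two master images, one for novel trials, a
#' parametric modulator weighting novel trials by mean-centered
#' recognition confidence, and a first-order polynomial drift plus
#' intercept.
#'
#' @param config A [sim_config()] (supplies `tr_seconds`).
#' @param drift_order Polynomial drift order (default 1: linear).
#' @return A list of class `design_spec`.
#' @export
design_spec <- function(config, drift_order = 1L) {
  structure(list(tr_seconds = config$tr_seconds,
                 drift_order = as.integer(drift_order)),
            class = "design_spec")
}

#' Canonical double-gamma haemodynamic response function
#'
#' `h(t) = dgamma(t, 6, 1) - dgamma(t, 16, 1) / 6`: response peaking
#' near 6 s with an undershoot near 16 s, the conventional canonical
#' shape. Zero for `t < 0`.
#'
#' @param t Time in seconds.
#' @return HRF values.
#' @export
hrf_double_gamma <- function(t) {
  ifelse(t < 0, 0, dgamma(t, shape = 6, rate = 1) -
           dgamma(t, shape = 16, rate = 1) / 6)
}

#' Build the first-level design matrix
#'
#' Columns: `master` and `novel` event regressors (impulses at trial
#' onsets convolved with the canonical HRF, evaluated at scan times),
#' `modulator` (novel-trial impulses weighted by confidence minus the
#' mean confidence — mean-centering makes it orthogonal in weights to
#' the novel regressor), polynomial drift columns and an intercept.
#' If all confidences are equal the modulator is identically zero; it
#' is then dropped with a warning and the design carries attribute
#' `dropped = "modulator"`.
#'
#' @param session An [simulate_session()] result (or any list with a
#'   compatible `trials` tibble).
#' @param spec A [design_spec()].
#' @param n_scans Number of volumes; default covers the last onset plus
#'   20 s.
#' @return The design matrix with named columns.
#' @export
build_design_matrix <- function(session, spec,
                                n_scans = NULL) {
  tr <- spec$tr_seconds
  trials <- session$trials
  if (!any(trials$trial_type == "master")) {
    abort("Session has no master trials; the novelty contrast is undefined.")
  }
  if (!any(trials$trial_type == "novel")) {
    abort("Session has no novel trials.")
  }
  if (is.null(n_scans)) n_scans <- ceiling((max(trials$onset) + 20) / tr)
  t_scan <- (seq_len(n_scans) - 1L) * tr

  conv <- function(onsets, weights) {
    out <- numeric(n_scans)
    for (i in seq_along(onsets)) {
      out <- out + weights[i] * hrf_double_gamma(t_scan - onsets[i])
    }
    out
  }
  nov <- trials$trial_type == "novel"
  mas <- trials$trial_type == "master"
  conf <- trials$confidence[nov]
  if (anyNA(conf)) abort("Novel trials must carry confidence ratings.")
  w_mod <- conf - mean(conf)

  x <- cbind(master = conv(trials$onset[mas], rep(1, sum(mas))),
             novel = conv(trials$onset[nov], rep(1, sum(nov))),
             modulator = conv(trials$onset[nov], w_mod))
  dropped <- character(0)
  if (all(w_mod == 0)) {
    warn("All confidences equal: zero-variance modulator column dropped.")
    x <- x[, c("master", "novel"), drop = FALSE]
    dropped <- "modulator"
  }
  drift <- sapply(seq_len(spec$drift_order), function(p) {
    d <- (t_scan - mean(t_scan))^p
    d / max(abs(d))
  })
  colnames(drift) <- paste0("drift", seq_len(spec$drift_order))
  x <- cbind(x, drift, intercept = 1)
  if (qr(x)$rank < ncol(x)) {
    abort("Design matrix is rank deficient.")
  }
  attr(x, "dropped") <- dropped
  x
}

#' Fit the voxelwise GLM and form contrast t-maps
#'
#' Ordinary least squares per voxel, then t statistics for the novelty
#' contrast (`novel - master`) and the subsequent-memory contrast (the
#' `modulator` regressor), with `t = c'b / sqrt(sigma2 * c'(X'X)^{-1}c)`
#' and `df = n - rank(X)`.
#'
#' @param timeseries `n_scans x n_voxel` matrix (e.g. `$bold` of
#'   [simulate_bold()]), or a `bold_sim` object.
#' @param design Design matrix from [build_design_matrix()]; taken from
#'   the `bold_sim` object if omitted.
#' @param grid_dims Grid dimensions for shaping the output maps; taken
#'   from the `bold_sim` object if omitted.
#' @return An object of class `glm_fit`: list with `betas`
#'   (`n_regressor x n_voxel`), `sigma2`, `df`, and `tmaps` — a list of
#'   3-D t-value arrays `novelty` and `memory` (`memory` is `NULL` when
#'   the modulator was dropped).
#' @export
fit_first_level <- function(timeseries, design = NULL, grid_dims = NULL) {
  if (inherits(timeseries, "bold_sim")) {
    design <- design %||% timeseries$design
    grid_dims <- grid_dims %||% timeseries$grid_dims
    timeseries <- timeseries$bold
  }
  y <- as.matrix(timeseries)
  if (!all(is.finite(y))) abort("Time series contains non-finite values.")
  if (nrow(y) != nrow(design)) {
    abort("Time series length must equal the number of design rows.")
  }
  xtx_inv <- chol2inv(chol(crossprod(design)))
  b <- xtx_inv %*% crossprod(design, y)
  rownames(b) <- colnames(design)
  res <- y - design %*% b
  df <- nrow(y) - qr(design)$rank
  sigma2 <- colSums(res^2) / df

  tmap <- function(cvec) {
    eff <- drop(crossprod(cvec, b))
    se <- sqrt(sigma2 * drop(t(cvec) %*% xtx_inv %*% cvec))
    arr <- eff / se
    if (!is.null(grid_dims)) array(arr, dim = grid_dims) else arr
  }
  cn <- colnames(design)
  c_nov <- (cn == "novel") - (cn == "master")
  maps <- list(novelty = tmap(c_nov))
  maps$memory <- if ("modulator" %in% cn) tmap(as.numeric(cn == "modulator"))
  structure(list(betas = b, sigma2 = sigma2, df = df, tmaps = maps),
            class = "glm_fit")
}
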