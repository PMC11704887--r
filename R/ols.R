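#' Complete-case least-squares fit
#'
#' Ordinary least squares of `outcome` on `predictors` using only rows
#' with no missing value among the used variables. Thin wrapper around
#' [stats::lm()] that rejects rank-deficient designs by name instead of
#' silently dropping columns; used for the interaction (slope
#' heterogeneity) F-test and as the complete-data cross-check of
#' [fiml_regression()].
#'
#' @inheritParams fiml_regression
#' @return An `lm` fit on the complete cases, with the number of rows
#'   used attached as attribute `n_complete`.
#' @export
ols_fit <- function(data, outcome, predictors) {
  vars <- c(outcome, predictors)
  missing_cols <- setdiff(vars, colnames(data))
  if (length(missing_cols) > 0) {
    abort(paste("Columns not found:", paste(missing_cols, collapse = ", ")))
  }
  d <- as.data.frame(data)[, vars, drop = FALSE]
  d <- d[complete.cases(d), , drop = FALSE]
  if (nrow(d) <= length(predictors) + 1L) {
    abort("Fewer complete cases than parameters.")
  }
  f <- as.formula(paste(outcome, "~",
                        paste(sprintf("`%s`", predictors), collapse = " + ")))
  fit <- lm(f, data = d)
  aliased <- is.na(coef(fit))
  if (any(aliased)) {
    abort(paste("Rank-deficient design; collinear column(s):",
                paste(names(coef(fit))[aliased], collapse = ", ")))
  }
  attr(fit, "n_complete") <- nrow(d)
  fit
}

#' F-test for slope heterogeneity across groups
#'
#' Compares, on complete cases, a model regressing `outcome` on the
#' focal predictor alone against one adding group main effects and
#' group-by-predictor interaction terms. With `g` groups the added
#' parameter count is `2 * (g - 1)` (e.g. 4 for three groups), and the
#' F statistic tests whether the regression slope differs between
#' groups.
#'
#' @param data Data frame.
#' @param group Name of the grouping column (factor or character).
#' @param predictor Name of the focal numeric predictor.
#' @param outcome Name of the outcome column.
#' @param min_per_group Minimum complete cases required per group.
#' @return A one-row tibble with `statistic`, `df1`, `df2`, `p.value`,
#'   `n` and the model formulas compared.
#' @export
interaction_ftest <- function(data, group, predictor, outcome,
                              min_per_group = 2L) {
  d <- as.data.frame(data)[, c(outcome, predictor, group)]
  names(d) <- c(".y", ".x", ".g")
  d <- d[complete.cases(d), , drop = FALSE]
  d$.g <- factor(d$.g)
  if (nlevels(d$.g) < 2L) abort("Need at least two groups with complete cases.")
  cnt <- table(d$.g)
  if (any(cnt < min_per_group)) {
    abort(paste("Group(s) with too few complete cases:",
                paste(names(cnt)[cnt < min_per_group], collapse = ", ")))
  }
  m0 <- lm(.y ~ .x, data = d)
  m1 <- lm(.y ~ .x * .g, data = d)
  a <- anova(m0, m1)
  tibble(
    statistic = a$F[2L], df1 = as.integer(a$Df[2L]),
    df2 = as.integer(a$Res.Df[2L]),
    p.value = a$`Pr(>F)`[2L], n = nrow(d),
    model_null = paste(outcome, "~", predictor),
    model_full = paste(outcome, "~", predictor, "*", group)
  )
}

#' Variance inflation factors
#'
#' Computes, for each predictor, `VIF = 1 / (1 - R^2)` where `R^2` is
#' from regressing that predictor on all the others (complete cases).
#' Orthogonal predictors give VIF exactly 1; perfectly collinear ones
#' give infinite VIF, which is reported as `Inf` together with a
#' warning.
#'
#' @param data Data frame or numeric matrix of predictors (no outcome).
#' @param predictors Optional character vector selecting columns; by
#'   default all columns are used.
#' @return A tibble with columns `term` and `vif`.
#' @export
vif_report <- function(data, predictors = NULL) {
  x <- as.data.frame(data)
  if (!is.null(predictors)) x <- x[, predictors, drop = FALSE]
  x <- x[complete.cases(x), , drop = FALSE]
  if (ncol(x) < 2L) abort("Need at least two predictors for VIF.")
  xm <- as.matrix(x)
  if (!is.numeric(xm)) abort("All predictor columns must be numeric.")
  vifs <- vapply(seq_len(ncol(xm)), function(j) {
    fit <- lm(xm[, j] ~ xm[, -j, drop = FALSE])
    r2 <- summary(fit)$r.squared
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  if (any(!is.finite(vifs))) {
    warn(paste("Perfect collinearity: infinite VIF for",
               paste(colnames(xm)[!is.finite(vifs)], collapse = ", ")))
  }
  tibble(term = colnames(xm), vif = vifs)
}
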