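#' Analysis configuration
#'
#' Declares which analyses the pipeline runs: the four single-value
#' scores as outcomes, the candidate covariates screened at
#' `screening_alpha`, whether scanner site enters the adjusted models,
#' and the subgroup roster.
#'
#' @param outcomes Outcome column names (default: the four scores).
#' @param covariate_candidates Candidate covariates of no interest.
#' @param screening_alpha Covariate-screening significance level.
#' @param screen_rule `"any"`: a covariate is selected if it associates
#'   with any outcome at `screening_alpha` (default); `"per_outcome"`:
#'   selection is outcome-specific.
#' @param site_adjust Include scanner-site dummies in adjusted models.
#' @param subgroups Subgroup labels analysed separately.
#' @param min_subgroup_n Minimum usable rows for a subgroup model.
#' @param focal_outcome Outcome used for subgroup and interaction
#'   analyses; `NULL` picks the outcome with the smallest primary
#'   p-value (the paper's rule: the one significant in the full
#'   sample).
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(outcomes = c("fade_novelty", "same_novelty",
                                         "fade_memory", "same_memory"),
                            covariate_candidates = c("age", "sex",
                                                     "education_years", "isei"),
                            screening_alpha = 0.05,
                            screen_rule = c("any", "per_outcome"),
                            site_adjust = TRUE,
                            subgroups = c("OA", "SCD", "FH"),
                            min_subgroup_n = 10L,
                            focal_outcome = NULL) {
  if (screening_alpha <= 0 || screening_alpha >= 1) {
    abort("`screening_alpha` must lie in (0, 1).")
  }
  structure(list(outcomes = outcomes,
                 covariate_candidates = covariate_candidates,
                 screening_alpha = screening_alpha,
                 screen_rule = match.arg(screen_rule),
                 site_adjust = site_adjust, subgroups = subgroups,
                 min_subgroup_n = as.integer(min_subgroup_n),
                 focal_outcome = focal_outcome),
            class = "analysis_config")
}

# One tabulated row per fitted model, Table-2 style: the EE (or focal
# predictor) coefficient with n, beta and p, plus the fit object.
fiml_row <- function(fit, sample, outcome, adjustment, focal = "ee_score") {
  co <- fit$coefficients[fit$coefficients$term == focal, ]
  tibble(sample = sample, outcome = outcome, adjustment = adjustment,
         n = fit$n, n_complete = fit$n_complete,
         beta = co$estimate, se = co$std.error, p.value = co$p.value,
         converged = fit$converged, fit = list(fit))
}

#' Primary regressions: each score on environmental enrichment
#'
#' One FIML simple regression per outcome, all variables z-scored on
#' the full sample in advance so the reported coefficients are
#' standardized betas.
#'
#' @param records Participant tibble with `ee_score` and the outcome
#'   columns.
#' @param config An [analysis_config()].
#' @param se Compute observed-information standard errors (disable for
#'   speed in simulation studies).
#' @return A tibble with one row per outcome (`sample`, `outcome`,
#'   `adjustment`, `n`, `n_complete`, `beta`, `se`, `p.value`,
#'   `converged`) and the full `fiml_result` in the `fit` list-column.
#' @export
run_primary <- function(records, config = analysis_config(), se = TRUE) {
  usable <- rowSums(!is.na(records[, c("ee_score", config$outcomes)])) > 0
  if (sum(usable) < 10L) abort("Fewer than 10 usable rows.")
  purrr::map_dfr(config$outcomes, function(oc) {
    fit <- fiml_regression(records, oc, "ee_score", scale = TRUE, se = se)
    fiml_row(fit, "all", oc, "unadjusted")
  })
}

#' Subgroup regressions with within-group scaling
#'
#' Re-fits the focal regression separately in each subgroup, z-scoring
#' the variables within the subgroup so betas reflect subgroup-specific
#' variation. Subgroups with fewer than `min_subgroup_n` usable rows
#' are skipped with a warning.
#'
#' @inheritParams run_primary
#' @param outcome The focal outcome (the one significant in the full
#'   sample).
#' @return A tibble like [run_primary()]'s with one row per subgroup.
#' @export
run_subgroups <- function(records, config = analysis_config(),
                          outcome, se = TRUE) {
  purrr::map_dfr(config$subgroups, function(g) {
    sub <- records[records$subgroup == g, , drop = FALSE]
    usable <- rowSums(!is.na(sub[, c("ee_score", outcome)])) > 0
    if (sum(usable) < config$min_subgroup_n) {
      warn(sprintf("Subgroup %s has %d usable rows (< %d); skipped.",
                   g, sum(usable), config$min_subgroup_n))
      return(NULL)
    }
    fit <- fiml_regression(sub, outcome, "ee_score", scale = TRUE, se = se)
    fiml_row(fit, g, outcome, "unadjusted")
  })
}

#' Screen candidate covariates against the outcomes
#'
#' Runs one FIML simple regression of each outcome on each candidate
#' covariate (same estimator as the main models) and selects the
#' covariates with p below `screening_alpha` for at least one outcome
#' (rule `"any"`), or per outcome (rule `"per_outcome"`).
#'
#' @inheritParams run_primary
#' @return A list with `selected` (character vector under rule
#'   `"any"`; named list per outcome otherwise) and `details`, the full
#'   covariate-by-outcome p-value tibble.
#' @export
screen_covariates <- function(records, config = analysis_config()) {
  grid <- tidyr::expand_grid(covariate = config$covariate_candidates,
                             outcome = config$outcomes)
  if (nrow(grid) == 0) {
    return(list(selected = character(0),
                details = tibble(covariate = character(0),
                                 outcome = character(0),
                                 beta = numeric(0), p.value = numeric(0))))
  }
  details <- purrr::pmap_dfr(grid, function(covariate, outcome) {
    fit <- fiml_regression(records, outcome, covariate, scale = TRUE)
    co <- fit$coefficients[fit$coefficients$term == covariate, ]
    tibble(covariate = covariate, outcome = outcome,
           beta = co$estimate, p.value = co$p.value)
  })
  if (config$screen_rule == "any") {
    sel <- details |>
      dplyr::group_by(.data$covariate) |>
      dplyr::summarise(min_p = min(.data$p.value)) |>
      dplyr::filter(.data$min_p < config$screening_alpha)
    selected <- sel$covariate
  } else {
    selected <- details |>
      dplyr::filter(.data$p.value < config$screening_alpha) |>
      dplyr::group_by(.data$outcome) |>
      dplyr::summarise(cov = list(.data$covariate)) |>
      (\(d) setNames(d$cov, d$outcome))()
  }
  list(selected = selected, details = details)
}

# Treatment-coded site dummies with the largest site as reference;
# sites with a single participant are dropped with a warning.
site_dummies <- function(records) {
  tab <- sort(table(records$site), decreasing = TRUE)
  singles <- names(tab)[tab < 2L]
  if (length(singles) > 0) {
    warn(paste("Dropping site dummy for single-participant site(s):",
               paste(singles, collapse = ", ")))
  }
  lev <- setdiff(names(tab)[tab >= 2L], names(tab)[1L])
  out <- records
  cols <- character(0)
  for (s in lev) {
    cl <- paste0("site_", s)
    out[[cl]] <- as.numeric(records$site == s)
    cols <- c(cols, cl)
  }
  list(records = out, columns = cols)
}

#' Covariate-adjusted regressions with multicollinearity diagnostics
#'
#' Refits the score-on-enrichment FIML regressions with the screened
#' covariates (and, optionally, scanner-site dummies) as additional
#' predictors, and computes variance inflation factors on each adjusted
#' design (complete cases).
#'
#' @inheritParams run_primary
#' @param covariates Character vector of covariates selected by
#'   [screen_covariates()].
#' @param site Include site dummies (defaults to the config flag).
#' @param sample Label for the tabulated rows.
#' @param outcomes Outcomes to adjust; defaults to all configured.
#' @return A tibble like [run_primary()]'s with one row per outcome and
#'   a `vif` list-column holding each model's [vif_report()].
#' @export
run_adjusted <- function(records, config = analysis_config(), covariates,
                         site = config$site_adjust, sample = "all",
                         outcomes = config$outcomes, se = TRUE) {
  sd_cols <- character(0)
  if (site) {
    sd_res <- site_dummies(records)
    records <- sd_res$records
    sd_cols <- sd_res$columns
  }
  purrr::map_dfr(outcomes, function(oc) {
    preds <- c("ee_score", covariates, sd_cols)
    fit <- fiml_regression(records, oc, preds, scale = TRUE, se = se)
    row <- fiml_row(fit, sample, oc, "adjusted")
    row$vif <- if (length(preds) >= 2L) {
      list(vif_report(records, preds))
    } else {
      list(NULL)
    }
    row
  })
}
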