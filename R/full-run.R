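#' Derive reproducible stage seeds from one master seed
#'
#' @param seed Master integer seed.
#' @param n Number of stage seeds.
#' @return Integer vector of length `n`.
#' @keywords internal
derive_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Run the whole study end to end on a synthetic cohort
#'
#' Executes every stage in order: simulate the older cohort's latents
#' and demographics; generate LEQ responses and blank items at random;
#' score them into the environmental-enrichment (EE) score; simulate
#' young reference and older contrast maps (fast path); derive the
#' young reference model and compute the four FADE/SAME scores; test
#' the LEQ missingness for MCAR; then run the full analysis roster —
#' four primary FIML regressions, subgroup models with within-group
#' scaling, the slope-heterogeneity F-test, covariate screening, and
#' covariate-(plus site-)adjusted models with VIF diagnostics — and
#' assemble scatter data (complete-case points, FIML-derived lines)
#' for the focal outcome.
#'
#' @param sim A [sim_config()].
#' @param analysis An [analysis_config()].
#' @param seed Master seed; every random stage derives its own seed
#'   from it, so equal seeds give identical reports.
#' @param out_dir If non-`NULL`, result tables (TSV), a JSON report, the
#'   participant CSV and a run log are written there via
#'   [write_report()].
#' @param se Compute FIML standard errors (disable to speed up
#'   simulation studies; p-values are then unavailable and the focal
#'   outcome falls back to the largest |beta|).
#' @return An object of class `fadesame_report`; see [tidy()] /
#'   [glance()] methods and [plot_enrichment_scatter()].
#' @export
full_run <- function(sim = sim_config(), analysis = analysis_config(),
                     seed = sim$seed, out_dir = NULL, se = TRUE) {
  seeds <- derive_seeds(seed, 5L)
  stage <- function(what, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("Pipeline stage '%s' failed: %s", what,
                    conditionMessage(e)))
    })
  }

  participants <- stage("simulate", simulate_participants(sim, seeds[1]))
  records <- stage("leq", {
    r <- generate_leq_responses(participants, seeds[2])
    inject_mcar(r, sim$mcar_rate, seeds[3])
  })
  records <- stage("score-leq", score_leq(records))

  topo <- make_topography(sim)
  reference <- stage("reference", {
    young <- simulate_tmaps(sim, NULL, topo, seeds[4])
    derive_reference(young, threshold = 0.001)
  })
  records <- stage("fade-same", {
    old_maps <- simulate_tmaps(sim, participants, topo, seeds[5])
    score_cohort(old_maps, reference, records)
  })

  leq_cols <- paste0("leq_", rep(leq_activities, 2), "_",
                     rep(c("early", "mid"), each = 6))
  mcar <- if (anyNA(records[, leq_cols])) {
    stage("mcar-test", little_mcar_test(records[, leq_cols]))
  }

  primary <- stage("analyze", run_primary(records, analysis, se = se))
  focal <- analysis$focal_outcome %||%
    if (se) primary$outcome[which.min(primary$p.value)] else
      primary$outcome[which.max(abs(primary$beta))]
  subgroup <- stage("analyze", run_subgroups(records, analysis, focal, se = se))
  interact <- stage("analyze",
                    interaction_ftest(records, "subgroup", "ee_score", focal))
  screening <- stage("analyze", screen_covariates(records, analysis))
  selected <- if (analysis$screen_rule == "any") screening$selected else
    unique(unlist(screening$selected))
  adjusted <- stage("analyze", dplyr::bind_rows(
    run_adjusted(records, analysis, selected, sample = "all", se = se),
    purrr::map_dfr(analysis$subgroups, function(g) {
      sub <- records[records$subgroup == g, , drop = FALSE]
      if (nrow(sub) < analysis$min_subgroup_n) return(NULL)
      run_adjusted(sub, analysis, selected, sample = g, outcomes = focal,
                   se = se)
    })
  ))

  scatter <- stage("analyze", {
    pts <- records[!is.na(records$ee_score) & !is.na(records[[focal]]),
                   c("id", "subgroup", "ee_score", focal)]
    lines <- purrr::map_dfr(c("all", analysis$subgroups), function(g) {
      d <- if (g == "all") records else
        records[records$subgroup == g, , drop = FALSE]
      fit <- fiml_regression(d, focal, "ee_score", scale = FALSE, se = FALSE)
      tibble(sample = g,
             intercept = fit$coefficients$estimate[1],
             slope = fit$coefficients$estimate[2])
    })
    list(points = pts, lines = lines)
  })

  report <- structure(
    list(seed = seed, sim_config = sim, analysis_config = analysis,
         config_hash = rlang::hash(list(sim = unclass(sim),
                                        analysis = unclass(analysis))),
         records = records, reference = reference, mcar = mcar,
         primary = primary, focal_outcome = focal, subgroup = subgroup,
         interaction = interact, screening = screening, adjusted = adjusted,
         scatter = scatter),
    class = "fadesame_report"
  )
  check_census(report)
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

# Every declared (sample, outcome, adjustment) combination must appear
# exactly once across the model tables.
check_census <- function(report) {
  rows <- dplyr::bind_rows(
    report$primary[, c("sample", "outcome", "adjustment")],
    report$subgroup[, c("sample", "outcome", "adjustment")],
    report$adjusted[, c("sample", "outcome", "adjustment")]
  )
  if (anyDuplicated(rows)) {
    abort("Duplicate analysis rows in the report (census violation).")
  }
  cfg <- report$analysis_config
  expected <- length(cfg$outcomes) +                 # primary
    nrow(report$subgroup) +                          # realized subgroup rows
    nrow(report$adjusted)
  if (nrow(rows) != expected) {
    abort("Analysis census mismatch between config and report.")
  }
  invisible(report)
}

#' @export
print.fadesame_report <- function(x, ...) {
  cat(sprintf("End-to-end run (seed %d, config %s)\n", x$seed, x$config_hash))
  if (!is.null(x$mcar)) {
    cat(sprintf("  Little's MCAR test: chi-square = %.2f, df = %d, p = %.3f\n",
                x$mcar$statistic, x$mcar$df, x$mcar$p.value))
  }
  cat("  Primary regressions (standardized beta of EE):\n")
  p <- x$primary
  for (i in seq_len(nrow(p))) {
    cat(sprintf("    %-13s beta = %6.3f  p = %.4f  (n = %d)\n",
                p$outcome[i], p$beta[i], p$p.value[i], p$n[i]))
  }
  cat(sprintf("  Focal outcome: %s; interaction F(%d, %d) = %.2f, p = %.3f\n",
              x$focal_outcome, x$interaction$df1, x$interaction$df2,
              x$interaction$statistic, x$interaction$p.value))
  sel <- x$screening$selected
  cat(sprintf("  Screened covariates: %s\n",
              if (length(sel) == 0) "(none)" else
                paste(unlist(sel), collapse = ", ")))
  invisible(x)
}

#' @export
tidy.fadesame_report <- function(x, ...) {
  dplyr::bind_rows(x$primary, x$subgroup, x$adjusted) |>
    dplyr::select(!dplyr::any_of(c("fit", "vif")))
}

#' @export
glance.fadesame_report <- function(x, ...) {
  tibble(seed = x$seed, n_old = nrow(x$records),
         n_models = nrow(x$primary) + nrow(x$subgroup) + nrow(x$adjusted),
         focal_outcome = x$focal_outcome,
         mcar_p = if (is.null(x$mcar)) NA_real_ else x$mcar$p.value,
         interaction_p = x$interaction$p.value)
}
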