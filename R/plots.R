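#' Scatter plot of enrichment against the focal score
#'
#' Mirrors the separation the FIML approach implies: the points are the
#' complete cases, while the regression lines use the intercept and
#' slope estimated by FIML from all (partially observed) rows — they
#' are not a least-squares fit of the plotted points.
#'
#' @param report A `fadesame_report` from [full_run()].
#' @param by_subgroup If `TRUE`, facet by subgroup with subgroup-
#'   specific FIML lines; otherwise one panel with the full-sample
#'   line.
#' @return A ggplot object.
#' @export
plot_enrichment_scatter <- function(report, by_subgroup = FALSE) {
  pts <- report$scatter$points
  focal <- report$focal_outcome
  lines <- report$scatter$lines
  p <- ggplot2::ggplot(pts, ggplot2::aes(x = .data$ee_score,
                                         y = .data[[focal]])) +
    ggplot2::geom_point(alpha = 0.6, size = 1.4) +
    ggplot2::labs(x = "Environmental enrichment score (0-60)",
                  y = paste(focal, "(t-scale)"),
                  caption = "Points: complete cases; line: FIML fit") +
    ggplot2::theme_minimal()
  if (by_subgroup) {
    sub_lines <- lines[lines$sample != "all", ]
    names(sub_lines)[names(sub_lines) == "sample"] <- "subgroup"
    p + ggplot2::facet_wrap(~subgroup) +
      ggplot2::geom_abline(data = sub_lines,
                           ggplot2::aes(intercept = .data$intercept,
                                        slope = .data$slope),
                           colour = "steelblue")
  } else {
    all_line <- lines[lines$sample == "all", ]
    p + ggplot2::geom_abline(intercept = all_line$intercept,
                             slope = all_line$slope, colour = "steelblue")
  }
}

#' @export
autoplot.fadesame_report <- function(object, by_subgroup = FALSE, ...) {
  plot_enrichment_scatter(object, by_subgroup = by_subgroup)
}

#' Coefficient plot of a set of fitted models
#'
#' Standardized betas of the focal predictor with normal-approximation
#' 95 percent intervals, one row per (sample, outcome, adjustment).
#'
#' @param report A `fadesame_report`.
#' @return A ggplot object.
#' @export
plot_coefficients <- function(report) {
  d <- tidy(report)
  d$label <- paste(d$sample, d$outcome, d$adjustment)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$beta, y = .data$label)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$beta - 1.96 * .data$se,
                   xmax = .data$beta + 1.96 * .data$se),
      height = 0.2
    ) +
    ggplot2::labs(x = "Standardized beta (EE)", y = NULL) +
    ggplot2::theme_minimal()
}
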