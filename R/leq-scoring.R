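#' @name leq_scoring
#' @title Scoring the lifetime leisure-activity questionnaire
#'
#' @description
#' The non-specific part of the Lifetime of Experiences Questionnaire
#' (LEQ) records how frequently a person engaged in six leisure
#' activities — social, musical, artistic, physical activity, reading,
#' and speaking an additional language — during two life stages: early
#' life (13–30 years) and midlife (30–65 years). Each item is answered
#' on a six-point frequency scale and scored 0–5 points (daily = 5,
#' weekly = 4, twice per month = 3, monthly = 2, less than monthly = 1,
#' never = 0). The six item scores of a stage sum to a stage subscore
#' (0–30), and the two subscores sum to the environmental-enrichment
#' (EE) score (0–60). A travel item exists in the questionnaire but
#' never contributes to these scores.
#'
#' Missing policy: any missing contributing item makes the affected
#' subscore — and hence the EE score — missing. No proration or item
#' imputation is applied; incomplete profiles are handled downstream by
#' full-information maximum likelihood ([fiml_regression()]).
NULL

#' Frequency categories of an LEQ item, lowest to highest
#' @export
leq_frequency_levels <- c("never", "less_than_monthly", "monthly",
                          "twice_monthly", "weekly", "daily")

#' The six scoring-eligible leisure activities
#' @export
leq_activities <- c("social", "musical", "artistic", "physical",
                    "reading", "additional_language")

#' Convert an LEQ frequency response to points
#'
#' Maps frequency categories to 0–5 points (`never` = 0 … `daily` = 5).
#' Vectorised; accepts category labels, or integers 0–5 which are
#' passed through (robust CSV ingestion). `NA` stays `NA`; any other
#' value is an error naming the offending entry.
#'
#' @param frequency Character or integer vector of responses.
#' @return Integer vector of points in 0–5, with `NA` preserved.
#' @examples
#' score_leq_item(c("daily", "never", "twice_monthly", NA))
#' @export
score_leq_item <- function(frequency) {
  if (is.numeric(frequency)) {
    bad <- !is.na(frequency) &
      (frequency %% 1 != 0 | frequency < 0 | frequency > 5)
    if (any(bad)) {
      abort(paste("Invalid numeric LEQ response(s):",
                  paste(unique(frequency[bad]), collapse = ", ")))
    }
    return(as.integer(frequency))
  }
  frequency <- as.character(frequency)
  pts <- match(frequency, leq_frequency_levels) - 1L
  bad <- is.na(pts) & !is.na(frequency)
  if (any(bad)) {
    abort(paste("Unrecognized LEQ frequency value(s):",
                paste(unique(frequency[bad]), collapse = ", ")))
  }
  pts
}

#' Subscore of one life stage
#'
#' Sums the item points of the six scoring-eligible activities for one
#' life stage. The input must cover exactly the six activities in
#' [leq_activities] (travel is excluded before this point); a named
#' vector is checked against that set, an unnamed length-6 vector is
#' accepted as already ordered.
#'
#' @param items Named (by activity) or unnamed length-6 vector of
#'   frequency responses (labels or 0–5 integers).
#' @return Integer subscore in 0–30, or `NA` if any item is missing.
#' @examples
#' leq_stage_subscore(rep("daily", 6))
#' @export
leq_stage_subscore <- function(items) {
  if (length(items) != 6L) {
    abort("A stage subscore needs exactly six activity responses.")
  }
  if (!is.null(names(items))) {
    if (!setequal(names(items), leq_activities)) {
      abort(paste("Activity set must be exactly:",
                  paste(leq_activities, collapse = ", ")))
    }
    items <- items[leq_activities]
  }
  pts <- score_leq_item(items)
  if (anyNA(pts)) return(NA_integer_)
  as.integer(sum(pts))
}

#' Score LEQ responses into subscores and the EE score
#'
#' Data-frame-first scoring of the whole cohort. The input must carry
#' the twelve scoring columns `leq_<activity>_<stage>` with
#' `<activity>` in [leq_activities] and `<stage>` in `early`, `mid`;
#' travel columns (`leq_travel_early`, `leq_travel_mid`), if present,
#' are ignored. Appends `early_subscore`, `mid_subscore` and
#' `ee_score`; any missing contributing item makes the affected
#' subscore and the EE score `NA`.
#'
#' @param data Data frame with the LEQ item columns (labels or 0–5
#'   integers).
#' @return The input as a tibble with the three score columns appended
#'   (replaced if already present).
#' @examples
#' d <- tibble::as_tibble(setNames(
#'   as.list(rep(5L, 12)),
#'   paste0("leq_", rep(leq_activities, 2), "_",
#'          rep(c("early", "mid"), each = 6))))
#' score_leq(d)$ee_score
#' @export
score_leq <- function(data) {
  data <- as_tibble(data)
  sub <- function(stage) {
    cols <- paste0("leq_", leq_activities, "_", stage)
    missing_cols <- setdiff(cols, colnames(data))
    if (length(missing_cols) > 0) {
      abort(paste("Missing LEQ column(s):",
                  paste(missing_cols, collapse = ", ")))
    }
    pts <- vapply(cols, function(cl) as.numeric(score_leq_item(data[[cl]])),
                  numeric(nrow(data)))
    pts <- matrix(pts, nrow = nrow(data))
    out <- rowSums(pts)            # NA if any item missing
    as.integer(out)
  }
  data$early_subscore <- sub("early")
  data$mid_subscore <- sub("mid")
  data$ee_score <- data$early_subscore + data$mid_subscore
  data
}
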