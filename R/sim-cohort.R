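# Ordinal draws from a cumulative-logit model with equally spaced (or
# explicitly given) thresholds: latent = shift + logistic noise / disc,
# response = number of thresholds below the latent (0-based).
draw_ordinal <- function(shift, thresholds, disc) {
  latent <- shift + rlogis(length(shift)) / disc
  findInterval(latent, thresholds)
}

# Frozen constants of the LEQ item response model. Calibrated once so
# the simulated cohort matches realistic enrichment descriptives
# (EE mean ~ 34, SD ~ 8 over a 0-60 range); see the methods vignette.
leq_item_model <- list(
  center = -0.55, spacing = 1.5, disc = 3,
  offsets = c(social = -0.7, physical = -0.3, reading = -0.9,
              musical = 0.5, artistic = 0.7, additional_language = 1.1,
              travel = 0.2)
)

conf_rating_model <- list(thresholds = c(-1.5, -0.5, 0.5, 1.5), disc = 2)

#' Simulate the older cohort's latent traits and demographics
#'
#' Draws one row per older participant: subgroup membership, the
#' latent traits that drive the generated data (preservation of the
#' young activation pattern, enrichment propensity, memory ability) and
#' demographic covariates (age, sex, education years, ISEI, scanner
#' site). The enrichment–brain coupling follows `config$wire`:
#' with `"preservation"` the enrichment propensity and the preservation
#' latent are bivariate normal with correlation `effect_beta`; with
#' `"same_novelty"` the preservation latent is independent of
#' enrichment and the coupling instead acts through a selective map
#' perturbation applied by [simulate_tmaps()]. The SCD subgroup's
#' preservation latent is mean-shifted by `config$scd_shift`.
#'
#' Demographics are drawn independently of the latents unless the
#' confounding knobs (`confound_age_ee`, `confound_age_pres`) are set,
#' in which case standardized age feeds the respective latent with the
#' given path weight (latents are rescaled to keep unit variance).
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; defaults to `config$seed`.
#' @return A tibble with columns `id`, `subgroup`, `preservation_z`,
#'   `ee_propensity_z`, `memory_ability`, `age`, `sex` (0 = male,
#'   1 = female), `education_years`, `isei`, `site`.
#' @export
simulate_participants <- function(config, seed = config$seed) {
  set.seed(seed)
  n <- config$n_old
  subgroup <- sample(names(config$subgroup_props), n, replace = TRUE,
                     prob = config$subgroup_props)

  age <- pmin(pmax(rnorm(n, 69.45, 5.77), 60), 87)
  age_z <- (age - mean(age)) / sd(age)

  mix <- function(noise, path) {
    if (path == 0) noise else sqrt(1 - path^2) * noise + path * age_z
  }
  ee_raw <- mix(rnorm(n), config$confound_age_ee)
  if (config$wire == "preservation") {
    rho <- config$effect_beta
    pres_noise <- rho * ee_raw + sqrt(1 - rho^2) * rnorm(n)
  } else {
    pres_noise <- rnorm(n)
  }
  pres <- mix(pres_noise, config$confound_age_pres)
  pres <- pres + ifelse(subgroup == "SCD", config$scd_shift, 0)

  tibble(
    id = sprintf("old%03d", seq_len(n)),
    subgroup = subgroup,
    preservation_z = pres,
    ee_propensity_z = ee_raw,
    memory_ability = rnorm(n),
    age = age,
    sex = rbinom(n, 1L, 197 / 372),
    education_years = round(pmin(pmax(rnorm(n, 14.91, 2.9), 8), 20)),
    isei = pmin(pmax(rnorm(n, 61.13, 17), 16), 90),
    site = sample(sprintf("S%d", seq_len(config$n_sites)), n, replace = TRUE,
                  prob = seq(config$n_sites, 1) / sum(seq_len(config$n_sites)))
  )
}

#' Generate LEQ item responses from the enrichment propensity
#'
#' Draws, for each participant, the twelve scoring-eligible LEQ items
#' (six leisure activities for each of the early-life and midlife
#' stages) plus the two travel items, from a cumulative-logit ordinal
#' model whose latent is the participant's enrichment propensity.
#' Responses are integer frequency codes 0–5 (never … daily), the
#' scale accepted by [score_leq()].
#'
#' @param participants Tibble from [simulate_participants()] (needs
#'   `ee_propensity_z`).
#' @param seed Integer seed.
#' @return The input tibble with columns `leq_<activity>_<stage>` for
#'   the six activities plus travel, stages `early` and `mid`.
#' @export
generate_leq_responses <- function(participants, seed = 1L) {
  set.seed(seed)
  m <- leq_item_model
  z <- participants$ee_propensity_z
  out <- participants
  for (stage in c("early", "mid")) {
    for (act in c(leq_activities, "travel")) {
      tau <- m$center + m$offsets[[act]] + ((1:5) - 3) * m$spacing
      out[[paste0("leq_", act, "_", stage)]] <-
        as.integer(draw_ordinal(z, tau, m$disc))
    }
  }
  out
}

#' Blank LEQ items completely at random
#'
#' Selects participants independently with probability `mcar_rate`;
#' each selected participant loses a uniform number (1–12) of their
#' twelve scoring items at uniformly random positions. The mechanism
#' never looks at any data value, so the induced missingness is MCAR by
#' construction.
#'
#' @param data Tibble with the twelve scoring columns
#'   `leq_<activity>_<stage>`.
#' @param mcar_rate Probability a participant is affected, in [0, 1].
#' @param seed Integer seed.
#' @return `data` with `NA`s injected; the logical missingness mask
#'   (rows x 12 items) is attached as attribute `"mcar_mask"`.
#' @export
inject_mcar <- function(data, mcar_rate, seed = 1L) {
  if (mcar_rate < 0 || mcar_rate > 1) abort("`mcar_rate` must lie in [0, 1].")
  set.seed(seed)
  cols <- paste0("leq_", rep(leq_activities, times = 2), "_",
                 rep(c("early", "mid"), each = 6))
  missing_cols <- setdiff(cols, colnames(data))
  if (length(missing_cols) > 0) {
    abort(paste("Missing LEQ column(s):", paste(missing_cols, collapse = ", ")))
  }
  n <- nrow(data)
  mask <- matrix(FALSE, n, length(cols), dimnames = list(NULL, cols))
  affected <- which(runif(n) < mcar_rate)
  for (i in affected) {
    n_miss <- sample.int(12L, 1L)
    mask[i, sample.int(12L, n_miss)] <- TRUE
  }
  for (j in seq_along(cols)) {
    v <- data[[cols[j]]]
    v[mask[, j]] <- NA
    data[[cols[j]]] <- v
  }
  attr(data, "mcar_mask") <- mask
  data
}
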