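#' Simulate per-participant contrast t-maps (fast path)
#'
#' Generates voxelwise t-maps directly on the toy grid, bypassing BOLD
#' simulation and GLM fitting. Young reference maps are the
#' ground-truth topography plus white noise. An older participant's map
#' is the topography multiplied by the preservation shrink
#' ([preservation_shrink()]) of their latent, plus noise — so higher
#' preservation means a map closer to the young pattern on both
#' contrasts.
#'
#' When `config$wire == "same_novelty"`, an additional selective
#' perturbation proportional to the enrichment propensity is added to
#' the novelty maps: it deepens (or shallows) the deactivation block
#' while compensating on neutral network voxels so the network means
#' entering the FADE score are unchanged. Its gain is calibrated in
#' closed form (see [wiring_gain()]) so the standardized association
#' between the enrichment propensity and the novelty SAME score equals
#' `config$effect_beta`.
#'
#' @param config A [sim_config()].
#' @param participants Tibble from [simulate_participants()] for the
#'   older cohort, or `NULL` to generate the young reference cohort.
#' @param topography A [make_topography()] result on the same grid.
#' @param seed Integer seed.
#' @return An object of class `cohort_maps`: list with `ids`,
#'   `grid_dims`, `mask`, and `tmaps`, a list of two `n x n_voxel`
#'   matrices named `novelty` and `memory` (voxels in array order over
#'   the full grid).
#' @export
simulate_tmaps <- function(config, participants = NULL,
                           topography = make_topography(config),
                           seed = config$seed) {
  if (!identical(as.integer(topography$grid_dims), config$grid_dims)) {
    abort("Topography grid does not match `config$grid_dims`.")
  }
  set.seed(seed)
  nv <- prod(config$grid_dims)
  young <- is.null(participants)
  n <- if (young) config$n_young else nrow(participants)
  ids <- if (young) sprintf("young%03d", seq_len(n)) else participants$id

  shrink <- if (young) rep(1, n) else {
    preservation_shrink(participants$preservation_z, config)
  }
  tmaps <- list()
  for (con in c("novelty", "memory")) {
    a <- as.vector(topography[[con]])
    m <- tcrossprod(shrink, a) +
      matrix(rnorm(n * nv, sd = config$noise_sd_map), n, nv)
    tmaps[[con]] <- m
  }
  if (!young && config$wire == "same_novelty" && config$effect_beta != 0) {
    d <- wiring_direction(topography)
    gain <- wiring_gain(config, topography)
    tmaps$novelty <- tmaps$novelty +
      tcrossprod(gain * config$noise_sd_map * participants$ee_propensity_z, d)
  }
  structure(
    list(ids = ids, grid_dims = config$grid_dims, mask = topography$mask,
         tmaps = tmaps),
    class = "cohort_maps"
  )
}

# Unit perturbation direction for the selective novelty-SAME wiring:
# -1 on the true deactivation block, a compensating constant on neutral
# network voxels (so the mean over mask-minus-activation is unchanged,
# leaving FADE untouched), 0 on the activation block and outside the
# network.
wiring_direction <- function(topography) {
  neg <- as.vector(topography$novelty_neg)
  neutral <- as.vector(topography$mask & !topography$novelty_pos &
                         !topography$novelty_neg)
  d <- numeric(length(neg))
  d[neg] <- -1
  d[neutral] <- sum(neg) / sum(neutral)
  d
}

#' Calibrated gain of the selective enrichment wiring
#'
#' Computes, in closed form, the gain that makes the standardized
#' association between the enrichment propensity and the novelty SAME
#' score equal `effect_beta` under the generator model. The novelty
#' SAME score decomposes into a preservation-shrink component with
#' variance `K^2 * var(shrink)` (`K` = summed absolute block amplitudes
#' over the noise SD), a map-noise component with variance
#' `1/|V+| + 1/|V-|`, and the wired component `gain * z`; solving
#' `corr = effect_beta` gives
#' `gain = effect_beta * sqrt(v0 / (1 - effect_beta^2))` with `v0` the
#' unwired variance. `var(shrink)` is integrated numerically over the
#' subgroup mixture of the preservation latent.
#'
#' @param config A [sim_config()].
#' @param topography A [make_topography()] result.
#' @return The scalar gain (SD units of the map noise per unit latent).
#' @export
wiring_gain <- function(config, topography) {
  rho <- config$effect_beta
  if (rho == 0) return(0)
  z <- seq(-8, 8, by = 0.005)
  dens <- numeric(length(z))
  for (g in names(config$subgroup_props)) {
    mu <- if (g == "SCD") config$scd_shift else 0
    dens <- dens + config$subgroup_props[[g]] * stats::dnorm(z, mu, 1)
  }
  dens <- dens / sum(dens)
  s <- preservation_shrink(z, config)
  var_g <- sum(dens * s^2) - sum(dens * s)^2
  k <- (config$amp_novelty[1] + abs(config$amp_novelty[2])) / config$noise_sd_map
  v0 <- k^2 * var_g +
    1 / sum(topography$novelty_pos) + 1 / sum(topography$novelty_neg)
  rho * sqrt(v0 / (1 - rho^2))
}

#' Extract one participant's map as a 3-D array
#'
#' @param maps A `cohort_maps` object.
#' @param id Participant id.
#' @param contrast `"novelty"` or `"memory"`.
#' @return A 3-D numeric array on the grid.
#' @export
as_contrast_map <- function(maps, id, contrast = c("novelty", "memory")) {
  contrast <- match.arg(contrast)
  i <- match(id, maps$ids)
  if (is.na(i)) abort(sprintf("Unknown participant id '%s'.", id))
  array(maps$tmaps[[contrast]][i, ], dim = maps$grid_dims)
}

#' @export
print.cohort_maps <- function(x, ...) {
  cat(sprintf("Contrast t-maps for %d participants on a %s grid (%d network voxels)\n",
              length(x$ids), paste(x$grid_dims, collapse = "x"), sum(x$mask)))
  invisible(x)
}

#' Simulate a 4-D BOLD time series for one session (slow path)
#'
#' Generates voxelwise BOLD data as design matrix times true betas plus
#' white noise. The true betas encode the novelty topography on the
#' novel-trial regressor (master trials carry no effect, so the
#' novel-minus-master contrast recovers the topography) and the memory
#' topography on the confidence parametric modulator; a constant
#' baseline of 100 loads on the intercept.
#'
#' @param session An [simulate_session()] result.
#' @param topography A [make_topography()] result.
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return A list of class `bold_sim` with `bold` (`n_scans x n_voxel`
#'   matrix), `design` (the design matrix used), `true_betas`
#'   (`n_regressor x n_voxel`), `grid_dims` and `tr_seconds`.
#' @export
simulate_bold <- function(session, topography, config, seed = config$seed) {
  set.seed(seed)
  x <- build_design_matrix(session, design_spec(config))
  nv <- prod(topography$grid_dims)
  b <- matrix(0, ncol(x), nv, dimnames = list(colnames(x), NULL))
  b["novel", ] <- as.vector(topography$novelty)
  b["modulator", ] <- as.vector(topography$memory)
  b["intercept", ] <- 100
  y <- x %*% b
  if (config$noise_sd_bold > 0) {
    y <- y + matrix(rnorm(length(y), sd = config$noise_sd_bold), nrow(y))
  }
  structure(
    list(bold = y, design = x, true_betas = b,
         grid_dims = topography$grid_dims, tr_seconds = config$tr_seconds),
    class = "bold_sim"
  )
}
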