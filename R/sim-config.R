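#' Simulation configuration
#'
#' Bundles every knob of the synthetic-cohort generator. Defaults
#' reproduce the study conditions the pipeline is meant to emulate: a
#' young reference cohort of 106, an older cohort of 372 split into the
#' OA/SCD/FH subgroups (127/199/46), an encoding session of 88 novel
#' photographs plus two master images repeated 22 times each, 44
#' recognition foils, 10 pre-scan familiarization repetitions, and an
#' LEQ missingness rate of 30/372 participants.
#'
#' @param grid_dims Integer vector of voxel counts per axis (toy grid).
#' @param n_young Young reference cohort size.
#' @param n_old Older cohort size.
#' @param subgroup_props Named proportions for the OA, SCD and FH
#'   subgroups; must sum to 1.
#' @param effect_beta Target standardized association between
#'   environmental enrichment and the coupled brain latent (see `wire`).
#' @param wire Where the enrichment–brain coupling acts.
#'   `"preservation"` (default) correlates the enrichment propensity
#'   with the global preservation latent that scales both contrasts, so
#'   all four scores move. `"same_novelty"` couples enrichment to a
#'   selective perturbation of the novelty maps that changes the
#'   novelty SAME score while leaving the novelty FADE score and the
#'   memory contrast untouched, calibrated so the standardized
#'   association with the novelty SAME score equals `effect_beta`.
#' @param mcar_rate Probability that an older participant has at least
#'   one missing LEQ item.
#' @param noise_sd_map SD of the voxelwise noise added to t-maps.
#' @param noise_sd_bold SD of the white noise in simulated BOLD series.
#' @param n_novel Novel trials per session (must be even: categories
#'   are balanced).
#' @param n_master_each Repetitions of each of the two master images.
#' @param n_foils New images in the post-scan recognition test.
#' @param n_familiarization Pre-scan repetitions of the master images.
#' @param tr_seconds Repetition time of the simulated scanner.
#' @param iti_seconds Fixed inter-trial interval (no jitter).
#' @param stim_seconds Stimulus duration recorded in the events table.
#' @param scd_shift Mean shift of the preservation latent in the SCD
#'   subgroup.
#' @param amp_novelty,amp_memory Length-2 `c(positive, negative)`
#'   amplitudes (t units) of the activation and deactivation blocks of
#'   each contrast's ground-truth topography.
#' @param shrink_c0,shrink_c1 Parameters of the preservation shrink
#'   `plogis(c0 + c1 * z)` applied to older participants' topography.
#' @param confound_age_ee,confound_age_pres Optional standardized paths
#'   from age to the enrichment propensity and to the preservation
#'   latent (0 = no confounding, the default).
#' @param n_sites Number of scanner sites.
#' @param seed Default seed used by generator functions when none is
#'   given.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(grid_dims = c(12L, 12L, 12L),
                       n_young = 106L,
                       n_old = 372L,
                       subgroup_props = c(OA = 127, SCD = 199, FH = 46) / 372,
                       effect_beta = 0.13,
                       wire = c("preservation", "same_novelty"),
                       mcar_rate = 30 / 372,
                       noise_sd_map = 1,
                       noise_sd_bold = 1,
                       n_novel = 88L,
                       n_master_each = 22L,
                       n_foils = 44L,
                       n_familiarization = 10L,
                       tr_seconds = 2,
                       iti_seconds = 3,
                       stim_seconds = 2.5,
                       scd_shift = -0.15,
                       amp_novelty = c(3, -2),
                       amp_memory = c(2.5, -1.5),
                       shrink_c0 = 0.5,
                       shrink_c1 = 0.8,
                       confound_age_ee = 0,
                       confound_age_pres = 0,
                       n_sites = 8L,
                       seed = 1L) {
  wire <- match.arg(wire)
  cfg <- list(
    grid_dims = as.integer(grid_dims), n_young = as.integer(n_young),
    n_old = as.integer(n_old), subgroup_props = subgroup_props,
    effect_beta = effect_beta, wire = wire, mcar_rate = mcar_rate,
    noise_sd_map = noise_sd_map, noise_sd_bold = noise_sd_bold,
    n_novel = as.integer(n_novel), n_master_each = as.integer(n_master_each),
    n_foils = as.integer(n_foils),
    n_familiarization = as.integer(n_familiarization),
    tr_seconds = tr_seconds, iti_seconds = iti_seconds,
    stim_seconds = stim_seconds, scd_shift = scd_shift,
    amp_novelty = amp_novelty, amp_memory = amp_memory,
    shrink_c0 = shrink_c0, shrink_c1 = shrink_c1,
    confound_age_ee = confound_age_ee, confound_age_pres = confound_age_pres,
    n_sites = as.integer(n_sites), seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  counts <- c("n_young", "n_old", "n_novel", "n_master_each", "n_foils",
              "n_familiarization", "n_sites")
  for (nm in counts) {
    if (length(cfg[[nm]]) != 1L || is.na(cfg[[nm]]) || cfg[[nm]] <= 0L) {
      abort(sprintf("`%s` must be a positive count.", nm))
    }
  }
  if (length(cfg$grid_dims) != 3L || any(cfg$grid_dims < 8L)) {
    abort("`grid_dims` must give three axes of at least 8 voxels.")
  }
  if (abs(sum(cfg$subgroup_props) - 1) > 1e-8 || any(cfg$subgroup_props < 0)) {
    abort("`subgroup_props` must be non-negative and sum to 1.")
  }
  if (!setequal(names(cfg$subgroup_props), c("OA", "SCD", "FH"))) {
    abort("`subgroup_props` must be named OA, SCD, FH.")
  }
  if (cfg$mcar_rate < 0 || cfg$mcar_rate > 1) {
    abort("`mcar_rate` must lie in [0, 1].")
  }
  if (abs(cfg$effect_beta) > 1) abort("`effect_beta` must lie in [-1, 1].")
  if (cfg$n_novel %% 2L != 0L) {
    abort("`n_novel` must be even so indoor/outdoor categories balance.")
  }
  if (cfg$noise_sd_map < 0 || cfg$noise_sd_bold < 0) {
    abort("Noise SDs must be non-negative.")
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  cat(sprintf("  grid %s, young n = %d, older n = %d (OA/SCD/FH %s)\n",
              paste(x$grid_dims, collapse = "x"), x$n_young, x$n_old,
              paste(round(x$subgroup_props * x$n_old), collapse = "/")))
  cat(sprintf("  session: %d novel + 2 x %d master trials, %d foils, %d familiarizations\n",
              x$n_novel, x$n_master_each, x$n_foils, x$n_familiarization))
  cat(sprintf("  enrichment coupling: beta = %.3g wired to %s; MCAR rate %.3g\n",
              x$effect_beta, x$wire, x$mcar_rate))
  invisible(x)
}

#' Ground-truth topography of the toy brain
#'
#' Builds, on the configured grid, the analysis mask (a central block
#' excluding a one-voxel shell, standing in for the
#' temporo-parieto-occipital network) and the per-contrast amplitude
#' maps: one activation block and one deactivation block per contrast,
#' zero elsewhere, with the novelty and memory contrasts using
#' disjoint block placements.
#'
#' @param config A [sim_config()].
#' @return A list of class `topography` with logical array `mask`,
#'   amplitude arrays `novelty` and `memory`, and for each contrast the
#'   logical arrays of true activation (`*_pos`) and deactivation
#'   (`*_neg`) voxels.
#' @export
make_topography <- function(config) {
  d <- config$grid_dims
  ax <- lapply(d, function(n) {
    inner <- 2:(n - 1L)
    len <- length(inner)
    nb <- max(2L, floor(len * 0.4))
    list(inner = inner, lo = inner[seq_len(nb)],
         hi = inner[(len - nb + 1L):len])
  })
  arr <- function() array(FALSE, dim = d)
  mask <- arr()
  mask[ax[[1]]$inner, ax[[2]]$inner, ax[[3]]$inner] <- TRUE

  nov_pos <- arr(); nov_pos[ax[[1]]$lo, ax[[2]]$lo, ax[[3]]$lo] <- TRUE
  nov_neg <- arr(); nov_neg[ax[[1]]$hi, ax[[2]]$hi, ax[[3]]$hi] <- TRUE
  mem_pos <- arr(); mem_pos[ax[[1]]$lo, ax[[2]]$hi, ax[[3]]$lo] <- TRUE
  mem_neg <- arr(); mem_neg[ax[[1]]$hi, ax[[2]]$lo, ax[[3]]$hi] <- TRUE

  amp <- function(pos, neg, a) {
    x <- array(0, dim = d)
    x[pos] <- a[1]
    x[neg] <- a[2]
    x
  }
  structure(
    list(grid_dims = d, mask = mask,
         novelty = amp(nov_pos, nov_neg, config$amp_novelty),
         memory = amp(mem_pos, mem_neg, config$amp_memory),
         novelty_pos = nov_pos, novelty_neg = nov_neg,
         memory_pos = mem_pos, memory_neg = mem_neg),
    class = "topography"
  )
}

#' Preservation shrink function
#'
#' Maps the preservation latent to the multiplicative shrinkage of an
#' older participant's topography: `plogis(c0 + c1 * z)`, increasing in
#' `z`, with `shrink(0) < 1` at the defaults so the average older adult
#' expresses an attenuated young pattern.
#'
#' @param z Preservation latent values.
#' @param config A [sim_config()] supplying `shrink_c0`, `shrink_c1`.
#' @return Numeric vector in (0, 1).
#' @export
preservation_shrink <- function(z, config) {
  plogis(config$shrink_c0 + config$shrink_c1 * z)
}
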