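#' Construct a reference model for one or both contrasts
#'
#' Low-level constructor holding, per contrast, the young-cohort voxel
#' sets and moments that the FADE and SAME scores are computed against:
#' `vpos` / `vneg` — logical vectors marking voxels where the young
#' cohort shows a positive / negative effect (within the network mask);
#' `m`, `s` — the young sample mean and SD of the t-values per voxel.
#' Normally built by [derive_reference()]; exported so small references
#' can be assembled directly.
#'
#' @param contrasts Named list (names among `novelty`, `memory`), each
#'   element a list with `vpos`, `vneg`, `m`, `s` over all grid voxels.
#' @param mask Logical vector (or array) marking the analysis network.
#' @param grid_dims Grid dimensions.
#' @param n_young Young sample size the moments come from.
#' @param threshold Voxel-selection p threshold used.
#' @return An object of class `reference_model`.
#' @export
reference_model <- function(contrasts, mask, grid_dims = NULL,
                            n_young = NA_integer_, threshold = NA_real_) {
  mask <- as.vector(mask)
  for (nm in names(contrasts)) {
    co <- contrasts[[nm]]
    co$vpos <- as.vector(co$vpos)
    co$vneg <- as.vector(co$vneg)
    if (any(co$vpos & co$vneg)) {
      abort("Positive and negative voxel sets must be disjoint.")
    }
    if (any(co$vpos & !mask) || any(co$vneg & !mask)) {
      abort("Voxel sets must lie within the mask.")
    }
    contrasts[[nm]] <- co
  }
  structure(list(contrasts = contrasts, mask = mask, grid_dims = grid_dims,
                 n_young = n_young, threshold = threshold),
            class = "reference_model")
}

#' Derive the young-cohort reference model
#'
#' For each contrast, runs a voxelwise one-sample t-test of the young
#' participants' t-values against zero and selects, within the network
#' mask, the voxels exceeding the positive critical value at
#' `threshold` (one-sided, uncorrected) as the positive-effect set and
#' those below the negative critical value as the negative-effect set.
#' The voxelwise young sample mean and SD are stored for the SAME
#' score. Zero-variance voxels are excluded from the sets with a
#' warning; an empty set only errors later, in the score that needs it.
#'
#' The function is deterministic: repeated calls on the same maps give
#' identical models.
#'
#' @param young_maps A `cohort_maps` object for the young cohort (from
#'   [simulate_tmaps()] or [read_cohort_maps()]).
#' @param mask Logical array/vector; defaults to the mask carried by
#'   `young_maps`.
#' @param threshold Voxelwise one-sided p threshold (default 0.001).
#' @return A [reference_model()].
#' @export
derive_reference <- function(young_maps, mask = young_maps$mask,
                             threshold = 0.001) {
  mask <- as.vector(mask)
  if (length(mask) != ncol(young_maps$tmaps[[1]])) {
    abort("Mask length does not match the map grid.")
  }
  n <- length(young_maps$ids)
  if (n < 2L) abort("Need at least two young maps.")
  crit <- qt(1 - threshold, df = n - 1L)
  contrasts <- list()
  for (nm in names(young_maps$tmaps)) {
    y <- young_maps$tmaps[[nm]]
    m <- colMeans(y)
    s <- sqrt(colSums(sweep(y, 2L, m)^2) / (n - 1L))
    zero_var <- s == 0
    if (any(zero_var & mask)) {
      warn(sprintf("%s: %d zero-variance voxel(s) excluded from the effect sets.",
                   nm, sum(zero_var & mask)))
    }
    tstat <- ifelse(zero_var, 0, m / (s / sqrt(n)))
    vpos <- mask & !zero_var & tstat > crit
    vneg <- mask & !zero_var & tstat < -crit
    if (!any(vpos) || !any(vneg)) {
      warn(sprintf("%s: empty %s-effect voxel set at threshold %g.", nm,
                   if (!any(vpos)) "positive" else "negative", threshold))
    }
    contrasts[[nm]] <- list(vpos = vpos, vneg = vneg, m = m, s = s)
  }
  reference_model(contrasts, mask, grid_dims = young_maps$grid_dims,
                  n_young = n, threshold = threshold)
}

#' @export
print.reference_model <- function(x, ...) {
  cat(sprintf("Young reference model (n = %s, threshold p < %s)\n",
              x$n_young, format(x$threshold)))
  for (nm in names(x$contrasts)) {
    co <- x$contrasts[[nm]]
    cat(sprintf("  %s: |V+| = %d, |V-| = %d of %d mask voxels\n",
                nm, sum(co$vpos), sum(co$vneg), sum(x$mask)))
  }
  invisible(x)
}

ref_contrast <- function(reference, contrast) {
  co <- reference$contrasts[[contrast]]
  if (is.null(co)) {
    abort(sprintf("Reference model has no '%s' contrast.", contrast))
  }
  co
}

#' FADE score of one contrast map
#'
#' Functional Activity Deviation during Encoding: the mean t-value of
#' the participant's map over the network voxels *outside* the young
#' positive-effect set, minus the mean over the positive-effect set
#' itself. Higher values mean greater deviation from the young
#' activation pattern; a constant map scores exactly 0.
#'
#' @param map 3-D array or numeric vector of t-values on the reference
#'   grid.
#' @param reference A [reference_model()].
#' @param contrast Which contrast's reference to use.
#' @return A single number.
#' @export
fade_score <- function(map, reference, contrast = "novelty") {
  co <- ref_contrast(reference, contrast)
  t <- as.vector(map)
  if (length(t) != length(reference$mask)) {
    abort("Map does not match the reference grid.")
  }
  outside <- reference$mask & !co$vpos
  if (!any(co$vpos)) abort("Empty positive-effect voxel set.")
  if (!any(outside)) abort("No network voxels outside the positive-effect set.")
  mean(t[outside]) - mean(t[co$vpos])
}

#' SAME score of one contrast map
#'
#' Similarity of Activations during Memory Encoding: the sum of the
#' mean standardized deviation from the young mean over the young
#' positive-effect voxels, `mean((t - m) / s)`, and over the young
#' negative-effect voxels, `mean((m - t) / s)`. Deviations are signed
#' and standardized by the per-voxel young SD, so reduced activations
#' and reduced deactivations both lower the score, a map equal to the
#' young mean scores exactly 0, and a super-young pattern scores
#' positive.
#'
#' @inheritParams fade_score
#' @return A single number.
#' @export
same_score <- function(map, reference, contrast = "novelty") {
  co <- ref_contrast(reference, contrast)
  t <- as.vector(map)
  if (length(t) != length(reference$mask)) {
    abort("Map does not match the reference grid.")
  }
  if (!any(co$vpos) || !any(co$vneg)) {
    abort("Empty positive- or negative-effect voxel set.")
  }
  used <- co$vpos | co$vneg
  if (any(co$s[used] == 0)) {
    abort(paste("Zero young SD at voxel(s):",
                paste(which(used & co$s == 0), collapse = ", ")))
  }
  mean((t[co$vpos] - co$m[co$vpos]) / co$s[co$vpos]) +
    mean((co$m[co$vneg] - t[co$vneg]) / co$s[co$vneg])
}

#' Score a whole cohort on both contrasts
#'
#' Computes the four single-value scores (`fade_novelty`,
#' `same_novelty`, `fade_memory`, `same_memory`) for every participant
#' in a `cohort_maps` object, vectorised over participants. If a
#' participant table is supplied the scores are joined onto it by `id`;
#' participants without maps keep `NA` scores and are flagged.
#'
#' @param maps A `cohort_maps` object for the older cohort.
#' @param reference A [reference_model()] with both contrasts.
#' @param participants Optional tibble with an `id` column to join the
#'   scores onto.
#' @return A tibble of scores (one row per participant).
#' @export
score_cohort <- function(maps, reference, participants = NULL) {
  out <- tibble(id = maps$ids)
  for (nm in c("novelty", "memory")) {
    co <- ref_contrast(reference, nm)
    if (!any(co$vpos) || !any(co$vneg)) {
      abort(sprintf("%s: empty effect voxel set; cannot score.", nm))
    }
    y <- maps$tmaps[[nm]]
    outside <- reference$mask & !co$vpos
    fade <- rowMeans(y[, outside, drop = FALSE]) -
      rowMeans(y[, co$vpos, drop = FALSE])
    zp <- sweep(sweep(y[, co$vpos, drop = FALSE], 2L, co$m[co$vpos]),
                2L, co$s[co$vpos], "/")
    zn <- sweep(sweep(-y[, co$vneg, drop = FALSE], 2L, -co$m[co$vneg]),
                2L, co$s[co$vneg], "/")
    out[[paste0("fade_", nm)]] <- fade
    out[[paste0("same_", nm)]] <- rowMeans(zp) + rowMeans(zn)
  }
  if (!is.null(participants)) {
    out <- dplyr::left_join(as_tibble(participants), out, by = "id")
    miss <- !participants$id %in% maps$ids
    if (any(miss)) {
      warn(sprintf("%d participant(s) without maps; scores set to NA.",
                   sum(miss)))
    }
  }
  out
}
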