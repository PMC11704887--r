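#' Write and read the participant table
#'
#' One row per participant, missing entries empty.
#'
#' @param records Participant tibble.
#' @param path CSV path.
#' @return `write_participants` returns `path` invisibly;
#'   `read_participants` returns a tibble.
#' @export
write_participants <- function(records, path) {
  readr::write_csv(records, path, na = "")
  invisible(path)
}

#' @rdname write_participants
#' @export
read_participants <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' Write and read cohort contrast maps as NIfTI volumes
#'
#' One `{id}_{contrast}_tmap.nii.gz` file per participant and contrast,
#' plus `mask.nii.gz` with integer labels (0 = outside, 1 = network).
#'
#' @param maps A `cohort_maps` object.
#' @param dir Output directory (created if needed).
#' @return `write_cohort_maps` returns `dir` invisibly;
#'   `read_cohort_maps` returns a `cohort_maps` object.
#' @export
write_cohort_maps <- function(maps, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  RNifti::writeNifti(array(as.integer(maps$mask), dim = maps$grid_dims),
                     file.path(dir, "mask.nii.gz"))
  for (con in names(maps$tmaps)) {
    for (i in seq_along(maps$ids)) {
      RNifti::writeNifti(
        array(maps$tmaps[[con]][i, ], dim = maps$grid_dims),
        file.path(dir, sprintf("%s_%s_tmap.nii.gz", maps$ids[i], con))
      )
    }
  }
  invisible(dir)
}

#' @rdname write_cohort_maps
#' @export
read_cohort_maps <- function(dir) {
  mask <- RNifti::readNifti(file.path(dir, "mask.nii.gz"))
  grid_dims <- dim(mask)
  files <- list.files(dir, pattern = "_tmap\\.nii\\.gz$")
  info <- regmatches(files, regexec("^(.*)_(novelty|memory)_tmap", files))
  ids <- unique(vapply(info, `[`, "", 2L))
  tmaps <- list()
  for (con in c("novelty", "memory")) {
    m <- matrix(NA_real_, length(ids), prod(grid_dims))
    for (i in seq_along(ids)) {
      f <- file.path(dir, sprintf("%s_%s_tmap.nii.gz", ids[i], con))
      if (file.exists(f)) m[i, ] <- as.vector(RNifti::readNifti(f))
    }
    tmaps[[con]] <- m
  }
  structure(list(ids = ids, grid_dims = grid_dims,
                 mask = array(as.vector(mask) > 0, dim = grid_dims),
                 tmaps = tmaps),
            class = "cohort_maps")
}

#' Serialize and restore a reference model
#'
#' Per contrast: young mean and SD volumes plus a label volume
#' (1 = positive-effect, 2 = negative-effect voxels) as NIfTI, the mask
#' as NIfTI, and a JSON sidecar with the threshold and young sample
#' size.
#'
#' @param reference A [reference_model()].
#' @param dir Output directory.
#' @return `write_reference_model` returns `dir` invisibly;
#'   `read_reference_model` returns a [reference_model()].
#' @export
write_reference_model <- function(reference, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  d <- reference$grid_dims
  RNifti::writeNifti(array(as.integer(reference$mask), dim = d),
                     file.path(dir, "mask.nii.gz"))
  for (con in names(reference$contrasts)) {
    co <- reference$contrasts[[con]]
    RNifti::writeNifti(array(co$m, dim = d),
                       file.path(dir, paste0(con, "_mean.nii.gz")))
    RNifti::writeNifti(array(co$s, dim = d),
                       file.path(dir, paste0(con, "_sd.nii.gz")))
    RNifti::writeNifti(array(as.integer(co$vpos) + 2L * as.integer(co$vneg),
                             dim = d),
                       file.path(dir, paste0(con, "_labels.nii.gz")))
  }
  jsonlite::write_json(
    list(n_young = reference$n_young, threshold = reference$threshold,
         contrasts = names(reference$contrasts)),
    file.path(dir, "reference.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}

#' @rdname write_reference_model
#' @export
read_reference_model <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "reference.json"),
                              simplifyVector = TRUE)
  mask <- RNifti::readNifti(file.path(dir, "mask.nii.gz"))
  contrasts <- list()
  for (con in meta$contrasts) {
    lab <- as.vector(RNifti::readNifti(file.path(dir,
                                                 paste0(con, "_labels.nii.gz"))))
    contrasts[[con]] <- list(
      vpos = lab == 1L, vneg = lab == 2L,
      m = as.vector(RNifti::readNifti(file.path(dir,
                                                paste0(con, "_mean.nii.gz")))),
      s = as.vector(RNifti::readNifti(file.path(dir,
                                                paste0(con, "_sd.nii.gz"))))
    )
  }
  reference_model(contrasts, as.vector(mask) > 0, grid_dims = dim(mask),
                  n_young = meta$n_young, threshold = meta$threshold)
}

#' Write a run report to disk
#'
#' Emits TSV model tables mirroring the published table layout
#' (`primary.tsv`, `subgroup.tsv`, `adjusted.tsv`), the covariate
#' screening table, scatter points and line parameters for the focal
#' outcome, the scored participant CSV, a JSON report and a plain-text
#' log with the seed and configuration hash.
#'
#' @param report A `fadesame_report` from [full_run()].
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  flat <- function(x) dplyr::select(x, !dplyr::any_of(c("fit", "vif")))
  readr::write_tsv(flat(report$primary), file.path(out_dir, "primary.tsv"))
  if (nrow(report$subgroup) > 0) {
    readr::write_tsv(flat(report$subgroup), file.path(out_dir, "subgroup.tsv"))
  }
  readr::write_tsv(flat(report$adjusted), file.path(out_dir, "adjusted.tsv"))
  readr::write_tsv(report$screening$details,
                   file.path(out_dir, "covariate_screening.tsv"))
  readr::write_tsv(report$scatter$points,
                   file.path(out_dir, "scatter_points.tsv"))
  readr::write_tsv(report$scatter$lines,
                   file.path(out_dir, "scatter_lines.tsv"))
  write_participants(report$records, file.path(out_dir, "participants.csv"))
  jsonlite::write_json(
    list(
      seed = report$seed, config_hash = report$config_hash,
      focal_outcome = report$focal_outcome,
      mcar = if (!is.null(report$mcar)) unclass(report$mcar),
      primary = flat(report$primary),
      subgroup = flat(report$subgroup),
      interaction = report$interaction,
      screening = report$screening$details,
      adjusted = flat(report$adjusted)
    ),
    file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA,
    na = "null"
  )
  writeLines(
    c(sprintf("seed: %d", report$seed),
      sprintf("config_hash: %s", report$config_hash),
      sprintf("n_old: %d", nrow(report$records)),
      sprintf("focal_outcome: %s", report$focal_outcome)),
    file.path(out_dir, "run_log.txt")
  )
  invisible(out_dir)
}
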