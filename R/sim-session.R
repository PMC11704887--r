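#' Simulate one encoding session and its recognition test
#'
#' Builds the trial sequence of the incidental visual encoding task:
#' `n_novel` novel photographs (half indoor, half outdoor scenes) and
#' two pre-familiarized master images (one indoor, one outdoor) each
#' repeated `n_master_each` times, in randomized order with a fixed
#' inter-trial interval. After the session, recognition-confidence
#' ratings (1 "definitely new" … 5 "definitely old") are generated for
#' every novel item and for `n_foils` unseen foils from a
#' cumulative-logit ordinal model: the latent for old items is the
#' participant's memory ability, for foils its negative, so a perfect
#' memory yields all 5s on old items and all 1s on foils.
#'
#' @param config A [sim_config()].
#' @param participant One-row tibble or list with `id` and
#'   `memory_ability`.
#' @param seed Integer seed.
#' @return An object of class `encoding_session`: list with
#'   `participant_id`, `trials` (tibble: `onset`, `duration`,
#'   `trial_type`, `category`, `item_id`, `confidence` — confidence is
#'   `NA` for master trials), `foil_ratings` (length `n_foils`), and
#'   `n_familiarization`.
#' @export
simulate_session <- function(config, participant, seed = config$seed) {
  set.seed(seed)
  if (config$n_novel %% 2L != 0L) {
    abort("`n_novel` must be even to balance indoor/outdoor categories.")
  }
  half <- config$n_novel %/% 2L
  trials <- tibble(
    trial_type = c(rep("novel", config$n_novel),
                   rep("master", 2L * config$n_master_each)),
    category = c(rep(c("indoor", "outdoor"), each = half),
                 rep(c("indoor", "outdoor"), times = config$n_master_each)),
    item_id = c(sprintf("novel%03d", seq_len(config$n_novel)),
                rep(c("master_indoor", "master_outdoor"),
                    times = config$n_master_each))
  )
  trials <- trials[sample.int(nrow(trials)), ]
  trials$onset <- 6 + (seq_len(nrow(trials)) - 1L) * config$iti_seconds
  trials$duration <- config$stim_seconds

  mdl <- conf_rating_model
  ability <- rep(participant$memory_ability, config$n_novel)
  conf_novel <- 1L + draw_ordinal(ability, mdl$thresholds, mdl$disc)
  trials$confidence <- NA_integer_
  trials$confidence[trials$trial_type == "novel"] <- as.integer(conf_novel)
  foil <- 1L + draw_ordinal(rep(-participant$memory_ability, config$n_foils),
                            mdl$thresholds, mdl$disc)

  structure(
    list(participant_id = participant$id,
         trials = trials[, c("onset", "duration", "trial_type", "category",
                             "item_id", "confidence")],
         foil_ratings = as.integer(foil),
         n_familiarization = config$n_familiarization),
    class = "encoding_session"
  )
}

#' @export
print.encoding_session <- function(x, ...) {
  tt <- table(x$trials$trial_type)
  cat(sprintf("Encoding session for %s: %d trials (%s), %d foil ratings\n",
              x$participant_id, nrow(x$trials),
              paste(sprintf("%s %d", names(tt), tt), collapse = ", "),
              length(x$foil_ratings)))
  invisible(x)
}

#' Write / read a session's events table
#'
#' The trial table is serialized as a BIDS-style events TSV with
#' columns `onset`, `duration`, `trial_type`, `category`, `item_id`,
#' `confidence` (empty for master trials).
#'
#' @param session An `encoding_session`.
#' @param path Output TSV path.
#' @return `write_events_tsv` returns `path` invisibly;
#'   `read_events_tsv` returns the trials tibble.
#' @export
write_events_tsv <- function(session, path) {
  readr::write_tsv(session$trials, path, na = "")
  invisible(path)
}

#' @rdname write_events_tsv
#' @export
read_events_tsv <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    onset = "d", duration = "d", trial_type = "c", category = "c",
    item_id = "c", confidence = "i"
  ))
}
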