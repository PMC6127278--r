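#' Clean a session (notch, rejection, ICA, back-projection)
#'
#' Full offline cleaning chain: bad channels are removed by a robust
#' rest-run variance criterion, the data are notch filtered, a 1-70 Hz
#' band-passed copy is epoched to trial starts for trial-based artifact
#' rejection and for fitting PCA + extended-Infomax ICA on the concatenated
#' artifact-free epochs, ocular components are marked by EOG correlation,
#' and the non-artifact components are back-projected onto the notch-only
#' continuous data (trials and rest runs alike).
#'
#' @param rec An [eeg_recording] with trial/rest events.
#' @param trials Trial-record tibble (used for trial windows and validity).
#' @param notch_freq Notch frequency in Hz (default 50).
#' @param reject_band Band for artifact rejection in Hz (default c(1, 70)).
#' @param amp_limit,sd_thresh Rejection thresholds, see
#'   [detect_artifact_trials()].
#' @param var_frac PCA explained-variance target (default 0.99).
#' @param corr_thresh EOG correlation threshold for component marking.
#' @param bad_channels Manual bad-channel override list.
#' @param extra_components Manual artifact-component override list.
#' @param ica_seed Seed recorded in the output metadata (default 1).
#' @return List of class `preprocess_result`: `cleaned` (notch-only, ICA-
#'   cleaned recording), `kept_trials`, `artifact_report`, `bad_channels`,
#'   `pca`, `ica`, `artifact_components`, `report` (JSON-ready list).
#' @export
preprocess_session <- function(rec, trials,
                               notch_freq = 50,
                               reject_band = c(1, 70),
                               amp_limit = 200, sd_thresh = 5,
                               var_frac = 0.99, corr_thresh = 0.7,
                               bad_channels = character(),
                               extra_components = integer(),
                               ica_seed = 1L) {
  bad <- detect_bad_channels(rec, extra = bad_channels)
  keep_labels <- setdiff(rec$channel_labels, bad)
  rec <- pick_channels(rec, keep_labels)

  rec_notch <- if (notch_freq < rec$fs / 2) notch_filter(rec, notch_freq) else rec
  high <- min(reject_band[2], rec$fs / 2 - 1)
  rec_wide <- bandpass_filter(rec_notch, reject_band[1], high)

  trial_window <- c(0, max(trials$trial_end - trials$trial_start))
  ep <- epoch_recording(rec_wide, trials$trial_start, trial_window,
    lock = "trial_start", trial_indices = trials$index
  )
  report <- detect_artifact_trials(ep, amp_limit, sd_thresh)
  kept <- setdiff(trials$index, report$removed_trial_indices)
  ep_keep <- subset_epochs(ep, match(kept, ep$trial_indices))

  # concatenate artifact-free epochs: (trials*samples) x channels
  d <- ep_keep$data
  concat <- matrix(aperm(d, c(3, 1, 2)), ncol = dim(d)[2])
  colnames(concat) <- ep_keep$channel_labels

  pca <- pca_reduce(concat, var_frac)
  ica <- ica_decompose(pca$scores, seed = ica_seed)
  eog_cols <- which(rec$channel_types == "EOG")
  art <- mark_artifact_components(
    ica, pca$scores, concat[, eog_cols, drop = FALSE],
    corr_thresh, extra_components
  )

  cleaned <- clean_backproject(rec_notch, pca, ica, art)
  structure(
    list(
      cleaned = cleaned,
      kept_trials = kept,
      artifact_report = report,
      bad_channels = bad,
      pca = pca, ica = ica,
      artifact_components = art,
      report = list(
        bad_channels = bad,
        removed_trials = report$removed_trial_indices,
        n_components = ica$k,
        artifact_components = art,
        ica_seed = ica_seed,
        ica_converged = ica$converged
      )
    ),
    class = "preprocess_result"
  )
}

#' @export
print.preprocess_result <- function(x, ...) {
  cat(sprintf(
    "<preprocess_result> %d trials kept, %d bad channels, %d/%d artifact components\n",
    length(x$kept_trials), length(x$bad_channels),
    length(x$artifact_components), x$ica$k
  ))
  invisible(x)
}

#' Write a preprocessing report as JSON
#'
#' @param result A `preprocess_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_preprocess_report <- function(result, path) {
  jsonlite::write_json(result$report, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
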