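#' Analyse one synthetic subject end to end
#'
#' Runs the whole chain on one generated session: report validation and IO
#' estimation, cleaning (notch, trial rejection, PCA + ICA, back-
#' projection), cue-locked ERP statistics (0.1-15 Hz, paired tmax test of
#' ID vs EC on [0, 2] s), IO-locked MRCP analysis (0.1-1 Hz, peak
#' negativity at the midline central channel), time-locked MI-vs-REST
#' cross-validation and asynchronous trial-based evaluation.
#'
#' @param cfg A [sim_config()].
#' @param subject_seed Integer seed for this subject.
#' @param feature_channels Channel set for detection (default the
#'   26-channel sensorimotor set, intersected with surviving channels).
#' @param repeats,folds Cross-validation scheme (default 10 x 5).
#' @param n_perm_erp Permutations for the tmax test (default 2000).
#' @param n_boot Bootstrap resamples for CIs (default 500).
#' @param async_cfg An [async_config()].
#' @return List of class `subject_result` with components `trials`,
#'   `preprocess`, `erp_test`, `io_comparison`, `mrcp_peaks`, `timelocked`,
#'   `async` and a one-row `summary` tibble.
#' @export
run_subject <- function(cfg, subject_seed,
                        feature_channels = sensorimotor_channels(),
                        repeats = 10, folds = 5,
                        n_perm_erp = 2000, n_boot = 500,
                        async_cfg = async_config()) {
  sess <- generate_session(cfg, subject_seed)
  trials <- estimate_io(validate_trials(sess$trials))
  valid_trials <- trials[trials$valid, ]

  pre <- preprocess_session(sess$recording, valid_trials,
    ica_seed = as.integer(subject_seed)
  )
  kept <- valid_trials[valid_trials$index %in% pre$kept_trials, ]
  cleaned <- pre$cleaned

  # cue-locked ERP statistics, 0.1-15 Hz
  erp_rec <- bandpass_filter(cleaned, 0.1, 15)
  erp_test <- NULL
  by_cond <- split(kept, kept$condition)
  if (all(c("ID", "EC") %in% names(by_cond))) {
    n_pair <- min(nrow(by_cond$ID), nrow(by_cond$EC))
    ep_id <- epoch_recording(erp_rec, by_cond$ID$cue_time[seq_len(n_pair)],
      c(-0.2, 2 + 1 / cleaned$fs),
      lock = "cue"
    )
    ep_ec <- epoch_recording(erp_rec, by_cond$EC$cue_time[seq_len(n_pair)],
      c(-0.2, 2 + 1 / cleaned$fs),
      lock = "cue"
    )
    erp_test <- tmax_permutation_test(ep_id, ep_ec,
      n_perm = n_perm_erp,
      seed = subject_seed, window = c(0, 2)
    )
  }

  # IO-locked MRCP, 0.1-1 Hz
  mrcp_rec <- bandpass_filter(cleaned, 0.1, 1)
  mrcp_ch <- intersect(c("Cz", "FCz", "CPz", "C1", "C2"), cleaned$channel_labels)
  ep_io <- epoch_recording(mrcp_rec, kept$io_time, c(-3, 3),
    channels = mrcp_ch,
    lock = "IO", trial_indices = kept$index
  )
  mrcp_peaks <- peak_negativity_table(ep_io,
    n_boot = n_boot,
    seed = subject_seed
  )

  # detection: 26-channel set at 10 Hz
  chans <- intersect(feature_channels, cleaned$channel_labels)
  cz_label <- intersect(c("Cz", "C1", "C2", "FCz", "CPz"), chans)[1]
  rec10 <- downsample_recording(pick_channels(mrcp_rec, chans), target_fs = 10)
  timelocked <- crossvalidate_timelocked(rec10, kept,
    cz_label = cz_label,
    repeats = repeats, folds = folds, seed = subject_seed
  )
  async <- async_crossvalidate(rec10, kept,
    cz_label = cz_label, cfg = async_cfg,
    repeats = repeats, folds = folds, seed = subject_seed
  )

  io_cmp <- compare_io_conditions(valid_trials)
  acc <- timelocked$metrics[timelocked$metrics$metric == "accuracy", ]
  peak_cz <- mrcp_peaks[mrcp_peaks$channel == mrcp_ch[1], ]
  summary <- tibble::tibble(
    subject_seed = subject_seed,
    n_trials = nrow(trials),
    n_valid = nrow(valid_trials),
    n_kept = nrow(kept),
    n_artifact_components = length(pre$artifact_components),
    mrcp_peak_latency = peak_cz$latency,
    mrcp_peak_amplitude = peak_cz$amplitude,
    erp_sig_cells = if (is.null(erp_test)) NA_integer_ else sum(erp_test$significance_mask),
    timelocked_accuracy = acc$mean,
    timelocked_sd = acc$sd,
    chance_upper = timelocked$chance_interval[2],
    async_percent_correct = unname(async$percent_correct["mean"]),
    async_chance = async$chance_level,
    async_plr = async$plr
  )
  structure(
    list(
      trials = trials, preprocess = pre, erp_test = erp_test,
      io_comparison = io_cmp, mrcp_peaks = mrcp_peaks,
      timelocked = timelocked, async = async, summary = summary
    ),
    class = "subject_result"
  )
}

#' @export
print.subject_result <- function(x, ...) {
  print(x$summary)
  invisible(x)
}

#' Run a multi-subject synthetic study
#'
#' Generates and analyses `cfg$n_subjects` subjects with seeds
#' `seed + 1, ..., seed + n_subjects` and binds their summaries.
#'
#' @param cfg A [sim_config()].
#' @param seed Base integer seed.
#' @param ... Passed to [run_subject()].
#' @return List with `summaries` (tibble, one row per subject) and
#'   `subjects` (list of `subject_result`).
#' @export
run_study <- function(cfg, seed = cfg$seed, ...) {
  subjects <- lapply(seq_len(cfg$n_subjects), function(s) {
    run_subject(cfg, subject_seed = seed + s, ...)
  })
  list(
    summaries = dplyr::bind_rows(lapply(subjects, function(s) s$summary)),
    subjects = subjects
  )
}
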