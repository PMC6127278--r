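# Per-component ERP waves (needed because each component has its own scalp
# topography when a session is synthesised).
erp_component_waves <- function(t_grid, params) {
  w <- params$component_widths
  lw <- params$late_window
  late <- numeric(length(t_grid))
  inside <- t_grid > lw[1] & t_grid < lw[2]
  late[inside] <- params$late_amplitude *
    0.5 * (1 - cos(2 * pi * (t_grid[inside] - lw[1]) / (lw[2] - lw[1])))
  list(
    p200 = params$p200_amplitude * exp(-0.5 * ((t_grid - params$p200_latency) / w[["p200"]])^2),
    p300 = params$p300_amplitude * exp(-0.5 * ((t_grid - params$p300_latency) / w[["p300"]])^2),
    late = late
  )
}

#' Generate a synthetic session
#'
#' Builds one subject's continuous recording and trial records.  Each trial
#' is: 2 s baseline, cue, 3-digit scroller numbers every `scroller_period`
#' seconds with distinct payloads, a self-paced imagination onset (IO) drawn
#' from the configured distribution, and a break.  Conditions (ID, IDII, EC)
#' are pseudo-randomly interleaved with equal counts.  The signal is 1/f
#' noise plus the condition's ERP template at each cue, the MRCP template at
#' each true IO, and optional blinks; three 60 s rest runs (noise only) are
#' appended.  A configurable fraction of trials receives an incorrect report
#' (a number never shown, or a target violating the condition).  Ground
#' truth (true IO, blink times, condition templates) is retained in the
#' events and trial records.
#'
#' Identical `(cfg, subject_seed)` give bitwise-identical output.
#'
#' @param cfg A [sim_config()].
#' @param subject_seed Integer seed for this subject.
#' @return List with elements `recording` ([eeg_recording]) and `trials`
#'   (tibble of trial records).
#' @export
generate_session <- function(cfg, subject_seed = cfg$seed) {
  stopifnot(inherits(cfg, "sim_config"))
  withr::with_seed(as.integer(subject_seed), generate_session_impl(cfg))
}

generate_session_impl <- function(cfg) {
  fs <- cfg$fs
  labels <- cfg$channel_names
  types <- ifelse(grepl("^EOG", labels), "EOG", "EEG")
  n_trials <- 3L * cfg$trials_per_condition
  conditions <- sample(rep(c("ID", "IDII", "EC"), each = cfg$trials_per_condition))
  trial_dur <- cfg$baseline_duration + cfg$post_cue_duration + cfg$break_duration
  rest_dur <- 60
  total_dur <- n_trials * trial_dur + 3 * rest_dur
  n_samples <- round(total_dur * fs)

  n_scroll <- sum(seq(0, cfg$post_cue_duration - 1e-9, by = cfg$scroller_period) <
    cfg$post_cue_duration)
  scroll_rel <- (seq_len(n_scroll) - 1) * cfg$scroller_period

  trials <- vector("list", n_trials)
  ev <- list()
  for (i in seq_len(n_trials)) {
    cond <- conditions[i]
    t_start <- (i - 1) * trial_dur
    cue <- t_start + cfg$baseline_duration
    trial_end <- cue + cfg$post_cue_duration
    numbers <- sample(100:999, n_scroll)
    onsets <- cue + scroll_rel
    water <- switch(cond,
      EC = sample(1:5, 1),
      IDII = sort(sample(1:5, 2)),
      ID = sort(sample(1:5, sample(2:5, 1)))
    )
    expected <- switch(cond, ID = 1:5, IDII = water, EC = water)
    io_rel <- draw_io_times(1, cfg$io_distribution)
    io_true <- cue + io_rel
    shown_idx <- findInterval(io_rel, scroll_rel)
    reported_number <- numbers[shown_idx]
    reported_target <- if (length(expected) == 1) expected else sample(expected, 1)
    if (stats::runif(1) < cfg$invalid_report_rate) {
      if (cond != "ID" && stats::runif(1) < 0.5) {
        reported_target <- sample(setdiff(1:5, expected), 1)
      } else {
        reported_number <- sample(setdiff(100:999, numbers), 1)
      }
    }
    trials[[i]] <- tibble::tibble(
      index = i, condition = cond,
      trial_start = t_start, cue_time = cue, trial_end = trial_end,
      scroller_numbers = list(numbers), scroller_onsets = list(onsets),
      expected_targets = list(expected),
      reported_number = reported_number, reported_target = reported_target,
      io_true = io_true, valid = NA, io_time = NA_real_
    )
    ev[[i]] <- tibble::tibble(
      onset = c(t_start, cue, onsets, io_true, trial_end),
      duration = c(0, 0, rep(cfg$scroller_period, n_scroll), 0, 0),
      label = c(
        "trial_start", "cue", rep("scroller", n_scroll),
        "io_true", "report"
      ),
      payload = c(
        as.character(i), cond, as.character(numbers),
        as.character(i), as.character(reported_number)
      )
    )
  }
  trials <- dplyr::bind_rows(trials)
  rest_starts <- n_trials * trial_dur + (0:2) * rest_dur
  ev[[n_trials + 1L]] <- tibble::tibble(
    onset = rest_starts, duration = rest_dur,
    label = "rest_run_start", payload = as.character(1:3)
  )
  events <- dplyr::bind_rows(ev)

  data <- pink_noise(n_samples, length(labels), cfg$noise_exponent, cfg$noise_scale)
  colnames(data) <- labels

  # component topographies (zero on EOG channels)
  topo <- list(
    p200 = default_topography(labels, "p200"),
    p300 = default_topography(labels, "p300"),
    late = default_topography(labels, "late")
  )
  topo_mrcp <- default_topography(labels, "mrcp")

  erp_rel <- seq(0, 1.5, by = 1 / fs)
  waves_by_cond <- lapply(cfg$erp_params, erp_component_waves, t_grid = erp_rel)
  mrcp_rel <- seq(
    -cfg$mrcp_params$onset_lead, cfg$mrcp_params$return_time,
    by = 1 / fs
  )
  mrcp_wave <- mrcp_waveform(mrcp_rel, cfg$mrcp_params)

  for (i in seq_len(n_trials)) {
    cue_i <- round(trials$cue_time[i] * fs)
    idx <- cue_i + seq_along(erp_rel)
    comp <- waves_by_cond[[trials$condition[i]]]
    for (nm in names(comp)) {
      data[idx, ] <- data[idx, ] + outer(comp[[nm]], topo[[nm]])
    }
    io_i <- round(trials$io_true[i] * fs)
    idx <- io_i + round(mrcp_rel[1] * fs) + seq_along(mrcp_rel)
    data[idx, ] <- data[idx, ] + outer(mrcp_wave, topo_mrcp)
  }

  rec <- eeg_recording(data, fs, labels, types, events)
  if (cfg$blink_rate > 0) {
    rec <- inject_blinks(rec, cfg$blink_rate, cfg$blink_amplitude)
  }
  list(recording = rec, trials = trials)
}
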