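# Shared fixtures, generated in code.  Sessions are cached per test run.

.fixture_cache <- new.env(parent = emptyenv())

# Small montage for fast session fixtures: 13 EEG (midline central +
# parietal + frontal) + 3 EOG.
small_montage <- function() {
  c(
    "Fp1", "Fz", "FCz", "FC1", "FC2", "C3", "Cz", "C4",
    "CP1", "CPz", "CP2", "Pz", "Oz", eog_labels()
  )
}

small_sim_config <- function(trials_per_condition = 8, fs = 100, ...) {
  sim_config(
    trials_per_condition = trials_per_condition, fs = fs,
    channel_names = small_montage(), ...
  )
}

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# One small session with blinks, reused across preprocessing tests.
small_session <- function() {
  cached("small_session", generate_session(small_sim_config(), 101))
}

# Noise-free session: signal is template only.
clean_session <- function() {
  cached("clean_session", generate_session(
    small_sim_config(
      trials_per_condition = 5, noise_scale = 0, blink_rate = 0,
      invalid_report_rate = 0
    ), 202
  ))
}

# Direct 10 Hz recording + trial table for classifier tests: the 0.1-1 Hz
# feature stream is emulated as an MRCP template at each IO plus smoothed
# noise, on `n_ch` channels with the first channel carrying gain 1.
make_rec10_fixture <- function(n_trials = 30, peak_amp = -6, noise = 1,
                               seed = 1, n_ch = 26, io_rel = NULL) {
  withr::with_seed(seed, {
    fs <- 10
    trial_dur <- 17
    n <- n_trials * trial_dur * fs
    gains <- c(1, stats::runif(n_ch - 1, 0.2, 0.8))
    data <- matrix(stats::rnorm(n * n_ch), n, n_ch)
    # crude 1/f-ish smoothing so neighbouring samples correlate
    data <- apply(data, 2, function(x) stats::filter(x, rep(1 / 4, 4), sides = 1))
    data[is.na(data)] <- 0
    data <- sweep(data, 2, apply(data, 2, stats::sd) / noise, "/")
    if (noise == 0) data[] <- 0
    cue <- 2 + (seq_len(n_trials) - 1) * trial_dur
    io_rel <- io_rel %||% stats::runif(n_trials, 2, 9)
    io <- cue + io_rel
    tgrid <- seq(-1, 2, by = 1 / fs)
    wave <- mrcp_waveform(tgrid, mrcp_template_params(peak_amplitude = peak_amp))
    for (i in seq_len(n_trials)) {
      idx <- round(io[i] * fs) + round(-1 * fs) + seq_along(tgrid)
      data[idx, ] <- data[idx, ] + outer(wave, gains)
    }
    labels <- paste0("ch", seq_len(n_ch))
    labels[1] <- "Cz"
    rec <- eeg_recording(data, fs, labels,
      channel_types = rep("EEG", n_ch)
    )
    trials <- tibble::tibble(
      index = seq_len(n_trials),
      condition = rep_len(c("ID", "IDII", "EC"), n_trials),
      trial_start = cue - 2, cue_time = cue, trial_end = cue + 13.5,
      io_time = io, io_true = io, valid = TRUE
    )
    list(rec = rec, trials = trials)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Epochs built directly from arrays.
epochs_from_array <- function(arr, fs, t0 = 0, labels = NULL) {
  labels <- labels %||% paste0("ch", seq_len(dim(arr)[2]))
  eeg_epochs(arr, fs, t0 + (seq_len(dim(arr)[3]) - 1) / fs,
    lock = "cue",
    channel_labels = labels, trial_indices = seq_len(dim(arr)[1])
  )
}
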