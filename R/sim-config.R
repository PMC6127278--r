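#' Cue-locked ERP template parameters
#'
#' Parameters of the three-component cue-locked ERP template: an early
#' positivity near 200 ms, a P300-like positivity near 500 ms, and a late
#' slow-wave component whose amplitude differs between internally-driven and
#' externally-cued conditions over roughly 0.6-0.8 s after the cue.
#'
#' @param p200_amplitude,p300_amplitude,late_amplitude Component peak
#'   amplitudes in microvolts.
#' @param p200_latency,p300_latency Component peak latencies in seconds after
#'   the cue; must be strictly increasing.
#' @param late_window Length-2 numeric, support of the late component in
#'   seconds after the cue.  The late component is a raised-cosine bump that
#'   is exactly zero outside this window.
#' @param component_widths Named numeric (`p200`, `p300`) Gaussian standard
#'   deviations in seconds.
#' @return List of class `erp_template_params`.
#' @export
erp_template_params <- function(p200_amplitude = 4, p200_latency = 0.2,
                                p300_amplitude = 5, p300_latency = 0.5,
                                late_amplitude = 3, late_window = c(0.6, 0.8),
                                component_widths = c(p200 = 0.05, p300 = 0.12)) {
  stopifnot(
    p200_latency < p300_latency,
    all(component_widths > 0),
    length(late_window) == 2, late_window[1] < late_window[2]
  )
  structure(
    list(
      p200_amplitude = p200_amplitude, p200_latency = p200_latency,
      p300_amplitude = p300_amplitude, p300_latency = p300_latency,
      late_amplitude = late_amplitude, late_window = late_window,
      component_widths = component_widths
    ),
    class = "erp_template_params"
  )
}

#' MRCP (Bereitschaftspotential-like) template parameters
#'
#' Slow negativity starting `onset_lead` seconds before the imagination onset
#' (IO), reaching `peak_amplitude` at `peak_latency` seconds after the IO and
#' returning to baseline by `return_time`.
#'
#' @param onset_lead Seconds before the IO at which the negativity starts
#'   (positive number, default 1).
#' @param peak_latency Seconds after the IO of the negative peak (default
#'   0.5; may be negative but must exceed `-onset_lead`).
#' @param peak_amplitude Peak amplitude in microvolts, strictly negative.
#' @param return_time Seconds after the IO at which baseline is recovered.
#' @return List of class `mrcp_template_params`.
#' @export
mrcp_template_params <- function(onset_lead = 1, peak_latency = 0.5,
                                 peak_amplitude = -6, return_time = 2) {
  if (onset_lead <= 0) stop("onset_lead must be > 0", call. = FALSE)
  if (peak_amplitude >= 0) stop("peak_amplitude must be negative", call. = FALSE)
  if (return_time <= peak_latency) stop("return_time must exceed peak_latency", call. = FALSE)
  if (peak_latency <= -onset_lead) stop("peak_latency must exceed -onset_lead", call. = FALSE)
  structure(
    list(
      onset_lead = onset_lead, peak_latency = peak_latency,
      peak_amplitude = peak_amplitude, return_time = return_time
    ),
    class = "mrcp_template_params"
  )
}

#' Simulation configuration for synthetic sessions
#'
#' Defines the paradigm timing (2 s baseline, cue, 3-digit scroller numbers
#' every 750 ms, self-paced imagination onset, 1.5 s break), the
#' condition-dependent ERP templates, the MRCP template, the 1/f background
#' and the blink/reporting-error model.  Defaults are the study conditions
#' assumed throughout the package; see the methods vignette for rationale.
#'
#' @param n_subjects Number of subjects (used by [run_study()]).
#' @param trials_per_condition Trials per condition (ID, IDII, EC); >= 5.
#' @param fs Sampling rate in Hz (default 250).
#' @param channel_names Montage labels (default 61 EEG + 3 EOG).
#' @param post_cue_duration Seconds from cue to trial end (default 13.5;
#'   must be >= 13 so the 12 s evaluation period starting 1 s after the cue
#'   fits in every trial).
#' @param baseline_duration Seconds from trial start to cue (default 2).
#' @param scroller_period Seconds between scroller numbers (default 0.75).
#' @param break_duration Inter-trial break in seconds (default 1.5).
#' @param io_distribution List describing the IO distribution relative to the
#'   cue: `family` ("lognormal" or "uniform"), parameters, and truncation
#'   bounds `min`/`max` in seconds (default truncated lognormal on [2, 9]).
#' @param erp_params Named list of [erp_template_params()] for conditions
#'   `ID`, `IDII`, `EC`.
#' @param mrcp_params [mrcp_template_params()].
#' @param noise_exponent Spectral exponent of the 1/f background (default 1).
#' @param noise_scale Per-channel RMS of the background in microvolts
#'   (default 2).
#' @param blink_rate Blink events per minute (default 4).
#' @param blink_amplitude Blink peak amplitude in microvolts (default 120).
#' @param invalid_report_rate Probability that a trial's report is invalid
#'   (default 0.05).
#' @param seed Base integer seed.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 1,
                       trials_per_condition = 60,
                       fs = 250,
                       channel_names = montage_labels(61),
                       post_cue_duration = 13.5,
                       baseline_duration = 2,
                       scroller_period = 0.75,
                       break_duration = 1.5,
                       io_distribution = list(
                         family = "lognormal", meanlog = log(4),
                         sdlog = 0.45, min = 2, max = 9
                       ),
                       erp_params = NULL,
                       mrcp_params = mrcp_template_params(),
                       noise_exponent = 1,
                       noise_scale = 2,
                       blink_rate = 4,
                       blink_amplitude = 120,
                       invalid_report_rate = 0.05,
                       seed = 1L) {
  if (is.null(erp_params)) {
    erp_params <- list(
      ID = erp_template_params(late_amplitude = 3),
      IDII = erp_template_params(late_amplitude = 3),
      EC = erp_template_params(late_amplitude = 1)
    )
  }
  stopifnot(
    trials_per_condition >= 5,
    scroller_period > 0,
    post_cue_duration >= 13,
    fs > 0, noise_exponent >= 0, noise_scale >= 0,
    blink_rate >= 0,
    invalid_report_rate >= 0, invalid_report_rate <= 1,
    setequal(names(erp_params), c("ID", "IDII", "EC"))
  )
  if (io_distribution$min <= 0 ||
    io_distribution$max > post_cue_duration - 3.5) {
    stop("io_distribution support must lie in (0, post_cue_duration - 3.5]",
      call. = FALSE
    )
  }
  structure(
    list(
      n_subjects = n_subjects,
      trials_per_condition = trials_per_condition,
      fs = fs, channel_names = channel_names,
      post_cue_duration = post_cue_duration,
      baseline_duration = baseline_duration,
      scroller_period = scroller_period,
      break_duration = break_duration,
      io_distribution = io_distribution,
      erp_params = erp_params,
      mrcp_params = mrcp_params,
      noise_exponent = noise_exponent,
      noise_scale = noise_scale,
      blink_rate = blink_rate,
      blink_amplitude = blink_amplitude,
      invalid_report_rate = invalid_report_rate,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

# Draw n IO times (seconds after cue) from the configured truncated
# distribution, by rejection.
draw_io_times <- function(n, dist) {
  out <- numeric(0)
  while (length(out) < n) {
    cand <- switch(dist$family,
      lognormal = stats::rlnorm(2 * n, dist$meanlog, dist$sdlog),
      uniform = stats::runif(2 * n, dist$min, dist$max),
      stop("unknown io_distribution family: ", dist$family, call. = FALSE)
    )
    out <- c(out, cand[cand >= dist$min & cand <= dist$max])
  }
  out[seq_len(n)]
}

#' Read and write simulation configs as YAML
#'
#' Serialises the scalar fields and template parameters of a [sim_config()];
#' topographies and custom distributions beyond the built-in families are
#' reconstructed from defaults.
#'
#' @param cfg A [sim_config()].
#' @param path File path.
#' @return `read_sim_config_yaml` returns a `sim_config`; the writer
#'   returns `path` invisibly.
#' @export
write_sim_config_yaml <- function(cfg, path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the yaml package is required", call. = FALSE)
  }
  x <- unclass(cfg)
  x$erp_params <- lapply(x$erp_params, function(p) {
    p <- unclass(p)
    p$component_widths <- as.list(p$component_widths)
    p
  })
  x$mrcp_params <- unclass(x$mrcp_params)
  yaml::write_yaml(x, path, precision = 15)
  invisible(path)
}

#' @rdname write_sim_config_yaml
#' @export
read_sim_config_yaml <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the yaml package is required", call. = FALSE)
  }
  x <- yaml::read_yaml(path)
  x$erp_params <- lapply(x$erp_params, function(p) {
    p$component_widths <- unlist(p$component_widths)
    p$late_window <- as.numeric(unlist(p$late_window))
    do.call(erp_template_params, p)
  })
  x$mrcp_params <- do.call(mrcp_template_params, x$mrcp_params)
  x$channel_names <- as.character(unlist(x$channel_names))
  do.call(sim_config, x)
}
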