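#' MRCP template waveform
#'
#' Piecewise raised-cosine Bereitschaftspotential-like curve: zero before the
#' negativity onset (`-onset_lead` s relative to the IO), monotone decrease
#' to `peak_amplitude` at `peak_latency`, monotone return to zero by
#' `return_time`, zero afterwards.
#'
#' @param t_grid Monotone increasing numeric vector of times in seconds
#'   relative to the imagination onset.
#' @param params [mrcp_template_params()].
#' @return Numeric vector of amplitudes (microvolts), same length as `t_grid`.
#' @export
#' @examples
#' mrcp_waveform(c(-2, 0.5, 2.5), mrcp_template_params())
mrcp_waveform <- function(t_grid, params = mrcp_template_params()) {
  if (!inherits(params, "mrcp_template_params")) {
    params <- do.call(mrcp_template_params, params)
  }
  if (is.unsorted(t_grid)) stop("t_grid must be monotone increasing", call. = FALSE)
  a <- params$peak_amplitude
  t0 <- -params$onset_lead
  tp <- params$peak_latency
  tr <- params$return_time
  y <- numeric(length(t_grid))
  fall <- t_grid >= t0 & t_grid < tp
  y[fall] <- a * 0.5 * (1 - cos(pi * (t_grid[fall] - t0) / (tp - t0)))
  rise <- t_grid >= tp & t_grid < tr
  y[rise] <- a * 0.5 * (1 + cos(pi * (t_grid[rise] - tp) / (tr - tp)))
  y
}

#' Cue-locked ERP template waveform
#'
#' Sum of Gaussian-shaped components at the configured latencies (early
#' positivity and P300-like peak) plus a raised-cosine late component with
#' compact support on `late_window`; the late amplitude is the
#' condition-dependent part of the template.
#'
#' @param t_grid Times in seconds relative to the cue.
#' @param params Either an [erp_template_params()] object, or a named list of
#'   them keyed by condition (in which case `condition` selects one).
#' @param condition Optional condition name ("ID", "IDII", "EC").
#' @return Numeric vector of amplitudes (microvolts).
#' @export
erp_waveform <- function(t_grid, params = erp_template_params(), condition = NULL) {
  if (!is.null(condition)) {
    params <- params[[condition]]
    if (is.null(params)) stop("unknown condition: ", condition, call. = FALSE)
  }
  if (!inherits(params, "erp_template_params")) {
    params <- do.call(erp_template_params, params)
  }
  w <- params$component_widths
  y <- params$p200_amplitude * exp(-0.5 * ((t_grid - params$p200_latency) / w[["p200"]])^2) +
    params$p300_amplitude * exp(-0.5 * ((t_grid - params$p300_latency) / w[["p300"]])^2)
  lw <- params$late_window
  inside <- t_grid > lw[1] & t_grid < lw[2]
  y[inside] <- y[inside] + params$late_amplitude *
    0.5 * (1 - cos(2 * pi * (t_grid[inside] - lw[1]) / (lw[2] - lw[1])))
  y
}

#' 1/f ("pink") background noise
#'
#' Spectrally-shaped Gaussian noise with power spectral density proportional
#' to \eqn{1/f^{exponent}}, synthesised in the frequency domain and scaled to
#' a per-channel RMS of `scale` microvolts.  Reproducible for a fixed seed.
#'
#' @param n_samples Number of samples (> 1).
#' @param n_channels Number of channels.
#' @param exponent Spectral exponent (>= 0; 0 gives white noise).
#' @param scale Per-channel RMS in microvolts.
#' @param seed Optional integer seed (local to this call).
#' @return `n_samples` x `n_channels` matrix.
#' @export
pink_noise <- function(n_samples, n_channels, exponent = 1, scale = 1, seed = NULL) {
  stopifnot(n_samples > 1, n_channels >= 1)
  if (exponent < 0) stop("exponent must be >= 0", call. = FALSE)
  gen <- function() {
    if (scale == 0) {
      return(matrix(0, n_samples, n_channels))
    }
    # two-sided frequency bins 0, 1/N, ...; DC forced to zero
    k <- c(0, seq_len(n_samples - 1))
    f <- pmin(k, n_samples - k) / n_samples
    gain <- c(0, f[-1]^(-exponent / 2))
    out <- matrix(0, n_samples, n_channels)
    for (ch in seq_len(n_channels)) {
      spec <- stats::fft(stats::rnorm(n_samples)) * gain
      x <- Re(stats::fft(spec, inverse = TRUE)) / n_samples
      out[, ch] <- x * (scale / sqrt(mean(x^2)))
    }
    out
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

# Raised-cosine blink kernel, `dur` seconds long.
blink_kernel <- function(fs, dur = 0.3) {
  n <- max(3L, round(dur * fs))
  0.5 * (1 - cos(2 * pi * seq(0, 1, length.out = n)))
}

#' Inject blink artifacts into a recording
#'
#' Adds raised-cosine blink transients (~300 ms) at Poisson-distributed times
#' to the EOG channels and, with decaying gain, to frontal EEG channels.
#' Ground-truth blink times are appended to the event stream with label
#' `"blink"`.
#'
#' @param rec An [eeg_recording] with EOG channels.
#' @param rate Blink rate in events per minute (>= 0).
#' @param amplitude Blink peak amplitude in microvolts.
#' @param seed Optional integer seed (local to this call).
#' @return A new `eeg_recording` with blinks added.
#' @export
inject_blinks <- function(rec, rate, amplitude, seed = NULL) {
  if (rate < 0) stop("rate must be >= 0", call. = FALSE)
  if (!any(rec$channel_types == "EOG")) stop("recording has no EOG channels", call. = FALSE)
  if (rate == 0) {
    return(rec)
  }
  run <- function() {
    dur_s <- nrow(rec$data) / rec$fs
    n_blinks <- stats::rpois(1, rate * dur_s / 60)
    times <- sort(stats::runif(n_blinks, 0, dur_s - 0.4))
    kern <- blink_kernel(rec$fs)
    topo <- default_topography(rec$channel_labels, "blink")
    data <- rec$data
    for (t0 in times) {
      i0 <- round(t0 * rec$fs) + 1L
      idx <- i0:(i0 + length(kern) - 1L)
      data[idx, ] <- data[idx, ] + amplitude * outer(kern, topo)
    }
    ev <- rbind(
      rec$events,
      tibble::tibble(
        onset = times, duration = 0.3,
        label = "blink", payload = as.character(seq_along(times))
      )
    )
    eeg_recording(
      data, rec$fs, rec$channel_labels, rec$channel_types,
      ev, rec$reference
    )
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
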