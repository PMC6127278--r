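#' MI-window start rule from the training-average MRCP
#'
#' Computes the peak negativity of a training-fold average MRCP (midline
#' central channel) in the closed [-2, 2] s window; a peak latency strictly
#' before 0.5 s selects an MI window starting at -1 s, otherwise at 0 s.
#'
#' @param values Training-average MRCP amplitude series (µV).
#' @param times Time axis in seconds relative to the IO.
#' @param search_window Peak search window (default c(-2, 2)).
#' @return MI window start in seconds relative to the IO: -1 or 0.
#' @export
select_mi_window <- function(values, times, search_window = c(-2, 2)) {
  pk <- find_peak_negativity(values, times, search_window)
  if (pk$latency < 0.5) -1 else 0
}

#' REST-window rule
#'
#' The 1 s REST window starts 4 s after the IO as long as its upper limit
#' does not exceed the end of the trial; otherwise it starts at -5 s.  For
#' the asynchronous training set the same criterion is applied to the 3 s
#' block of three consecutive windows (`n_windows = 3`).
#'
#' @param io_time IO time (same clock as `trial_end`).
#' @param trial_end Trial end time.
#' @param n_windows Number of consecutive 1 s windows in the block
#'   (default 1).
#' @return Numeric `(start, end)` of the block in seconds relative to the
#'   IO: `c(4, 4 + n_windows)` or `c(-5, -5 + n_windows)`.
#' @export
select_rest_window <- function(io_time, trial_end, n_windows = 1) {
  if (io_time + 4 + n_windows <= trial_end) {
    c(4, 4 + n_windows)
  } else {
    c(-5, -5 + n_windows)
  }
}

# Amplitude features of one 1 s window at 10 Hz: 10 consecutive samples per
# channel, concatenated channel-wise (10 * n_channels features).  `start` is
# the absolute window start in seconds; the window is [start, start + 1).
window_feature_vector <- function(rec10, start) {
  i0 <- round(start * rec10$fs)
  idx <- i0 + seq_len(round(rec10$fs)) # 1-based rows for 0-based sample i0
  if (idx[1] < 1 || idx[length(idx)] > nrow(rec10$data)) {
    return(NULL)
  }
  as.vector(rec10$data[idx, , drop = FALSE])
}

#' Extract windowed amplitude features
#'
#' Builds the observations x features matrix for a set of 1 s windows from
#' a cleaned, 0.1-1 Hz filtered recording downsampled to 10 Hz: each window
#' contributes 10 amplitude samples per channel (260 features for the
#' 26-channel sensorimotor set).  Windows falling outside the recording are
#' skipped and reported via the `skipped` attribute.
#'
#' @param rec10 An [eeg_recording] at 10 Hz, already restricted to the
#'   feature channels.
#' @param windows Tibble with columns `trial_id`, `class` ("MI"/"REST"),
#'   `start` (absolute seconds) and `window_start` (seconds relative to the
#'   IO).
#' @return List of class `feature_set`: `X` (observations x features), `y`,
#'   `trial_id`, `window_start`, `channel_labels`.
#' @export
extract_features <- function(rec10, windows) {
  if (abs(rec10$fs - 10) > 1e-9) stop("rec10 must be sampled at 10 Hz", call. = FALSE)
  feats <- lapply(windows$start, function(s) window_feature_vector(rec10, s))
  ok <- !vapply(feats, is.null, logical(1))
  X <- do.call(rbind, feats[ok])
  out <- list(
    X = X, y = windows$class[ok], trial_id = windows$trial_id[ok],
    window_start = windows$window_start[ok],
    channel_labels = rec10$channel_labels
  )
  attr(out, "skipped") <- windows$trial_id[!ok]
  class(out) <- "feature_set"
  out
}

# Windows for the time-locked problem: one MI window (start mi_start rel.
# IO) and one REST window (per-trial rule) per trial.
timelocked_windows <- function(trials, mi_start) {
  purrr::map_dfr(seq_len(nrow(trials)), function(i) {
    io <- trials$io_time[i]
    rest <- select_rest_window(io, trials$trial_end[i], n_windows = 1)
    tibble::tibble(
      trial_id = trials$index[i],
      class = c("MI", "REST"),
      start = c(io + mi_start, io + rest[1]),
      window_start = c(mi_start, rest[1])
    )
  })
}

# Windows for the asynchronous training set: three consecutive MI windows
# from mi_start and three consecutive REST windows from the block rule.
async_windows <- function(trials, mi_start) {
  purrr::map_dfr(seq_len(nrow(trials)), function(i) {
    io <- trials$io_time[i]
    rest <- select_rest_window(io, trials$trial_end[i], n_windows = 3)
    starts_mi <- mi_start + 0:2
    starts_rest <- rest[1] + 0:2
    tibble::tibble(
      trial_id = trials$index[i],
      class = rep(c("MI", "REST"), each = 3),
      start = io + c(starts_mi, starts_rest),
      window_start = c(starts_mi, starts_rest)
    )
  })
}

#' Build the asynchronous training feature set
#'
#' Three consecutive 1 s MI windows starting at the subject's MI-window
#' start (-1 or 0 s relative to the IO) and three consecutive REST windows
#' starting at +4 s, or at -5 s when the 3 s block would cross the end of
#' the trial.
#'
#' @param rec10 10 Hz feature-channel recording (see [extract_features()]).
#' @param trials Valid trial records with `io_time` set.
#' @param mi_start MI window start in seconds (-1 or 0), decided on
#'   training folds.
#' @return A `feature_set` with up to 6 observations per trial.
#' @export
build_async_training_set <- function(rec10, trials, mi_start) {
  extract_features(rec10, async_windows(trials, mi_start))
}

#' Adjusted Wald (Agresti-Coull) interval
#'
#' Chance-level interval for a classifier tested on `n` trials:
#' with \eqn{z = \Phi^{-1}(1-\alpha/2)},
#' \eqn{\tilde p = (n p_0 + z^2/2)/(n + z^2)} and half-width
#' \eqn{z \sqrt{\tilde p (1-\tilde p)/(n + z^2)}}, clipped to [0, 1].
#'
#' @param n Number of trials (>= 1).
#' @param alpha Two-sided level (default 0.05).
#' @param p0 Null proportion (default 0.5).
#' @return Numeric `(lo, hi)` proportions.
#' @export
adjusted_wald_interval <- function(n, alpha = 0.05, p0 = 0.5) {
  stopifnot(n >= 1)
  z <- stats::qnorm(1 - alpha / 2)
  p_tilde <- (n * p0 + z^2 / 2) / (n + z^2)
  hw <- z * sqrt(p_tilde * (1 - p_tilde) / (n + z^2))
  c(max(0, p_tilde - hw), min(1, p_tilde + hw))
}
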