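#' Epoch set
#'
#' Trials x channels x samples array locked to an event (cue, IO or trial
#' start) with a shared relative time axis.
#'
#' @param data 3-d numeric array, trials x channels x samples (microvolts).
#' @param fs Sampling rate in Hz.
#' @param times Relative time axis in seconds (length = samples).
#' @param lock Lock event: "cue", "IO" or "trial_start".
#' @param channel_labels Channel labels (length = channels).
#' @param trial_indices Integer indices mapping epochs back to trial records.
#' @return Object of class `eeg_epochs`.
#' @export
eeg_epochs <- function(data, fs, times, lock, channel_labels, trial_indices) {
  stopifnot(
    length(dim(data)) == 3,
    dim(data)[2] == length(channel_labels),
    dim(data)[3] == length(times),
    dim(data)[1] == length(trial_indices)
  )
  structure(
    list(
      data = data, fs = fs, times = times, lock = lock,
      channel_labels = channel_labels, trial_indices = trial_indices
    ),
    class = "eeg_epochs"
  )
}

#' @export
print.eeg_epochs <- function(x, ...) {
  cat(sprintf(
    "<eeg_epochs> %d trials x %d channels x %d samples @ %g Hz, locked to %s [%g, %g) s\n",
    dim(x$data)[1], dim(x$data)[2], dim(x$data)[3], x$fs, x$lock,
    x$times[1], x$times[length(x$times)] + 1 / x$fs
  ))
  invisible(x)
}

#' Extract epochs from a continuous recording
#'
#' The epoch window is half-open `[start, end)` in seconds relative to each
#' lock event; the sample at relative time `t` of an event at `e` seconds is
#' the recording sample with 0-based index `round((e + t) * fs)`.  Lock
#' events whose window falls outside the recording are dropped with a
#' warning listing their indices.
#'
#' @param rec An [eeg_recording].
#' @param lock_times Numeric vector of event times in seconds (non-empty).
#' @param window Length-2 numeric `(start, end)` in seconds.
#' @param channels Optional subset of channel labels.
#' @param lock Label stored on the result ("cue", "IO", "trial_start", ...).
#' @param trial_indices Optional indices identifying each lock event's trial
#'   (defaults to `seq_along(lock_times)`).
#' @return An [eeg_epochs] object.
#' @export
epoch_recording <- function(rec, lock_times, window, channels = NULL,
                            lock = "cue", trial_indices = seq_along(lock_times)) {
  if (length(lock_times) == 0) stop("lock_times is empty", call. = FALSE)
  stopifnot(length(window) == 2, window[1] < window[2])
  fs <- rec$fs
  if (is.null(channels)) channels <- rec$channel_labels
  ch_idx <- match(channels, rec$channel_labels)
  if (anyNA(ch_idx)) stop("unknown channels requested", call. = FALSE)
  n_s <- round((window[2] - window[1]) * fs)
  rel0 <- round(window[1] * fs)
  rel_idx <- rel0 + seq_len(n_s) - 1L
  times <- rel_idx / fs
  first <- round(lock_times * fs) + rel_idx[1] + 1L
  last <- first + n_s - 1L
  ok <- first >= 1L & last <= nrow(rec$data)
  if (!all(ok)) {
    warning(
      "dropping out-of-bounds epochs: ",
      paste(trial_indices[!ok], collapse = ", ")
    )
  }
  keep <- which(ok)
  data <- array(0, dim = c(length(keep), length(ch_idx), n_s))
  for (k in seq_along(keep)) {
    seg <- rec$data[first[keep[k]]:last[keep[k]], ch_idx, drop = FALSE]
    data[k, , ] <- t(seg)
  }
  eeg_epochs(data, fs, times, lock, channels, trial_indices[keep])
}

# Restrict an epoch set to a closed time window.
crop_epochs <- function(epochs, window) {
  keep <- epochs$times >= window[1] & epochs$times <= window[2]
  if (!any(keep)) stop("window outside epoch time axis", call. = FALSE)
  eeg_epochs(
    epochs$data[, , keep, drop = FALSE], epochs$fs, epochs$times[keep],
    epochs$lock, epochs$channel_labels, epochs$trial_indices
  )
}

# Subset trials of an epoch set.
subset_epochs <- function(epochs, trial_sel) {
  eeg_epochs(
    epochs$data[trial_sel, , , drop = FALSE], epochs$fs, epochs$times,
    epochs$lock, epochs$channel_labels, epochs$trial_indices[trial_sel]
  )
}
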