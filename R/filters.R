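# Zero-phase IIR filtering with odd-reflection edge padding.  signal::filter
# starts from rest, so both ends are padded with the signal mirrored through
# its endpoint value before the forward and backward passes; this keeps edge
# transients out of the retained segment even for very low corner
# frequencies.
filtfilt_padded <- function(b, a, x, padlen) {
  n <- length(x)
  padlen <- min(n - 1L, max(1L, as.integer(padlen)))
  pre <- 2 * x[1] - x[(padlen + 1L):2L]
  post <- 2 * x[n] - x[(n - 1L):(n - padlen)]
  xp <- c(pre, x, post)
  y <- signal::filter(b, a, xp)
  y <- rev(signal::filter(b, a, rev(y)))
  y[(padlen + 1L):(padlen + n)]
}

# Apply a list of (b, a, padlen) stages column-wise to a samples x channels
# matrix.
apply_stages <- function(X, stages) {
  for (st in stages) {
    for (j in seq_len(ncol(X))) {
      X[, j] <- filtfilt_padded(st$b, st$a, X[, j], st$padlen)
    }
  }
  X
}

with_filtered_data <- function(rec, stages) {
  if (inherits(rec, "eeg_recording")) {
    out <- rec
    out$data <- apply_stages(rec$data, stages)
    out
  } else {
    apply_stages(as.matrix(rec), stages)
  }
}

#' Zero-phase notch filter
#'
#' Forward-backward 2nd-order Butterworth band-stop centred on `f0`,
#' attenuating power at `f0` by well over 20 dB while leaving the passband
#' (and DC) untouched.
#'
#' @param rec An [eeg_recording] or a samples x channels matrix.
#' @param f0 Notch frequency in Hz (default 50); must be below Nyquist.
#' @param width Stop-band width in Hz (default 4).
#' @param fs Sampling rate; taken from `rec` when it is a recording.
#' @return Filtered object of the same type as `rec`.
#' @export
notch_filter <- function(rec, f0 = 50, width = 6, fs = NULL) {
  fs <- fs %||% rec$fs
  if (f0 >= fs / 2) stop("notch frequency must be below Nyquist", call. = FALSE)
  bt <- signal::butter(2, c(f0 - width / 2, f0 + width / 2) / (fs / 2), type = "stop")
  st <- list(list(b = bt$b, a = bt$a, padlen = round(fs)))
  with_filtered_data(rec, st)
}

#' Zero-phase Butterworth band-pass filter
#'
#' Forward-backward Butterworth filtering of the stated order per pass,
#' realised as a high-pass / low-pass cascade (numerically robust for very
#' low corner frequencies such as 0.1 Hz).  Zero-phase: a symmetric pulse
#' keeps its peak sample.
#'
#' @param rec An [eeg_recording] or samples x channels matrix.
#' @param low,high Band edges in Hz, `0 < low < high < fs/2`.
#' @param order Filter order per pass (default 4).
#' @param fs Sampling rate; taken from `rec` when it is a recording.
#' @return Filtered object of the same type as `rec`.
#' @export
bandpass_filter <- function(rec, low, high, order = 4, fs = NULL) {
  fs <- fs %||% rec$fs
  if (!(low > 0 && low < high && high < fs / 2)) {
    stop("need 0 < low < high < fs/2", call. = FALSE)
  }
  hp <- signal::butter(order, low / (fs / 2), type = "high")
  lp <- signal::butter(order, high / (fs / 2), type = "low")
  padlen <- min(round(3 * fs / low), 30 * fs)
  st <- list(
    list(b = hp$b, a = hp$a, padlen = padlen),
    list(b = lp$b, a = lp$a, padlen = round(fs))
  )
  with_filtered_data(rec, st)
}

#' Zero-phase low-pass filter
#'
#' @inheritParams bandpass_filter
#' @param corner Corner frequency in Hz.
#' @return Filtered object of the same type as `rec`.
#' @export
lowpass_filter <- function(rec, corner, order = 4, fs = NULL) {
  fs <- fs %||% rec$fs
  if (!(corner > 0 && corner < fs / 2)) stop("corner must be in (0, fs/2)", call. = FALSE)
  lp <- signal::butter(order, corner / (fs / 2), type = "low")
  with_filtered_data(rec, list(list(b = lp$b, a = lp$a, padlen = round(2 * fs))))
}

#' Anti-aliased downsampling
#'
#' Zero-phase low-pass (4th-order Butterworth, default corner 4 Hz) followed
#' by decimation to `target_fs`.  `fs / target_fs` must be an integer.  The
#' retained samples sit at times 0, 1/target_fs, 2/target_fs, ... so event
#' times stay valid.
#'
#' @param rec An [eeg_recording].
#' @param target_fs Target rate in Hz (default 10).
#' @param corner Anti-alias corner in Hz (default 4).
#' @param order Filter order (default 4).
#' @return Downsampled `eeg_recording`.
#' @export
downsample_recording <- function(rec, target_fs = 10, corner = 4, order = 4) {
  factor <- rec$fs / target_fs
  if (abs(factor - round(factor)) > 1e-9) {
    stop("fs must be an integer multiple of target_fs", call. = FALSE)
  }
  factor <- as.integer(round(factor))
  out <- lowpass_filter(rec, corner, order)
  keep <- seq(1L, nrow(out$data), by = factor)
  eeg_recording(
    out$data[keep, , drop = FALSE], target_fs,
    rec$channel_labels, rec$channel_types, rec$events, rec$reference
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
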