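#' Trial-based artifact detection
#'
#' Flags trials of a 1-70 Hz band-passed, trial-start-locked epoch set by
#' three criteria: (1) any sample outside `±amp_limit` microvolts; (2)
#' abnormal joint probability -- per channel, the negative mean
#' log-likelihood of the trial's samples under the empirical distribution
#' (100-bin histogram) pooled over all trials, flagged when the statistic
#' exceeds its across-trial mean by more than `sd_thresh` standard
#' deviations on any channel or on the all-channel aggregate; (3) abnormal
#' kurtosis, flagged when a trial's per-channel excess kurtosis deviates
#' from the across-trial distribution by more than `sd_thresh` standard
#' deviations (two-sided).  Channels with zero across-trial spread produce
#' no flags.
#'
#' @param epochs An [eeg_epochs] locked to trial start.
#' @param amp_limit Amplitude limit in microvolts (default 200).
#' @param sd_thresh Standard-deviation threshold for both statistics
#'   (default 5).
#' @return Object of class `artifact_report`: a list with a per-trial flag
#'   tibble, the thresholds used, and `removed_trial_indices` (the union of
#'   the flagged sets).
#' @export
detect_artifact_trials <- function(epochs, amp_limit = 200, sd_thresh = 5) {
  n_trials <- dim(epochs$data)[1]
  if (n_trials < 3) stop("artifact statistics need at least 3 trials", call. = FALSE)
  n_ch <- dim(epochs$data)[2]

  amp_flag <- apply(epochs$data, 1, function(tr) any(abs(tr) > amp_limit))

  # pooled per-channel histograms
  jp <- matrix(0, n_trials, n_ch) # neg. mean log-likelihood
  ku <- matrix(0, n_trials, n_ch) # excess kurtosis
  for (ch in seq_len(n_ch)) {
    x_all <- as.vector(epochs$data[, ch, ])
    brk <- seq(min(x_all), max(x_all), length.out = 101)
    if (brk[1] == brk[101]) brk <- brk[1] + seq(-1, 1, length.out = 101)
    dens <- hist(x_all, breaks = brk, plot = FALSE)$density + 1e-12
    for (tr in seq_len(n_trials)) {
      x <- epochs$data[tr, ch, ]
      bin <- pmin(pmax(findInterval(x, brk, all.inside = TRUE), 1L), 100L)
      jp[tr, ch] <- -mean(log(dens[bin]))
      m2 <- mean((x - mean(x))^2)
      ku[tr, ch] <- if (m2 > 0) mean((x - mean(x))^4) / m2^2 - 3 else 0
    }
  }

  zscore_cols <- function(M) {
    mu <- colMeans(M)
    sdv <- apply(M, 2, stats::sd)
    Z <- sweep(sweep(M, 2, mu), 2, ifelse(sdv > 0, sdv, Inf), "/")
    Z
  }
  z_one <- function(v) {
    s <- stats::sd(v)
    if (s > 0) (v - mean(v)) / s else rep(0, length(v))
  }
  jp_z <- zscore_cols(jp)
  jp_flag <- apply(jp_z, 1, function(z) any(z > sd_thresh)) |
    (z_one(rowMeans(jp)) > sd_thresh)
  ku_z <- zscore_cols(ku)
  ku_flag <- apply(ku_z, 1, function(z) any(abs(z) > sd_thresh)) |
    (abs(z_one(rowMeans(ku))) > sd_thresh)

  flags <- tibble::tibble(
    trial_index = epochs$trial_indices,
    amplitude_exceeded = as.logical(amp_flag),
    abnormal_joint_probability = as.logical(jp_flag),
    abnormal_kurtosis = as.logical(ku_flag)
  )
  removed <- flags$trial_index[flags$amplitude_exceeded |
    flags$abnormal_joint_probability | flags$abnormal_kurtosis]
  structure(
    list(
      flags = flags,
      amp_limit = amp_limit, sd_thresh = sd_thresh,
      removed_trial_indices = removed
    ),
    class = "artifact_report"
  )
}

#' @export
print.artifact_report <- function(x, ...) {
  cat(sprintf(
    "<artifact_report> %d/%d trials removed (amp %d, joint-prob %d, kurtosis %d)\n",
    length(x$removed_trial_indices), nrow(x$flags),
    sum(x$flags$amplitude_exceeded),
    sum(x$flags$abnormal_joint_probability),
    sum(x$flags$abnormal_kurtosis)
  ))
  invisible(x)
}

#' Robust bad-channel detection on rest runs
#'
#' Flags EEG channels whose variance over the rest runs deviates from the
#' median channel variance by more than `thresh` robust standard deviations
#' (median absolute deviation scaled to the normal).  A manual override list
#' is unioned in.
#'
#' @param rec An [eeg_recording] whose events contain `rest_run_start`.
#' @param thresh Robust z threshold (default 5).
#' @param extra Channel labels to remove regardless of the criterion.
#' @return Character vector of bad channel labels.
#' @export
detect_bad_channels <- function(rec, thresh = 5, extra = character()) {
  rest <- rec$events[rec$events$label == "rest_run_start", ]
  eeg <- which(rec$channel_types == "EEG")
  if (nrow(rest) == 0) {
    seg <- rec$data[, eeg, drop = FALSE]
  } else {
    idx <- unlist(lapply(seq_len(nrow(rest)), function(i) {
      i0 <- round(rest$onset[i] * rec$fs) + 1L
      i1 <- min(nrow(rec$data), i0 + round(rest$duration[i] * rec$fs) - 1L)
      i0:i1
    }))
    seg <- rec$data[idx, eeg, drop = FALSE]
  }
  # robust per-channel scale (MAD) so sparse transients such as blinks do
  # not inflate the statistic; a minimum 2x scale ratio guards against
  # flagging when all channels are nearly identical
  v <- log(apply(seg, 2, stats::mad) + 1e-12)
  med <- stats::median(v)
  s <- stats::mad(v)
  dev <- abs(v - med)
  bad <- rec$channel_labels[eeg][dev > pmax(thresh * s, log(2))]
  union(bad, extra)
}
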