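#' Continuous multichannel recording
#'
#' Container for a continuous EEG/EOG recording: a samples-by-channels matrix
#' in microvolts, a sampling rate, per-channel metadata and an event stream.
#'
#' @param data Numeric matrix, samples x channels (microvolts).
#' @param fs Sampling rate in Hz.
#' @param channel_labels Character vector, one label per column.
#' @param channel_types Character vector of "EEG"/"EOG" per channel.
#' @param events Event stream: tibble with columns `onset` (s from recording
#'   start), `duration` (s), `label`, `payload`.
#' @param reference Label of the reference, free text.
#' @return Object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, fs, channel_labels,
                          channel_types = NULL,
                          events = empty_events(),
                          reference = "avg") {
  data <- as.matrix(data)
  if (is.null(channel_types)) {
    channel_types <- ifelse(grepl("^EOG", channel_labels), "EOG", "EEG")
  }
  stopifnot(
    is.numeric(fs), fs > 0,
    ncol(data) == length(channel_labels),
    length(channel_types) == length(channel_labels)
  )
  if (anyDuplicated(channel_labels)) stop("channel labels must be unique", call. = FALSE)
  if (!any(channel_types == "EEG")) stop("recording needs at least one EEG channel", call. = FALSE)
  events <- validate_events(events)
  colnames(data) <- channel_labels
  structure(
    list(
      data = data, fs = fs,
      channel_labels = channel_labels,
      channel_types = channel_types,
      events = events,
      reference = reference
    ),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf(
    "<eeg_recording> %d samples x %d channels @ %g Hz (%.1f s), %d events\n",
    nrow(x$data), ncol(x$data), x$fs, nrow(x$data) / x$fs, nrow(x$events)
  ))
  invisible(x)
}

#' @rdname eeg_recording
#' @export
empty_events <- function() {
  tibble::tibble(
    onset = numeric(), duration = numeric(),
    label = character(), payload = character()
  )
}

validate_events <- function(events) {
  events <- tibble::as_tibble(events)
  need <- c("onset", "duration", "label", "payload")
  if (!all(need %in% names(events))) {
    stop("events need columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  if (is.unsorted(events$onset)) {
    events <- events[order(events$onset), ]
  }
  events$payload <- as.character(events$payload)
  events
}

#' Select channels of a recording
#'
#' @param rec An [eeg_recording].
#' @param labels Channel labels to keep, in the requested order.
#' @return A new `eeg_recording` restricted to `labels`.
#' @export
pick_channels <- function(rec, labels) {
  miss <- setdiff(labels, rec$channel_labels)
  if (length(miss) > 0) stop("unknown channels: ", paste(miss, collapse = ", "), call. = FALSE)
  idx <- match(labels, rec$channel_labels)
  eeg_recording(
    rec$data[, idx, drop = FALSE], rec$fs,
    rec$channel_labels[idx], rec$channel_types[idx],
    rec$events, rec$reference
  )
}

#' Event accessors
#'
#' Convenience extraction of event onsets by label from a recording's event
#' stream.
#'
#' @param rec An [eeg_recording].
#' @param label Event label to select.
#' @return Numeric vector of onsets in seconds.
#' @export
event_onsets <- function(rec, label) {
  rec$events$onset[rec$events$label == label]
}

#' Read and write event streams as TSV
#'
#' The on-disk event format is a tab-separated table with columns
#' `onset_s`, `duration_s`, `label`, `payload`.
#'
#' @param events Event tibble (columns onset, duration, label, payload).
#' @param path File path.
#' @return `read_events_tsv` returns the event tibble; `write_events_tsv`
#'   returns `path` invisibly.
#' @export
write_events_tsv <- function(events, path) {
  events <- validate_events(events)
  out <- data.frame(
    onset_s = events$onset, duration_s = events$duration,
    label = events$label, payload = events$payload
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events_tsv
#' @export
read_events_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, colClasses = c(
    onset_s = "numeric", duration_s = "numeric",
    label = "character", payload = "character"
  ))
  tibble::tibble(
    onset = df$onset_s, duration = df$duration_s,
    label = df$label, payload = df$payload
  )
}

#' Read and write trial records as JSON
#'
#' @param trials Trial-record tibble as produced by [generate_session()].
#' @param path File path.
#' @return `read_trials_json` returns the trial tibble; the writer returns
#'   `path` invisibly.
#' @export
write_trials_json <- function(trials, path) {
  jsonlite::write_json(trials, path, dataframe = "rows", digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_trials_json
#' @export
read_trials_json <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  tr <- tibble::as_tibble(raw)
  for (col in c("scroller_numbers", "scroller_onsets", "expected_targets")) {
    if (col %in% names(tr) && !is.list(tr[[col]])) tr[[col]] <- as.list(tr[[col]])
  }
  tr
}
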