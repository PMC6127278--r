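#' Standard 10-10 electrode label sets
#'
#' Label vectors for the montages used throughout the package: a 61-channel
#' equally-spaced 10-10 EEG cap (plus three EOG channels) and a reduced
#' 32-channel cap that still contains the full sensorimotor channel set used
#' for movement-imagination detection.
#'
#' @param n_eeg Number of EEG channels, one of 61 or 32.
#' @param eog If `TRUE` (default) the three EOG labels are appended.
#' @return Character vector of channel labels.
#' @export
#' @examples
#' montage_labels(32)
montage_labels <- function(n_eeg = 61, eog = TRUE) {
  eeg61 <- c(
    "Fp1", "Fpz", "Fp2",
    "AF7", "AF3", "AFz", "AF4", "AF8",
    "F7", "F5", "F3", "F1", "Fz", "F2", "F4", "F6", "F8",
    "FT7", "FC5", "FC3", "FC1", "FCz", "FC2", "FC4", "FC6", "FT8",
    "T7", "C5", "C3", "C1", "Cz", "C2", "C4", "C6", "T8",
    "TP7", "CP5", "CP3", "CP1", "CPz", "CP2", "CP4", "CP6", "TP8",
    "P7", "P5", "P3", "P1", "Pz", "P2", "P4", "P6", "P8",
    "PO7", "PO3", "POz", "PO4", "PO8",
    "O1", "Oz", "O2"
  )
  labels <- switch(as.character(n_eeg),
    "61" = eeg61,
    "32" = c(
      "Fp1", "Fp2", "F3", "Fz", "F4",
      sensorimotor_channels(),
      "O1"
    ),
    stop("n_eeg must be 61 or 32", call. = FALSE)
  )
  if (eog) labels <- c(labels, eog_labels())
  labels
}

#' @rdname montage_labels
#' @export
eog_labels <- function() c("EOG1", "EOG2", "EOG3")

#' Sensorimotor channel set used for MI-vs-REST detection
#'
#' 26 fronto-central / centro-parietal labels over somatosensory and motor
#' cortex.  The published montage is shown only graphically, so this set is a
#' documented approximation covering the same scalp region.
#'
#' @return Character vector of 26 labels.
#' @export
sensorimotor_channels <- function() {
  c(
    "FC5", "FC3", "FC1", "FCz", "FC2", "FC4", "FC6",
    "C5", "C3", "C1", "Cz", "C2", "C4", "C6",
    "CP5", "CP3", "CP1", "CPz", "CP2", "CP4", "CP6",
    "P3", "P1", "Pz", "P2", "P4"
  )
}

#' Scalp topography gain map
#'
#' A topography is a named numeric vector of unitless gains in [0, 1] over a
#' montage; channels absent from the map have gain 0.  Topographies here are
#' abstract gain maps, not biophysical forward models.
#'
#' @param labels Full montage label vector.
#' @param weights Named numeric vector of gains for a subset of `labels`.
#' @return Named numeric vector over all of `labels`.
#' @export
scalp_topography <- function(labels, weights) {
  stopifnot(is.numeric(weights), !is.null(names(weights)))
  if (!all(names(weights) %in% labels)) {
    stop("topography labels outside montage: ",
      paste(setdiff(names(weights), labels), collapse = ", "),
      call. = FALSE
    )
  }
  if (!any(weights > 0)) stop("topography needs at least one positive weight", call. = FALSE)
  if (any(weights < 0 | weights > 1)) stop("topography gains must lie in [0, 1]", call. = FALSE)
  out <- stats::setNames(numeric(length(labels)), labels)
  out[names(weights)] <- weights
  out
}

# Built-in gain maps.  `component` picks the scalp distribution: midline
# central for the MRCP, parieto-occipital for the early positivity, centro-
# parietal for P300 and the late slow wave, frontal for blinks.
default_topography <- function(labels, component) {
  w <- switch(component,
    mrcp = c(
      Cz = 1, C1 = 0.85, C2 = 0.85, FCz = 0.85, CPz = 0.85,
      C3 = 0.6, C4 = 0.6, FC1 = 0.6, FC2 = 0.6, CP1 = 0.6, CP2 = 0.6,
      FC3 = 0.35, FC4 = 0.35, CP3 = 0.35, CP4 = 0.35, C5 = 0.35, C6 = 0.35
    ),
    p200 = c(
      Oz = 1, O1 = 0.9, O2 = 0.9, POz = 0.8, PO3 = 0.7, PO4 = 0.7,
      Pz = 0.6, P1 = 0.5, P2 = 0.5, P3 = 0.45, P4 = 0.45
    ),
    p300 = c(
      Pz = 1, P1 = 0.9, P2 = 0.9, CPz = 0.9, P3 = 0.75, P4 = 0.75,
      CP1 = 0.7, CP2 = 0.7, POz = 0.6, CP3 = 0.45, CP4 = 0.45, Cz = 0.3
    ),
    late = c(
      Pz = 1, P1 = 0.9, P2 = 0.9, CPz = 0.9, P3 = 0.75, P4 = 0.75,
      CP1 = 0.7, CP2 = 0.7, POz = 0.6, CP3 = 0.45, CP4 = 0.45
    ),
    blink = {
      b <- c(0.8, 0.8, 0.8, 0.5, 0.5, 0.5, 0.5, 0.5, 0.25, 0.25, 0.25)
      names(b) <- c("Fp1", "Fpz", "Fp2", "AF7", "AF3", "AFz", "AF4", "AF8", "F3", "Fz", "F4")
      b <- c(b, stats::setNames(rep(1, length(eog_labels())), eog_labels()))
      b
    },
    stop("unknown topography component: ", component, call. = FALSE)
  )
  scalp_topography(labels, w[names(w) %in% labels])
}
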