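# Stratified fold assignment: within each stratum, shuffled indices are
# dealt round-robin into k folds.
make_folds <- function(strata, k) {
  fold <- integer(length(strata))
  for (s in unique(strata)) {
    idx <- sample(which(strata == s))
    fold[idx] <- rep_len(sample(k), length(idx))
  }
  fold
}

# Average MRCP curve at the window-selection channel over a trial subset.
train_average_cz <- function(cz_epochs, trial_ids) {
  sel <- cz_epochs$trial_indices %in% trial_ids
  colMeans(matrix(cz_epochs$data[sel, 1, ], nrow = sum(sel)))
}

#' Time-locked MI-vs-REST cross-validation
#'
#' Repeated stratified trial-level cross-validation of the time-locked
#' detector: within every training split the MI-window rule is re-derived
#' from the training-average MRCP at the midline central channel (no
#' leakage), MRCP amplitude features are extracted (1 s windows, 10 Hz,
#' feature channels), a shrinkage-regularised LDA is fitted, and the held
#' out trials' MI and REST windows are classified.  The chance level is the
#' adjusted-Wald interval at the number of trials.
#'
#' @param rec10 Cleaned 0.1-1 Hz recording, downsampled to 10 Hz and
#'   restricted to the feature channels (see [downsample_recording()]).
#' @param trials Valid trial records with `io_time` set.
#' @param cz_label Window-selection channel (default `"Cz"`); must be in
#'   `rec10`.
#' @param repeats,folds Cross-validation scheme (default 10 x 5).
#' @param seed Integer seed for fold assignment.
#' @param alpha Level for the chance interval (default 0.05).
#' @return Object of class `timelocked_result`: summary tibble `metrics`
#'   (accuracy/tpr/fpr/fnr/tnr mean and sd in percent), `chance_interval`
#'   (percent), `n_trials`, `mi_window_starts` (per fold), `fold_table`.
#' @export
crossvalidate_timelocked <- function(rec10, trials, cz_label = "Cz",
                                     repeats = 10, folds = 5, seed = 1L,
                                     alpha = 0.05) {
  n_tr <- nrow(trials)
  if (n_tr < 2 * folds) stop("too few trials for the fold scheme", call. = FALSE)
  if (min(table(trials$condition)) < folds) {
    stop("need at least `folds` trials per condition", call. = FALSE)
  }
  cz <- pick_channels(rec10, cz_label)
  cz_epochs <- epoch_recording(cz, trials$io_time, c(-2, 2 + 1 / rec10$fs),
    lock = "IO", trial_indices = trials$index
  )
  feats <- list(
    `-1` = extract_features(rec10, timelocked_windows(trials, -1)),
    `0` = extract_features(rec10, timelocked_windows(trials, 0))
  )

  rows <- withr::with_seed(as.integer(seed), {
    purrr::map_dfr(seq_len(repeats), function(rep_i) {
      fold <- make_folds(trials$condition, folds)
      purrr::map_dfr(seq_len(folds), function(f) {
        train_ids <- trials$index[fold != f]
        test_ids <- trials$index[fold == f]
        avg <- train_average_cz(cz_epochs, train_ids)
        mi_start <- select_mi_window(avg, cz_epochs$times)
        fs <- feats[[as.character(mi_start)]]
        tr_sel <- fs$trial_id %in% train_ids
        te_sel <- fs$trial_id %in% test_ids
        model <- fit_slda(fs$X[tr_sel, , drop = FALSE], fs$y[tr_sel])
        pred <- ifelse(decision_values(model, fs$X[te_sel, , drop = FALSE]) > 0,
          "MI", "REST"
        )
        truth <- fs$y[te_sel]
        tibble::tibble(
          repeat_i = rep_i, fold = f, mi_window_start = mi_start,
          n_test = length(truth),
          accuracy = 100 * mean(pred == truth),
          tpr = 100 * mean(pred[truth == "MI"] == "MI"),
          tnr = 100 * mean(pred[truth == "REST"] == "REST")
        )
      })
    })
  })
  rows$fpr <- 100 - rows$tnr
  rows$fnr <- 100 - rows$tpr
  chance <- 100 * adjusted_wald_interval(n_tr, alpha = alpha)
  metrics <- tibble::tibble(
    metric = c("accuracy", "tpr", "fpr", "fnr", "tnr"),
    mean = vapply(c("accuracy", "tpr", "fpr", "fnr", "tnr"), function(m) mean(rows[[m]]), 1, USE.NAMES = FALSE),
    sd = vapply(c("accuracy", "tpr", "fpr", "fnr", "tnr"), function(m) stats::sd(rows[[m]]), 1, USE.NAMES = FALSE)
  )
  structure(
    list(
      metrics = metrics, chance_interval = chance, n_trials = n_tr,
      mi_window_starts = rows$mi_window_start, fold_table = rows,
      alpha = alpha
    ),
    class = "timelocked_result"
  )
}

#' @export
print.timelocked_result <- function(x, ...) {
  acc <- x$metrics[x$metrics$metric == "accuracy", ]
  cat(sprintf(
    "<timelocked_result> accuracy %.1f +/- %.1f%% (chance upper %.1f%%, n = %d trials)\n",
    acc$mean, acc$sd, x$chance_interval[2], x$n_trials
  ))
  invisible(x)
}

#' @method tidy timelocked_result
#' @export
tidy.timelocked_result <- function(x, ...) x$metrics

#' @method glance timelocked_result
#' @export
glance.timelocked_result <- function(x, ...) {
  acc <- x$metrics[x$metrics$metric == "accuracy", ]
  tibble::tibble(
    accuracy = acc$mean, accuracy_sd = acc$sd,
    chance_lo = x$chance_interval[1], chance_hi = x$chance_interval[2],
    n_trials = x$n_trials
  )
}
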