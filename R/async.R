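#' Asynchronous evaluation configuration
#'
#' @param eval_start Seconds after the cue at which the evaluation period
#'   starts (default 1).
#' @param eval_duration Evaluation period length in seconds (default 12).
#' @param window_length Sliding feature window in seconds (default 1).
#' @param prob_threshold MI probability threshold (default 0.5, strict).
#' @param x_range Integer range of the consecutive-detection parameter
#'   (default 5:15).
#' @param n_perm Structured permutations for the chance level (default 500).
#' @param mi_label_duration MI period length in seconds (default 3).
#' @return List of class `async_config`.
#' @export
async_config <- function(eval_start = 1, eval_duration = 12, window_length = 1,
                         prob_threshold = 0.5, x_range = 5:15, n_perm = 500,
                         mi_label_duration = 3) {
  stopifnot(
    eval_duration > mi_label_duration,
    length(x_range) >= 1, all(x_range == as.integer(x_range)), all(x_range >= 1)
  )
  structure(
    list(
      eval_start = eval_start, eval_duration = eval_duration,
      window_length = window_length, prob_threshold = prob_threshold,
      x_range = as.integer(x_range), n_perm = n_perm,
      mi_label_duration = mi_label_duration
    ),
    class = "async_config"
  )
}

# Sliding-window feature matrix for one trial: one row per 10 Hz sample of
# the evaluation period (both endpoints included), features from the
# trailing window [s - 1, s).
trial_sliding_features <- function(rec10, cue_time, cfg) {
  fs <- rec10$fs
  t_eval <- cue_time + cfg$eval_start + (0:round(cfg$eval_duration * fs)) / fs
  rows <- lapply(t_eval - cfg$window_length, function(s) {
    window_feature_vector(rec10, s)
  })
  if (any(vapply(rows, is.null, logical(1)))) {
    stop("trial segment shorter than the evaluation period", call. = FALSE)
  }
  list(F = do.call(rbind, rows), times = t_eval - cue_time) # times rel. cue
}

#' Sliding MI-probability trace of one trial
#'
#' Evaluates the classifier at every 10 Hz sample of the 12 s evaluation
#' period with features from the trailing 1 s window, giving P(MI) per
#' sample.  The MI period is `[IO + mi_start, IO + mi_start + 3]` and the
#' true-positive window is the MI period shifted by +0.5 s (half the
#' sliding window).
#'
#' @param model An `slda` fit.
#' @param sliding Output of the internal sliding-feature builder (list with
#'   `F`, `times`), or a recording via `rec10` + `cue_time`.
#' @param io_rel IO time in seconds relative to the cue.
#' @param mi_start MI window start (-1 or 0 s relative to the IO).
#' @param cfg An [async_config()].
#' @param rec10,cue_time Alternative input: 10 Hz feature recording and the
#'   trial's cue time (seconds).
#' @return Object of class `probability_trace`: `p`, `times` (s relative to
#'   cue), `mi_period`, `tp_window` (s relative to cue).
#' @export
sliding_probability_trace <- function(model, sliding = NULL, io_rel, mi_start,
                                      cfg = async_config(),
                                      rec10 = NULL, cue_time = NULL) {
  if (is.null(sliding)) {
    sliding <- trial_sliding_features(rec10, cue_time, cfg)
  }
  p <- predict_proba(model, sliding$F)
  mi_period <- io_rel + mi_start + c(0, cfg$mi_label_duration)
  structure(
    list(
      p = p, times = sliding$times,
      mi_period = mi_period, tp_window = mi_period + 0.5
    ),
    class = "probability_trace"
  )
}

#' Consecutive-detection rule
#'
#' Sample `s_i` is a detection iff that sample and all `x` previous samples
#' have MI probability strictly above the threshold, i.e. runs of at least
#' `x + 1` supra-threshold samples produce detections at their trailing
#' samples.
#'
#' @param p Probability series.
#' @param x Consecutive-detection parameter (>= 1).
#' @param threshold Strict probability threshold (default 0.5).
#' @return Integer indices of detection samples within `p`.
#' @export
apply_consecutive_rule <- function(p, x, threshold = 0.5) {
  stopifnot(x >= 1)
  ok <- p > threshold
  run <- Reduce(function(acc, v) if (v) acc + 1L else 0L, ok, accumulate = TRUE)
  which(run >= x + 1L)
}

#' Trial verdict from detections
#'
#' A trial is correct iff there is at least one detection inside the
#' (closed) true-positive window and none outside it.
#'
#' @param detection_times Numeric detection times (same clock as
#'   `tp_window`).
#' @param tp_window Length-2 numeric window.
#' @return Tibble with `n_tp`, `n_fp`, `correct`.
#' @export
evaluate_trial <- function(detection_times, tp_window) {
  inside <- detection_times >= tp_window[1] & detection_times <= tp_window[2]
  tibble::tibble(
    n_tp = sum(inside), n_fp = sum(!inside),
    correct = sum(inside) >= 1 && sum(!inside) == 0
  )
}

# Percent of correct trials for a given x over a list of traces.
percent_correct_for_x <- function(traces, x, threshold) {
  ok <- vapply(traces, function(tr) {
    det <- tr$times[apply_consecutive_rule(tr$p, x, threshold)]
    evaluate_trial(det, tr$tp_window)$correct
  }, logical(1))
  100 * mean(ok)
}

#' Optimise the consecutive-detection parameter
#'
#' Scans `x_range` on validation traces and returns the `x` maximising the
#' percentage of correct trials; ties are broken toward the smallest `x`
#' (faster detection).
#'
#' @param traces List of `probability_trace` objects (validation fold).
#' @param x_range Integer candidates (default 5:15).
#' @param threshold Probability threshold (default 0.5).
#' @return The selected integer `x`.
#' @export
optimize_consecutive <- function(traces, x_range = 5:15, threshold = 0.5) {
  if (length(traces) == 0) stop("empty validation set", call. = FALSE)
  pc <- vapply(x_range, percent_correct_for_x,
    numeric(1),
    traces = traces, threshold = threshold
  )
  x_range[which.max(pc)]
}

#' Asynchronous cross-validated trial-based evaluation
#'
#' 10 x 5-fold scheme in which, per repetition and fold, 3 folds train the
#' shrinkage LDA (three MI and three REST windows per trial), 1 fold
#' validates the consecutive-detection parameter x, and 1 fold is tested:
#' sliding probability traces over the 12 s evaluation period are
#' thresholded with the consecutive rule and each test trial is judged
#' correct iff it has at least one true positive and no false positive.
#'
#' @param rec10 Cleaned 0.1-1 Hz recording at 10 Hz, feature channels only.
#' @param trials Valid trial records with `io_time` set.
#' @param cz_label Window-selection channel (default "Cz").
#' @param cfg An [async_config()].
#' @param repeats,folds Scheme (default 10 x 5; `folds` must be >= 3).
#' @param seed Integer seed.
#' @param chance Whether to estimate the structured-permutation chance
#'   level from the first repetition's pooled test detections
#'   (default TRUE).
#' @return Object of class `async_result`: `percent_correct` (mean, sd over
#'   folds), `chosen_x`, `plr`, `chance_level`, `fold_table`, `verdicts`.
#' @export
async_crossvalidate <- function(rec10, trials, cz_label = "Cz",
                                cfg = async_config(), repeats = 10, folds = 5,
                                seed = 1L, chance = TRUE) {
  stopifnot(folds >= 3)
  if (min(table(trials$condition)) < folds) {
    stop("need at least `folds` trials per condition", call. = FALSE)
  }
  cz <- pick_channels(rec10, cz_label)
  cz_epochs <- epoch_recording(cz, trials$io_time, c(-2, 2 + 1 / rec10$fs),
    lock = "IO", trial_indices = trials$index
  )
  feats <- list(
    `-1` = build_async_training_set(rec10, trials, -1),
    `0` = build_async_training_set(rec10, trials, 0)
  )
  sliding <- lapply(seq_len(nrow(trials)), function(i) {
    trial_sliding_features(rec10, trials$cue_time[i], cfg)
  })
  io_rel <- trials$io_time - trials$cue_time

  run_all <- function() {
    fold_rows <- list()
    verdicts <- list()
    detections_rep1 <- vector("list", nrow(trials))
    mi_start_rep1 <- numeric(nrow(trials))
    for (rep_i in seq_len(repeats)) {
      fold <- make_folds(trials$condition, folds)
      for (f in seq_len(folds)) {
        val_f <- f %% folds + 1L
        test_sel <- which(fold == f)
        val_sel <- which(fold == val_f)
        train_sel <- which(fold != f & fold != val_f)
        train_ids <- trials$index[train_sel]
        avg <- train_average_cz(cz_epochs, train_ids)
        mi_start <- select_mi_window(avg, cz_epochs$times)
        fs <- feats[[as.character(mi_start)]]
        tr_sel <- fs$trial_id %in% train_ids
        model <- fit_slda(fs$X[tr_sel, , drop = FALSE], fs$y[tr_sel])
        trace_of <- function(i) {
          sliding_probability_trace(model, sliding[[i]], io_rel[i], mi_start, cfg)
        }
        x_star <- optimize_consecutive(
          lapply(val_sel, trace_of),
          cfg$x_range, cfg$prob_threshold
        )
        vres <- purrr::map_dfr(test_sel, function(i) {
          tr <- trace_of(i)
          det <- tr$times[apply_consecutive_rule(tr$p, x_star, cfg$prob_threshold)]
          if (rep_i == 1L) {
            detections_rep1[[i]] <<- det
            mi_start_rep1[i] <<- mi_start
          }
          v <- evaluate_trial(det, tr$tp_window)
          samples_in_tp <- tr$times >= tr$tp_window[1] & tr$times <= tr$tp_window[2]
          det_idx <- tr$times %in% det
          tibble::tibble(
            repeat_i = rep_i, fold = f, trial_index = trials$index[i],
            n_tp = v$n_tp, n_fp = v$n_fp, correct = v$correct,
            tp_samples = sum(det_idx & samples_in_tp),
            pos_samples = sum(samples_in_tp),
            fp_samples = sum(det_idx & !samples_in_tp),
            neg_samples = sum(!samples_in_tp)
          )
        })
        verdicts[[length(verdicts) + 1]] <- vres
        fold_rows[[length(fold_rows) + 1]] <- tibble::tibble(
          repeat_i = rep_i, fold = f, chosen_x = x_star,
          mi_window_start = mi_start,
          percent_correct = 100 * mean(vres$correct)
        )
      }
    }
    list(
      fold_table = dplyr::bind_rows(fold_rows),
      verdicts = dplyr::bind_rows(verdicts),
      detections_rep1 = detections_rep1,
      mi_start_rep1 = mi_start_rep1
    )
  }
  res <- withr::with_seed(as.integer(seed), run_all())

  v <- res$verdicts
  tpr_s <- sum(v$tp_samples) / max(1, sum(v$pos_samples))
  fpr_s <- sum(v$fp_samples) / max(1, sum(v$neg_samples))
  chance_level <- NA_real_
  if (chance) {
    chance_level <- chance_by_permutation(
      res$detections_rep1, io_rel, res$mi_start_rep1,
      cfg = cfg, n_perm = cfg$n_perm,
      seed = as.integer(seed) + 1L
    )
  }
  structure(
    list(
      percent_correct = c(
        mean = mean(res$fold_table$percent_correct),
        sd = stats::sd(res$fold_table$percent_correct)
      ),
      chosen_x = res$fold_table$chosen_x,
      plr = if (fpr_s > 0) tpr_s / fpr_s else Inf,
      chance_level = chance_level,
      fold_table = res$fold_table,
      verdicts = v
    ),
    class = "async_result"
  )
}

#' @export
print.async_result <- function(x, ...) {
  cat(sprintf(
    "<async_result> %.1f +/- %.1f%% correct trials (chance %.1f%%), PLR %.2f\n",
    x$percent_correct["mean"], x$percent_correct["sd"],
    x$chance_level, x$plr
  ))
  invisible(x)
}

#' Structured-permutation chance level
#'
#' Empirical chance of the trial-based asynchronous evaluation: the
#' observed IOs are shuffled across trials without replacement (preserving
#' the IO marginal distribution), the MI period and true-positive window of
#' every trial are recomputed under the permuted IO, and the trials are
#' re-scored against their unchanged detections.  Assignments whose
#' true-positive window does not fit the evaluation period are redrawn (up
#' to 100 attempts, then kept and counted).
#'
#' @param detections List (one element per trial) of detection times in
#'   seconds relative to the cue.
#' @param io_pool Observed IO times relative to the cue (one per trial).
#' @param mi_starts MI window start per trial (-1 or 0), or a scalar.
#' @param cfg An [async_config()].
#' @param n_perm Number of permutations (default 500, >= 1).
#' @param seed Optional integer seed.
#' @return Chance level as a percentage of correct trials.
#' @export
chance_by_permutation <- function(detections, io_pool, mi_starts = 0,
                                  cfg = async_config(), n_perm = 500,
                                  seed = NULL) {
  if (n_perm < 1) stop("n_perm must be >= 1", call. = FALSE)
  n <- length(detections)
  stopifnot(length(io_pool) == n)
  mi_starts <- rep_len(mi_starts, n)
  eval_lo <- cfg$eval_start
  eval_hi <- cfg$eval_start + cfg$eval_duration
  feasible <- function(perm) {
    tp_lo <- perm + mi_starts + 0.5
    tp_hi <- tp_lo + cfg$mi_label_duration
    all(tp_lo >= eval_lo & tp_hi <= eval_hi)
  }
  run <- function() {
    pc <- numeric(n_perm)
    for (b in seq_len(n_perm)) {
      perm <- sample(io_pool)
      tries <- 0
      while (!feasible(perm) && tries < 100) {
        perm <- sample(io_pool)
        tries <- tries + 1
      }
      ok <- vapply(seq_len(n), function(i) {
        tp <- perm[i] + mi_starts[i] + 0.5 + c(0, cfg$mi_label_duration)
        evaluate_trial(detections[[i]], tp)$correct
      }, logical(1))
      pc[b] <- 100 * mean(ok)
    }
    mean(pc)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
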