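test_that("consecutive-detection rule has the stated off-by-one semantics", {
  expect_length(apply_consecutive_rule(rep(0.4, 50), 5), 0)
  p <- rep(0.1, 40)
  p[10:14] <- 0.9 # run of exactly x = 5
  expect_length(apply_consecutive_rule(p, 5), 0)
  p[15] <- 0.9 # run of x + 1
  expect_equal(apply_consecutive_rule(p, 5), 15L)
  expect_length(apply_consecutive_rule(rep(0.5, 50), 5), 0) # strict threshold
  expect_error(apply_consecutive_rule(p, 0), "x >= 1")
})

test_that("detection sets are nested in x", {
  set.seed(13)
  for (i in 1:200) {
    p <- stats::runif(60)
    x <- sample(5:14, 1)
    d_hi <- apply_consecutive_rule(p, x + 1)
    d_lo <- apply_consecutive_rule(p, x)
    expect_true(all(d_hi %in% d_lo))
  }
})

test_that("trial verdicts demand one true positive and zero false positives", {
  tp <- c(4, 7)
  expect_true(evaluate_trial(5.2, tp)$correct)
  v <- evaluate_trial(c(5.2, 8.0), tp)
  expect_false(v$correct)
  expect_equal(v$n_tp, 1)
  expect_equal(v$n_fp, 1)
  expect_false(evaluate_trial(numeric(0), tp)$correct)
  # closed window boundaries
  expect_true(evaluate_trial(c(4, 7), tp)$correct)
})

test_that("verdicts are invariant to a common time shift", {
  set.seed(3)
  for (i in 1:20) {
    det <- sort(stats::runif(5, 0, 12))
    tp <- c(4, 7)
    delta <- stats::runif(1, -3, 3)
    expect_identical(
      evaluate_trial(det, tp)$correct,
      evaluate_trial(det + delta, tp + delta)$correct
    )
  }
})

test_that("x optimisation scans the range with the low-tie rule", {
  fs <- 10
  times <- 1 + (0:120) / fs
  mk_trace <- function(p) {
    structure(
      list(p = p, times = times, mi_period = c(4, 7), tp_window = c(4.5, 7.5)),
      class = "probability_trace"
    )
  }
  # oracle traces: a long supra-threshold run inside the TP window only
  oracle <- mk_trace({
    p <- rep(0.1, 121)
    p[times >= 4.5 & times <= 7.5] <- 0.95
    p
  })
  expect_equal(optimize_consecutive(list(oracle, oracle)), 5)
  expect_equal(optimize_consecutive(list(oracle), x_range = 11L), 11L)
  expect_error(optimize_consecutive(list()), "empty")

  # a 9-sample noise spike outside the window defeats x <= 8 but not x >= 9
  spiky <- mk_trace({
    p <- rep(0.1, 121)
    p[times >= 4.5 & times <= 7.5] <- 0.95
    p[5:13] <- 0.95
    p
  })
  traces <- list(spiky, oracle)
  x_star <- optimize_consecutive(traces)
  # exhaustive scan oracle
  pc <- vapply(5:15, function(x) {
    mean(vapply(traces, function(tr) {
      det <- tr$times[apply_consecutive_rule(tr$p, x, 0.5)]
      evaluate_trial(det, tr$tp_window)$correct
    }, logical(1)))
  }, 1)
  expect_equal(x_star, (5:15)[which.max(pc)])
  expect_gte(x_star, 9)
})

test_that("async training windows follow the figure-8 layout", {
  trials <- tibble::tibble(
    index = 1:2, condition = c("ID", "EC"),
    trial_start = c(0, 17), cue_time = c(2, 19),
    trial_end = c(15.5, 32.5),
    io_time = c(5, 28), io_true = c(5, 28), valid = TRUE
  )
  w0 <- mrcpdetect:::async_windows(trials[1, ], 0)
  expect_equal(w0$window_start[w0$class == "MI"], c(0, 1, 2))
  expect_equal(w0$window_start[w0$class == "REST"], c(4, 5, 6)) # io+7 <= end
  w1 <- mrcpdetect:::async_windows(trials[2, ], -1)
  expect_equal(w1$window_start[w1$class == "MI"], c(-1, 0, 1))
  expect_equal(w1$window_start[w1$class == "REST"], c(-5, -4, -3)) # io+7 > end

  fx <- make_rec10_fixture(n_trials = 4, seed = 2)
  fs <- build_async_training_set(fx$rec, fx$trials, 0)
  expect_equal(nrow(fs$X), 4 * 6) # 6 observations per fully-usable trial
  expect_equal(ncol(fs$X), 10 * ncol(fx$rec$data))
})

test_that("probability traces cover the evaluation period sample-wise", {
  fx <- make_rec10_fixture(n_trials = 6, noise = 0.3, seed = 5)
  fs <- build_async_training_set(fx$rec, fx$trials, 0)
  model <- fit_slda(fs$X, fs$y)
  tr <- sliding_probability_trace(model,
    io_rel = 4, mi_start = 0,
    rec10 = fx$rec, cue_time = fx$trials$cue_time[1]
  )
  expect_length(tr$p, 121) # 12 s at 10 Hz, both endpoints included
  expect_equal(range(tr$times), c(1, 13))
  expect_true(all(tr$p >= 0 & tr$p <= 1))
  expect_equal(tr$mi_period, c(4, 7))
  expect_equal(tr$tp_window, c(4.5, 7.5))

  # constant signal with a symmetric model gives a constant trace
  rec_const <- eeg_recording(matrix(1, 400, ncol(fx$rec$data)), 10,
    fx$rec$channel_labels,
    channel_types = rep("EEG", ncol(fx$rec$data))
  )
  tr2 <- sliding_probability_trace(model,
    io_rel = 4, mi_start = 0,
    rec10 = rec_const, cue_time = 2, cfg = async_config()
  )
  expect_lt(diff(range(tr2$p)), 1e-12)

  short <- eeg_recording(matrix(1, 50, ncol(fx$rec$data)), 10,
    fx$rec$channel_labels,
    channel_types = rep("EEG", ncol(fx$rec$data))
  )
  expect_error(
    sliding_probability_trace(model,
      io_rel = 4, mi_start = 0,
      rec10 = short, cue_time = 2
    ),
    "shorter"
  )
})

test_that("async cross-validation scores oracle and degenerate classifiers", {
  fx <- make_rec10_fixture(n_trials = 20, peak_amp = -8, noise = 0.05, seed = 8)
  res <- async_crossvalidate(fx$rec, fx$trials,
    repeats = 2, seed = 3,
    cfg = async_config(n_perm = 100)
  )
  expect_equal(unname(res$percent_correct["mean"]), 100) # near-oracle regime
  expect_true(all(res$chosen_x %in% 5:15))
  # every trial tested exactly once per repeat
  expect_equal(nrow(res$verdicts), 2 * 20)
  expect_true(res$chance_level < 100 && res$chance_level >= 0)

  # always-positive classifier: a FP in every trial -> 0 % correct
  times <- 1 + (0:120) / 10
  always <- structure(
    list(
      p = rep(0.99, 121), times = times,
      mi_period = c(4, 7), tp_window = c(4.5, 7.5)
    ),
    class = "probability_trace"
  )
  det <- times[apply_consecutive_rule(always$p, 5)]
  expect_false(evaluate_trial(det, always$tp_window)$correct)
  expect_equal(mrcpdetect:::percent_correct_for_x(list(always), 5, 0.5), 0)
})

test_that("structured-permutation chance matches degenerate closed forms", {
  cfg <- async_config()
  io <- c(3, 4, 5, 6)
  # no detections anywhere -> no true positives -> 0 %
  expect_equal(chance_by_permutation(
    replicate(4, numeric(0), simplify = FALSE), io,
    mi_starts = 0, cfg = cfg, n_perm = 50, seed = 1
  ), 0)
  # detections covering the whole period -> always false positives -> 0 %
  dense <- replicate(4, seq(1, 13, by = 0.1), simplify = FALSE)
  expect_equal(
    chance_by_permutation(dense, io, 0, cfg, n_perm = 50, seed = 2),
    0
  )
  expect_error(chance_by_permutation(dense, io, 0, cfg, n_perm = 0), "n_perm")
})

test_that("permutation chance agrees with the exhaustive assignment oracle", {
  cfg <- async_config()
  set.seed(9)
  n <- 5
  io <- c(3, 4.2, 5.5, 6.3, 7.1)
  mi_starts <- rep(0, n)
  det <- lapply(seq_len(n), function(i) stats::runif(1, 2, 12)) # one detection each

  est <- chance_by_permutation(det, io, mi_starts, cfg, n_perm = 500, seed = 4)

  # enumerate all 5! IO-to-trial assignments
  perms <- as.matrix(expand.grid(rep(list(1:n), n)))
  perms <- perms[apply(perms, 1, function(r) length(unique(r)) == n), , drop = FALSE]
  pc <- apply(perms, 1, function(ord) {
    ok <- vapply(seq_len(n), function(i) {
      tp <- io[ord[i]] + mi_starts[i] + 0.5 + c(0, cfg$mi_label_duration)
      evaluate_trial(det[[i]], tp)$correct
    }, logical(1))
    100 * mean(ok)
  })
  exact <- mean(pc)
  se <- stats::sd(pc) / sqrt(500)
  expect_lt(abs(est - exact), max(2 * se, 1e-8))
})
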