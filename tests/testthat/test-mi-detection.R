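test_that("MI window rule follows the training-average peak latency", {
  fs <- 10
  tgrid <- seq(-2, 2, by = 1 / fs)
  curve_at <- function(lat) -5 * exp(-0.5 * ((tgrid - lat) / 0.3)^2)
  expect_equal(select_mi_window(curve_at(0.4), tgrid), -1)
  expect_equal(select_mi_window(curve_at(0.6), tgrid), 0)
  expect_equal(select_mi_window(curve_at(0.5), tgrid), 0) # "before" is strict
})

test_that("REST window switches exactly at the trial-end boundary", {
  expect_equal(select_rest_window(5, 13.5), c(4, 5)) # io at cue+3
  expect_equal(select_rest_window(11, 13.5), c(-5, -4)) # io at cue+9
  expect_equal(select_rest_window(8.5, 13.5), c(4, 5)) # exact fit is inclusive
  expect_equal(select_rest_window(8.5 + 1e-9, 13.5), c(-5, -4))
  # async 3-window block uses the analogous criterion
  expect_equal(select_rest_window(6.5, 13.5, n_windows = 3), c(4, 7))
  expect_equal(select_rest_window(6.6, 13.5, n_windows = 3), c(-5, -2))
})

test_that("windowed features are 10 consecutive amplitudes per channel", {
  n_ch <- 26
  rec <- eeg_recording(matrix(3, 400, n_ch), 10, paste0("c", 1:n_ch),
    channel_types = rep("EEG", n_ch)
  )
  w <- tibble::tibble(trial_id = 1L, class = "MI", start = 5, window_start = 0)
  fs <- extract_features(rec, w)
  expect_equal(ncol(fs$X), 260)
  expect_true(all(fs$X == 3))

  # windows outside the recording are skipped and logged
  w2 <- tibble::tibble(
    trial_id = c(1L, 2L), class = c("MI", "MI"),
    start = c(5, 300), window_start = c(0, 0)
  )
  fs2 <- extract_features(rec, w2)
  expect_equal(nrow(fs2$X), 1)
  expect_equal(attr(fs2, "skipped"), 2L)
})

test_that("10 Hz downsampling of a slow sinusoid matches the analytic curve", {
  fs <- 250
  t <- (0:(60 * fs - 1)) / fs
  x <- sin(2 * pi * 0.5 * t)
  rec <- eeg_recording(matrix(x), fs, "Cz", channel_types = "EEG")
  ds <- downsample_recording(rec, target_fs = 10)
  t10 <- (seq_len(nrow(ds$data)) - 1) / 10
  interior <- t10 > 2 & t10 < 58
  err <- max(abs(ds$data[interior, 1] - sin(2 * pi * 0.5 * t10[interior])))
  expect_lt(err, 0.02)
  expect_error(downsample_recording(rec, target_fs = 9), "integer multiple")
})

test_that("sLDA separates, shrinks analytically, and honours forced gamma", {
  set.seed(2)
  X1 <- matrix(stats::rnorm(50 * 8), 50, 8)
  X1[, 1] <- X1[, 1] + 10
  X0 <- matrix(stats::rnorm(50 * 8), 50, 8)
  X <- rbind(X1, X0)
  y <- rep(c("MI", "REST"), each = 50)
  m <- fit_slda(X, y)
  expect_equal(mean((decision_values(m, X) > 0) == (y == "MI")), 1)

  m1 <- fit_slda(X, y, gamma = 1)
  dm <- colMeans(X1) - colMeans(X0)
  expect_gt(abs(stats::cor(m1$weights, dm)), 1 - 1e-9)

  # independent Ledoit-Wolf computation on a small fixture
  set.seed(3)
  Xs <- rbind(
    matrix(stats::rnorm(15 * 10), 15, 10) + 1,
    matrix(stats::rnorm(15 * 10), 15, 10)
  )
  ys <- rep(c("MI", "REST"), each = 15)
  ms <- fit_slda(Xs, ys)
  Xc <- Xs
  Xc[1:15, ] <- scale(Xs[1:15, ], scale = FALSE)
  Xc[16:30, ] <- scale(Xs[16:30, ], scale = FALSE)
  n <- 30
  S <- crossprod(Xc) / n
  nu <- mean(diag(S))
  num <- 0
  for (i in 1:n) {
    num <- num + sum((tcrossprod(Xc[i, ]) - S)^2)
  }
  num <- num / n^2
  den <- sum((S - nu * diag(10))^2)
  gamma_ref <- min(1, max(0, num / den))
  expect_equal(ms$shrinkage_gamma, gamma_ref, tolerance = 1e-10)

  # high-dimensional fit: no singularity, positive shrinkage
  set.seed(4)
  Xh <- matrix(stats::rnorm(30 * 260), 30, 260)
  Xh[1:15, 5] <- Xh[1:15, 5] + 2
  mh <- fit_slda(Xh, rep(c("MI", "REST"), each = 15))
  expect_true(all(is.finite(mh$weights)))
  expect_gt(mh$shrinkage_gamma, 0)
  expect_error(fit_slda(X1, rep("MI", 50)), "two classes")

  # broom-style accessors
  expect_equal(nrow(tidy.slda(m)), 8)
  expect_equal(glance.slda(m)$n, 100)
})

test_that("probabilities are a monotone logistic map of decision values", {
  set.seed(5)
  X1 <- matrix(stats::rnorm(40 * 6), 40, 6) + 3
  X0 <- matrix(stats::rnorm(40 * 6), 40, 6)
  m <- fit_slda(rbind(X1, X0), rep(c("MI", "REST"), each = 40))
  mid <- (m$class_means[1, ] + m$class_means[2, ]) / 2
  expect_equal(predict_proba(m, matrix(mid, 1)), 0.5, tolerance = 1e-9)
  expect_gt(predict_proba(m, matrix(m$class_means[2, ], 1)), 0.9)
  p <- predict_proba(m, rbind(X1, X0))
  expect_true(all((p > 0.5) == (decision_values(m, rbind(X1, X0)) > 0)))
  expect_error(predict_proba(m, matrix(0, 1, 3)), "dimension")
})

test_that("adjusted Wald interval matches the closed form and is monotone", {
  z <- stats::qnorm(0.975)
  pt <- (100 * 0.5 + z^2 / 2) / (100 + z^2)
  hw <- z * sqrt(pt * (1 - pt) / (100 + z^2))
  expect_equal(adjusted_wald_interval(100), c(pt - hw, pt + hw))
  expect_equal(round(adjusted_wald_interval(100)[2], 3), 0.596)
  expect_gt(adjusted_wald_interval(50)[2], adjusted_wald_interval(200)[2])
  big <- adjusted_wald_interval(1e7)
  expect_lt(big[2] - big[1], 0.002)
})

test_that("time-locked CV partitions trials, selects windows on train only", {
  fx <- make_rec10_fixture(n_trials = 30, noise = 0.8, seed = 10)
  res <- crossvalidate_timelocked(fx$rec, fx$trials, repeats = 3, seed = 2)
  # every trial tested exactly once per repeat
  expect_equal(sum(res$fold_table$n_test), 3 * 2 * 30)
  expect_true(all(res$mi_window_starts %in% c(-1, 0)))
  acc <- res$metrics[res$metrics$metric == "accuracy", ]
  expect_true(acc$mean >= 0 && acc$mean <= 100)
  expect_equal(
    unname(res$metrics$mean[res$metrics$metric == "tpr"] +
      res$metrics$mean[res$metrics$metric == "fnr"]), 100
  )
  expect_equal(glance(res)$chance_hi, res$chance_interval[2])

  # near-noise-free, large-margin data: perfect accuracy
  fx2 <- make_rec10_fixture(n_trials = 20, peak_amp = -8, noise = 0.05, seed = 3)
  res2 <- crossvalidate_timelocked(fx2$rec, fx2$trials, repeats = 2, seed = 4)
  expect_equal(unname(res2$metrics$mean[res2$metrics$metric == "accuracy"]), 100)
})

test_that("model fitting never touches held-out trials", {
  fx <- make_rec10_fixture(n_trials = 20, noise = 0.5, seed = 6)
  feats <- mrcpdetect:::timelocked_windows(fx$trials, 0)
  fs <- extract_features(fx$rec, feats)
  train_ids <- 1:15
  tr_sel <- fs$trial_id %in% train_ids
  m1 <- fit_slda(fs$X[tr_sel, ], fs$y[tr_sel])
  # swap a held-out trial's label: the trained model must be unchanged
  y2 <- fs$y
  y2[fs$trial_id == 18] <- rev(y2[fs$trial_id == 18])
  m2 <- fit_slda(fs$X[tr_sel, ], y2[tr_sel])
  expect_identical(m1$weights, m2$weights)
  expect_identical(m1$bias, m2$bias)
})

test_that("accuracy does not decrease with template amplitude", {
  accs <- vapply(c(-2, -4, -8), function(a) {
    vals <- vapply(1:3, function(s) {
      fx <- make_rec10_fixture(n_trials = 18, peak_amp = a, noise = 1.6, seed = 100 + s)
      res <- crossvalidate_timelocked(fx$rec, fx$trials, repeats = 2, seed = s)
      unname(res$metrics$mean[res$metrics$metric == "accuracy"])
    }, 1)
    mean(vals)
  }, 1)
  expect_true(sum(diff(accs) < -1e-9) <= 1) # allow one sampling inversion
  expect_gt(accs[3], accs[1] - 1e-9)
})
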