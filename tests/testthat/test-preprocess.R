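test_that("notch filter attenuates the line frequency and spares the passband", {
  fs <- 250
  t <- (0:999) / fs
  line <- matrix(sin(2 * pi * 50 * t))
  out <- notch_filter(line, 50, fs = fs)
  expect_lt(sqrt(mean(out^2)) / sqrt(mean(line^2)), 0.1)

  alpha <- matrix(sin(2 * pi * 10 * t))
  out10 <- notch_filter(alpha, 50, fs = fs)
  expect_lt(abs(sqrt(mean(out10^2)) / sqrt(mean(alpha^2)) - 1), 0.01)

  dc <- matrix(rep(2.5, 600))
  expect_lt(max(abs(notch_filter(dc, 50, fs = fs) - 2.5)), 1e-4)
  expect_error(notch_filter(line, 130, fs = fs), "Nyquist")
})

test_that("band-pass is zero-phase with the stated band edges", {
  fs <- 250
  t <- (0:2499) / fs
  inband <- matrix(sin(2 * pi * 10 * t))
  out <- bandpass_filter(inband, 1, 70, fs = fs)
  expect_lt(abs(sqrt(mean(out[500:2000]^2)) / sqrt(mean(inband[500:2000]^2)) - 1), 0.02)

  slow <- matrix(sin(2 * pi * 0.05 * (0:24999) / fs))
  att <- bandpass_filter(slow, 0.1, 1, fs = fs)
  expect_lt(sqrt(mean(att^2)) / sqrt(mean(slow^2)), 0.2)

  pulse <- matrix(exp(-0.5 * ((0:999 - 500) / 20)^2))
  filtered <- bandpass_filter(pulse, 1, 70, fs = fs)
  expect_equal(which.max(filtered), which.max(pulse))
  expect_error(bandpass_filter(inband, 1, 200, fs = fs), "fs/2")
})

test_that("artifact rejection flags amplitude, probability and kurtosis deviants", {
  set.seed(5)
  n_tr <- 100
  arr <- array(stats::rnorm(n_tr * 2 * 150), c(n_tr, 2, 150))
  arr[60, 1, ] <- stats::rnorm(150, sd = 10) # variance deviant
  arr[10, 2, 75] <- 300 # amplitude spike
  ep <- epochs_from_array(arr, fs = 50)
  rep_ <- detect_artifact_trials(ep)
  expect_true(rep_$flags$amplitude_exceeded[10])
  expect_true(rep_$flags$abnormal_joint_probability[60] ||
    rep_$flags$abnormal_kurtosis[60])
  expect_setequal(
    rep_$removed_trial_indices,
    rep_$flags$trial_index[rep_$flags$amplitude_exceeded |
      rep_$flags$abnormal_joint_probability | rep_$flags$abnormal_kurtosis]
  )

  # all-identical trials: zero across-trial spread -> no statistic flags
  same <- array(rep(sin(seq(0, 6, length.out = 120)), each = 12), c(12, 1, 120))
  rep2 <- detect_artifact_trials(epochs_from_array(same, 50))
  expect_false(any(rep2$flags$abnormal_joint_probability))
  expect_false(any(rep2$flags$abnormal_kurtosis))

  expect_error(detect_artifact_trials(epochs_from_array(arr[1:2, , , drop = FALSE], 50)), "3 trials")
})

test_that("rejection is monotone in the amplitude limit and recovers ground truth", {
  set.seed(11)
  n_tr <- 200
  arr <- array(0, c(n_tr, 3, 200))
  for (i in seq_len(n_tr)) arr[i, , ] <- t(pink_noise(200, 3, 1, 20))
  bad <- sample(n_tr, 20)
  for (i in bad) arr[i, sample(3, 1), sample(200, 1)] <- sample(c(-300, 300), 1)
  ep <- epochs_from_array(arr, 100)
  rep_ <- detect_artifact_trials(ep)
  expect_gte(mean(bad %in% rep_$removed_trial_indices), 0.9)
  clean <- setdiff(seq_len(n_tr), bad)
  expect_lt(mean(clean %in% rep_$removed_trial_indices), 0.1)

  tighter <- detect_artifact_trials(ep, amp_limit = 100)
  expect_true(all(rep_$flags$trial_index[rep_$flags$amplitude_exceeded] %in%
    tighter$flags$trial_index[tighter$flags$amplitude_exceeded]))
})

test_that("pca_reduce picks the smallest k reaching the variance target", {
  set.seed(3)
  X <- matrix(stats::rnorm(500 * 4), 500, 4)
  expect_equal(pca_reduce(X, 1.0)$k, 4)

  # exactly rank 2
  B <- matrix(stats::rnorm(500 * 2), 500, 2)
  X2 <- B %*% matrix(stats::rnorm(8), 2, 4)
  expect_equal(pca_reduce(X2, 0.99)$k, 2)

  # empirical eigenvalues exactly (8, 1, 1): cumulative 0.8, 0.9, 1 -> k = 3
  Z <- matrix(stats::rnorm(300 * 3), 300, 3)
  Z <- scale(Z, center = TRUE, scale = FALSE)
  Z <- Z %*% solve(chol(crossprod(Z) / (nrow(Z) - 1)))
  X3 <- Z %*% diag(sqrt(c(8, 1, 1)))
  p <- pca_reduce(X3, 0.99)
  expect_equal(p$k, 3)
  expect_equal(cumsum(p$explained), c(0.8, 0.9, 1.0), tolerance = 1e-9)
  expect_error(pca_reduce(X, 0), "var_frac")
})

test_that("extended Infomax separates super-Gaussian sources deterministically", {
  set.seed(1)
  n <- 20000
  S <- cbind(stats::rt(n, 3), stats::rt(n, 3) * 0.5)
  X <- S %*% t(matrix(c(1, 0.6, -0.4, 1), 2, 2))
  pca <- pca_reduce(X, 1.0)
  ica <- ica_decompose(pca$scores, seed = 3)
  acts <- sweep(pca$scores, 2, ica$score_mean) %*% t(ica$unmixing)
  r <- abs(stats::cor(acts, S))
  expect_gt(max(r[, 1]), 0.95)
  expect_gt(max(r[, 2]), 0.95)

  # inverse contract
  recon <- acts %*% t(ica$mixing)
  centred <- sweep(pca$scores, 2, ica$score_mean)
  expect_lt(max(abs(recon - centred)) / max(abs(centred)), 1e-6)

  ica2 <- ica_decompose(pca$scores, seed = 3)
  expect_identical(ica$unmixing, ica2$unmixing)
  expect_error(ica_decompose(pca$scores, method = "jade"), "unknown ICA method")
})

test_that("EOG-correlated components are marked and back-projection cleans blinks", {
  set.seed(8)
  n <- 5000
  eog_src <- stats::rbinom(n, 1, 0.01) * 80 # sparse blink-like source
  neural <- cbind(stats::rt(n, 5), stats::rt(n, 5))
  X <- cbind(
    neural[, 1] + 0.8 * eog_src,
    neural[, 2] + 0.5 * eog_src,
    neural[, 1] - neural[, 2] + 0.2 * eog_src
  )
  pca <- pca_reduce(X, 1.0)
  ica <- ica_decompose(pca$scores, seed = 2)
  marked <- mark_artifact_components(ica, pca$scores, matrix(eog_src))
  expect_gte(length(marked), 1)

  # component orthogonal to EOG is not marked
  acts <- sweep(pca$scores, 2, ica$score_mean) %*% t(ica$unmixing)
  r <- abs(stats::cor(acts, eog_src))
  expect_true(all(r[setdiff(seq_len(ica$k), marked)] <= 0.7))

  cleaned <- clean_backproject(X, pca, ica, marked)
  blink_rows <- eog_src > 0
  expect_lt(
    mean(abs(cleaned[blink_rows, 1])),
    0.3 * mean(abs(X[blink_rows, 1]))
  )

  # empty artifact set at full rank reproduces the input; all marked zeroes it
  expect_equal(clean_backproject(X, pca, ica, integer()), X, tolerance = 1e-8)
  allz <- clean_backproject(X, pca, ica, seq_len(ica$k))
  expect_lt(max(abs(sweep(allz, 2, colMeans(X)))), 1e-8)
  expect_error(clean_backproject(X, pca, ica, 99), "range")

  # idempotence
  once <- clean_backproject(X, pca, ica, marked)
  twice <- clean_backproject(once, pca, ica, marked)
  expect_equal(twice, once, tolerance = 1e-10)
})

test_that("session preprocessing removes injected blinks from frontal EEG", {
  sess <- small_session()
  trials <- estimate_io(validate_trials(sess$trials))
  vt <- trials[trials$valid, ]
  pre <- preprocess_session(sess$recording, vt, ica_seed = 5)
  expect_gte(length(pre$artifact_components), 1)

  blinks <- event_onsets(sess$recording, "blink")
  blinks <- blinks[blinks < (nrow(sess$recording$data) / sess$recording$fs - 0.5)]
  blink_peak <- function(rec) {
    ep <- epoch_recording(rec, blinks, c(0, 0.3),
      channels = "Fp1",
      lock = "trial_start"
    )
    max(abs(colMeans(matrix(ep$data[, 1, ], nrow = dim(ep$data)[1]))))
  }
  before <- blink_peak(sess$recording)
  after <- blink_peak(pre$cleaned)
  expect_lt(after, 0.2 * before) # >= 80% reduction of the blink-locked average

  # report serialises
  path <- withr::local_tempfile(fileext = ".json")
  write_preprocess_report(pre, path)
  expect_true(file.exists(path))
  got <- jsonlite::fromJSON(path)
  expect_equal(got$n_components, pre$ica$k)
})

test_that("bad-channel criterion flags a deviant channel and obeys overrides", {
  sess <- small_session()
  rec <- sess$recording
  rec$data[, "Oz"] <- rec$data[, "Oz"] * 8
  bad <- detect_bad_channels(rec)
  expect_true("Oz" %in% bad)
  expect_false("Cz" %in% bad)
  expect_true("Pz" %in% detect_bad_channels(rec, extra = "Pz"))
  expect_length(detect_bad_channels(sess$recording), 0)
})
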