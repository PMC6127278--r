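#' Condition average with t-percentile bootstrap confidence interval
#'
#' Per channel and sample: the mean over trials and a nonparametric
#' t-percentile bootstrap CI of the mean.  Trials are resampled with
#' replacement, each resample is studentised as
#' \eqn{t^* = (\bar{x}^* - \bar{x})/se^*}, the empirical \eqn{\alpha/2} and
#' \eqn{1-\alpha/2} quantiles of \eqn{t^*} are taken, and the interval is
#' inverted around the observed mean and standard error.
#'
#' @param epochs An [eeg_epochs] with at least 2 trials.
#' @param alpha Two-sided level (default 0.05).
#' @param n_boot Bootstrap resamples (default 1000; < 100 warns).
#' @param seed Optional integer seed.
#' @return Object of class `bootstrap_ci`: list with `mean`, `lower`,
#'   `upper` (channels x samples matrices), `times`, `channel_labels`,
#'   `alpha`, `n_boot`.
#' @export
condition_average_ci <- function(epochs, alpha = 0.05, n_boot = 1000, seed = NULL) {
  n <- dim(epochs$data)[1]
  if (n < 2) stop("need at least 2 trials", call. = FALSE)
  if (n_boot < 100) warning("n_boot < 100 gives unstable quantiles")
  n_ch <- dim(epochs$data)[2]
  n_s <- dim(epochs$data)[3]

  idx <- if (is.null(seed)) {
    matrix(sample.int(n, n * n_boot, replace = TRUE), n_boot, n)
  } else {
    withr::with_seed(seed, matrix(sample.int(n, n * n_boot, replace = TRUE), n_boot, n))
  }

  mean_mat <- matrix(0, n_ch, n_s)
  lower <- matrix(0, n_ch, n_s)
  upper <- matrix(0, n_ch, n_s)
  probs <- c(alpha / 2, 1 - alpha / 2)
  for (ch in seq_len(n_ch)) {
    X <- epochs$data[, ch, , drop = TRUE] # trials x samples
    if (is.null(dim(X))) X <- matrix(X, nrow = n)
    m <- colMeans(X)
    se <- sqrt(pmax(colMeans(X^2) - m^2, 0) * n / (n - 1) / n)
    Tq_lo <- numeric(n_s)
    Tq_hi <- numeric(n_s)
    Tb <- matrix(0, n_boot, n_s)
    for (b in seq_len(n_boot)) {
      Xb <- X[idx[b, ], , drop = FALSE]
      mb <- colMeans(Xb)
      seb <- sqrt(pmax(colMeans(Xb^2) - mb^2, 0) * n / (n - 1) / n)
      tb <- (mb - m) / seb
      tb[seb == 0] <- 0
      Tb[b, ] <- tb
    }
    for (s in seq_len(n_s)) {
      q <- stats::quantile(Tb[, s], probs, names = FALSE, type = 7)
      Tq_lo[s] <- q[1]
      Tq_hi[s] <- q[2]
    }
    mean_mat[ch, ] <- m
    lower[ch, ] <- m - Tq_hi * se
    upper[ch, ] <- m - Tq_lo * se
  }
  structure(
    list(
      mean = mean_mat, lower = lower, upper = upper,
      times = epochs$times, channel_labels = epochs$channel_labels,
      alpha = alpha, n_boot = n_boot
    ),
    class = "bootstrap_ci"
  )
}

#' Paired tmax permutation test over channels x time
#'
#' Family-wise-error-controlling paired permutation test: per permutation
#' the paired condition differences are sign-flipped whole-trial-wise, a
#' paired t-statistic is computed at every channel x sample cell, and the
#' signed value with the largest magnitude (`tmax`) enters the reference
#' distribution (the observed labelling included).  Critical values cut off
#' `alpha/2` on each tail; adjusted p-values per cell are the fraction of
#' the `|tmax|` distribution at or above the cell's `|t|`.  When
#' `2^n_pairs <= exhaustive_limit` the full sign-flip enumeration replaces
#' Monte-Carlo sampling and results are exactly reproducible.
#'
#' @param A,B [eeg_epochs] paired by trial (same trial count and axes).
#' @param alpha Two-sided level (default 0.05).
#' @param n_perm Monte-Carlo permutations (default 10000).
#' @param seed Optional integer seed.
#' @param window Optional closed time window (s) to restrict the tested
#'   samples, e.g. `c(0, 2)` for cue-locked use.
#' @param exhaustive_limit Enumerate exhaustively when `2^n_pairs` is at or
#'   below this limit (default 4096).
#' @return Object of class `perm_test_result`: `t_map`, `adjusted_p`,
#'   `significance_mask` (channels x samples), `tmax_distribution`,
#'   `critical_low`, `critical_high`, `times`, `channel_labels`, `n_perm`,
#'   `alpha`, `exhaustive`.
#' @export
tmax_permutation_test <- function(A, B, alpha = 0.05, n_perm = 10000,
                                  seed = NULL, window = NULL,
                                  exhaustive_limit = 4096) {
  if (!identical(dim(A$data), dim(B$data)) ||
    !isTRUE(all.equal(A$times, B$times))) {
    stop("A and B must be paired epoch sets with identical axes", call. = FALSE)
  }
  if (!is.null(window)) {
    A <- crop_epochs(A, window)
    B <- crop_epochs(B, window)
  }
  n <- dim(A$data)[1]
  n_ch <- dim(A$data)[2]
  n_s <- dim(A$data)[3]
  D <- matrix(A$data - B$data, nrow = n) # pairs x (channels*samples)

  exhaustive <- 2^n <= exhaustive_limit
  S <- if (exhaustive) {
    m <- as.matrix(expand.grid(rep(list(c(1, -1)), n)))
    dimnames(m) <- NULL
    m
  } else {
    draw <- function() {
      rbind(
        rep(1, n),
        matrix(sample(c(1, -1), (n_perm - 1) * n, replace = TRUE), n_perm - 1, n)
      )
    }
    if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  }
  n_used <- nrow(S)

  ss <- colSums(D^2)
  big <- .Machine$double.xmax^0.25
  # sign flips leave per-pair squares unchanged, so the permutation variance
  # follows from the fixed sum of squares and the permuted mean; permutations
  # are processed in chunks to bound memory
  t_from_means <- function(Mc) {
    Vc <- pmax(sweep(-n * Mc^2, 2, ss, "+"), 0) / (n - 1)
    denom <- sqrt(Vc / n)
    Tc <- Mc / denom
    zero <- denom == 0
    if (any(zero)) Tc[zero] <- ifelse(abs(Mc[zero]) > 0, sign(Mc[zero]) * big, 0)
    Tc
  }
  t_obs <- drop(t_from_means(matrix(colMeans(D * 1), nrow = 1)))
  tmax <- numeric(n_used)
  chunk <- max(1L, as.integer(2^22 %/% max(1L, ncol(D))))
  for (start in seq(1L, n_used, by = chunk)) {
    rows <- start:min(start + chunk - 1L, n_used)
    Tc <- t_from_means((S[rows, , drop = FALSE] %*% D) / n)
    pick <- max.col(abs(Tc), ties.method = "first")
    tmax[rows] <- Tc[cbind(seq_along(rows), pick)]
  }

  abs_sorted <- sort(abs(tmax))
  adj_p <- (n_used - findInterval(abs(t_obs) - 1e-12, abs_sorted)) / n_used
  crit <- stats::quantile(tmax, c(alpha / 2, 1 - alpha / 2), names = FALSE, type = 1)
  mask <- adj_p <= alpha

  structure(
    list(
      t_map = matrix(t_obs, n_ch, n_s),
      adjusted_p = matrix(adj_p, n_ch, n_s),
      significance_mask = matrix(mask, n_ch, n_s),
      tmax_distribution = tmax,
      critical_low = crit[1], critical_high = crit[2],
      times = A$times, channel_labels = A$channel_labels,
      n_perm = n_used, alpha = alpha, exhaustive = exhaustive
    ),
    class = "perm_test_result"
  )
}

#' @export
print.perm_test_result <- function(x, ...) {
  cat(sprintf(
    "<perm_test_result> %d x %d cells, %d permutations (%s), %d significant\n",
    nrow(x$t_map), ncol(x$t_map), x$n_perm,
    if (x$exhaustive) "exhaustive" else "Monte-Carlo",
    sum(x$significance_mask)
  ))
  invisible(x)
}

#' Summarise significant clusters of a permutation test
#'
#' Contiguous significant runs per channel, as a tidy table.
#'
#' @param result A `perm_test_result`.
#' @return Tibble with columns `channel`, `t_start`, `t_end` (seconds).
#' @export
significant_clusters <- function(result) {
  out <- list()
  for (ch in seq_len(nrow(result$significance_mask))) {
    r <- rle(result$significance_mask[ch, ])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    sig <- which(r$values)
    if (length(sig) > 0) {
      out[[length(out) + 1]] <- tibble::tibble(
        channel = result$channel_labels[ch],
        t_start = result$times[starts[sig]],
        t_end = result$times[ends[sig]]
      )
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(
      channel = character(), t_start = numeric(), t_end = numeric()
    ))
  }
  dplyr::bind_rows(out)
}

#' Plot a condition average with its bootstrap CI
#'
#' @param object A `bootstrap_ci`.
#' @param channels Channels to facet (default first four).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot bootstrap_ci
#' @export
autoplot.bootstrap_ci <- function(object, channels = NULL, ...) {
  channels <- channels %||% utils::head(object$channel_labels, 4)
  idx <- match(channels, object$channel_labels)
  df <- purrr::map_dfr(seq_along(idx), function(k) {
    tibble::tibble(
      channel = channels[k], time = object$times,
      mean = object$mean[idx[k], ],
      lower = object$lower[idx[k], ],
      upper = object$upper[idx[k], ]
    )
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
      alpha = 0.3
    ) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~channel) +
    ggplot2::labs(x = "time (s)", y = "amplitude (µV)")
}
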