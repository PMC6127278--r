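#' PCA dimensionality reduction
#'
#' Projects observations x channels data onto the smallest number of
#' principal axes whose cumulative explained variance reaches `var_frac`.
#'
#' @param X Numeric matrix, observations x channels (>= 2 channels).
#' @param var_frac Target explained-variance fraction in (0, 1]
#'   (default 0.99).
#' @return List with `basis` (channels x k, orthonormal), `scores`
#'   (observations x k), `mean` (channel means), `explained` (per-component
#'   variance fractions) and `k`.
#' @export
pca_reduce <- function(X, var_frac = 0.99) {
  X <- as.matrix(X)
  if (ncol(X) < 2) stop("need at least 2 channels", call. = FALSE)
  if (!(var_frac > 0 && var_frac <= 1)) stop("var_frac must be in (0, 1]", call. = FALSE)
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  eg <- eigen(crossprod(Xc) / (nrow(X) - 1), symmetric = TRUE)
  ev <- pmax(eg$values, 0)
  frac <- ev / sum(ev)
  k <- which(cumsum(frac) >= var_frac - 1e-12)[1]
  basis <- eg$vectors[, seq_len(k), drop = FALSE]
  list(
    basis = basis, scores = Xc %*% basis, mean = mu,
    explained = frac, k = k
  )
}

#' Extended Infomax independent component analysis
#'
#' Natural-gradient extended Infomax on PCA-reduced data: the data are
#' whitened, then an orthogonal-initialised unmixing matrix is updated in
#' mini-batches with the extended rule that switches the component
#' nonlinearity by the sign of its kurtosis, so both super- and
#' sub-Gaussian sources are recovered.  Deterministic under a fixed seed.
#'
#' @param scores Observations x components matrix (PCA scores); observations
#'   should far exceed components.
#' @param method Identifier, currently `"extended-infomax"`.
#' @param seed Integer seed for initialisation and batch shuffling.
#' @param max_pass Maximum passes over the data (default 75).
#' @param lr Initial learning rate (default scaled by component count).
#' @param tol Convergence tolerance on the weight change (default 1e-5).
#' @return List of class `ica_decomposition` with `unmixing` and `mixing`
#'   (k x k, acting on the score space), plus convergence diagnostics.
#'   Compose with the PCA basis for channel-space maps.
#' @export
ica_decompose <- function(scores, method = "extended-infomax", seed = 1L,
                          max_pass = 75, lr = NULL, tol = 1e-5) {
  if (!identical(method, "extended-infomax")) {
    stop("unknown ICA method: ", method, call. = FALSE)
  }
  X <- as.matrix(scores)
  n <- nrow(X)
  k <- ncol(X)
  if (n <= 2 * k) stop("need many more observations than components", call. = FALSE)
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  sdv <- sqrt(colMeans(Xc^2))
  sdv[sdv == 0] <- 1
  Xw <- sweep(Xc, 2, sdv, "/")
  lr <- lr %||% 0.1
  block <- min(n, max(2048L, 32L * k))
  n_blocks <- ceiling(n / block)
  max_pass <- max(10L, min(max_pass, ceiling(6000 / n_blocks)))
  W <- withr::with_seed(seed, {
    Q <- qr.Q(qr(matrix(stats::rnorm(k * k), k, k)))
    perm_seeds <- sample.int(.Machine$integer.max, max_pass)
    attr(Q, "perm_seeds") <- perm_seeds
    Q
  })
  perm_seeds <- attr(W, "perm_seeds")
  attr(W, "perm_seeds") <- NULL
  I_k <- diag(k)
  signs <- rep(1, k)
  converged <- FALSE
  delta <- NA_real_
  for (pass in seq_len(max_pass)) {
    W_old <- W
    ord <- withr::with_seed(perm_seeds[pass], sample.int(n))
    # refresh kurtosis signs on a subsample
    U_all <- Xw[ord[seq_len(min(n, 8192L))], , drop = FALSE] %*% t(W)
    m2 <- colMeans(U_all^2)
    kt <- colMeans(U_all^4) / m2^2 - 3
    signs <- ifelse(kt >= 0, 1, -1)
    for (start in seq(1L, n, by = block)) {
      idx <- ord[start:min(start + block - 1L, n)]
      U <- Xw[idx, , drop = FALSE] %*% t(W)
      th <- tanh(U)
      B <- length(idx)
      G <- I_k - sweep(crossprod(th, U), 1, signs, "*") / B - crossprod(U) / B
      W <- W + lr * G %*% W
      if (!all(is.finite(W)) || max(abs(W)) > 1e8) {
        # blow-up: anneal and restart from the last stable point
        lr <- lr / 2
        W <- W_old
      }
    }
    delta <- max(abs(W - W_old))
    if (delta < tol) {
      converged <- TRUE
      break
    }
    lr <- lr * 0.96
  }
  unmixing <- W %*% diag(1 / sdv, k) # acts on centred scores
  mixing <- solve(unmixing)
  structure(
    list(
      unmixing = unmixing, mixing = mixing,
      score_mean = mu, k = k, method = method, seed = seed,
      converged = converged, final_delta = delta, passes = pass
    ),
    class = "ica_decomposition"
  )
}

# Component activations for centred scores.
ica_activations <- function(ica, scores) {
  sweep(scores, 2, ica$score_mean) %*% t(ica$unmixing)
}

#' Mark artifact components by EOG correlation
#'
#' Components whose activation correlates (absolute Pearson r) with any EOG
#' channel above `corr_thresh` are marked; a manual override list is
#' unioned in.  This automates the visual component screening step.
#'
#' @param ica An `ica_decomposition`.
#' @param scores The PCA scores the decomposition was fitted on (or other
#'   time-aligned scores).
#' @param eog Matrix of time-aligned EOG channel series (samples x channels).
#' @param corr_thresh Absolute correlation threshold (default 0.7).
#' @param extra Integer component indices to mark regardless.
#' @return Sorted integer vector of marked component indices.
#' @export
mark_artifact_components <- function(ica, scores, eog, corr_thresh = 0.7,
                                     extra = integer()) {
  eog <- as.matrix(eog)
  stopifnot(nrow(eog) == nrow(scores))
  acts <- ica_activations(ica, scores)
  r <- abs(stats::cor(acts, eog))
  marked <- which(apply(r, 1, max) > corr_thresh)
  sort(union(marked, as.integer(extra)))
}

#' Back-project non-artifact components
#'
#' Removes the marked components from a recording by projecting its
#' (channel-mean-centred) data through the PCA basis and ICA unmixing,
#' zeroing the artifact components, and back-projecting the remainder into
#' channel space.  The ICA weights are typically fitted on 1-70 Hz epoched
#' data and applied here to notch-only continuous data (including rest
#' runs).  Channel count and event stream are preserved; the operation is
#' idempotent for a fixed decomposition.
#'
#' @param rec An [eeg_recording] (or samples x channels matrix) with the
#'   same channels the decomposition was fitted on.
#' @param pca PCA object from [pca_reduce()].
#' @param ica `ica_decomposition` from [ica_decompose()].
#' @param artifact_idx Integer set of components to remove (within
#'   `1:ica$k`).
#' @return Cleaned object of the same type as `rec`.
#' @export
clean_backproject <- function(rec, pca, ica, artifact_idx = integer()) {
  artifact_idx <- as.integer(artifact_idx)
  if (length(artifact_idx) > 0 &&
    (min(artifact_idx) < 1 || max(artifact_idx) > ica$k)) {
    stop("artifact_idx out of component range", call. = FALSE)
  }
  X <- if (inherits(rec, "eeg_recording")) rec$data else as.matrix(rec)
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  acts <- (Xc %*% pca$basis) %*% t(ica$unmixing)
  if (length(artifact_idx) > 0) acts[, artifact_idx] <- 0
  clean <- sweep(acts %*% t(ica$mixing) %*% t(pca$basis), 2, mu, "+")
  if (inherits(rec, "eeg_recording")) {
    out <- rec
    out$data <- clean
    colnames(out$data) <- rec$channel_labels
    out
  } else {
    clean
  }
}
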