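#' Shrinkage-regularised linear discriminant analysis
#'
#' Two-class LDA whose pooled (within-class) covariance is shrunk toward a
#' scaled identity, \eqn{\tilde\Sigma = (1-\gamma)S + \gamma\nu I} with
#' \eqn{\nu = tr(S)/d}, using the analytic (Ledoit-Wolf) shrinkage
#' intensity estimated from the training data only.  Usable when features
#' outnumber observations.  The positive class is `"MI"`.
#'
#' @param X Numeric matrix, observations x features.
#' @param y Vector of class labels, two classes; `"MI"` is treated as the
#'   positive class (otherwise the second level in sort order).
#' @param gamma Optional fixed shrinkage intensity in [0, 1]; by default the
#'   analytic estimate is used.
#' @return Object of class `slda`: `weights`, `bias`, `shrinkage_gamma`,
#'   `class_means`, `nu`, `classes`, `n`, `d`.  Decision value is
#'   `weights . x + bias`, positive for the MI side of the boundary.
#' @export
fit_slda <- function(X, y, gamma = NULL) {
  X <- as.matrix(X)
  y <- as.character(y)
  classes <- sort(unique(y))
  if (length(classes) != 2) stop("need exactly two classes", call. = FALSE)
  if ("MI" %in% classes) classes <- c(setdiff(classes, "MI"), "MI")
  neg <- classes[1]
  pos <- classes[2]
  n <- nrow(X)
  d <- ncol(X)
  mu_pos <- colMeans(X[y == pos, , drop = FALSE])
  mu_neg <- colMeans(X[y == neg, , drop = FALSE])
  Xc <- X
  Xc[y == pos, ] <- sweep(X[y == pos, , drop = FALSE], 2, mu_pos)
  Xc[y == neg, ] <- sweep(X[y == neg, , drop = FALSE], 2, mu_neg)
  S <- crossprod(Xc) / n
  nu <- mean(diag(S))
  if (is.null(gamma)) {
    # Ledoit-Wolf: gamma = sum_i ||x_i x_i' - S||^2 / n^2 / ||S - nu I||^2
    sum_s2 <- sum(S^2)
    num <- sum(rowSums(Xc^2)^2) / n^2 - sum_s2 / n
    den <- sum_s2 - d * nu^2
    gamma <- if (den > 1e-300) min(1, max(0, num / den)) else 1
  } else {
    stopifnot(gamma >= 0, gamma <= 1)
  }
  S_shrunk <- (1 - gamma) * S
  diag(S_shrunk) <- diag(S_shrunk) + gamma * nu
  w <- drop(solve(S_shrunk, mu_pos - mu_neg))
  b <- -sum(w * (mu_pos + mu_neg)) / 2
  structure(
    list(
      weights = w, bias = b, shrinkage_gamma = gamma,
      class_means = rbind(stats::setNames(mu_neg, NULL), mu_pos),
      nu = nu, classes = c(neg, pos), n = n, d = d
    ),
    class = "slda"
  )
}

#' Decision values and MI probabilities
#'
#' `decision_values` returns `w . x + b`; `predict_proba` maps them through
#' a logistic link so that `p > 0.5` exactly when the decision value is
#' positive.
#'
#' @param model An `slda` fit.
#' @param X Observations x features matrix (feature dimension must match).
#' @return Numeric vector, one value per observation.
#' @export
decision_values <- function(model, X) {
  X <- as.matrix(X)
  if (ncol(X) != model$d) stop("feature dimension mismatch", call. = FALSE)
  drop(X %*% model$weights) + model$bias
}

#' @rdname decision_values
#' @export
predict_proba <- function(model, X) {
  stats::plogis(decision_values(model, X))
}

#' @export
predict.slda <- function(object, newdata, type = c("class", "prob", "decision"), ...) {
  type <- match.arg(type)
  dv <- decision_values(object, newdata)
  switch(type,
    class = ifelse(dv > 0, object$classes[2], object$classes[1]),
    prob = stats::plogis(dv),
    decision = dv
  )
}

#' @export
print.slda <- function(x, ...) {
  cat(sprintf(
    "<slda> %s vs %s, %d features, n = %d, gamma = %.3f\n",
    x$classes[2], x$classes[1], x$d, x$n, x$shrinkage_gamma
  ))
  invisible(x)
}

#' Tidy an sLDA model
#'
#' @param x An `slda` fit.
#' @param ... Unused.
#' @return Tibble with one row per feature: `term`, `estimate` (weight).
#' @method tidy slda
#' @export
tidy.slda <- function(x, ...) {
  tibble::tibble(
    term = paste0("f", seq_along(x$weights)),
    estimate = x$weights
  )
}

#' Glance at an sLDA model
#'
#' @param x An `slda` fit.
#' @param ... Unused.
#' @return One-row tibble: `n`, `d`, `shrinkage_gamma`, `nu`, `bias`.
#' @method glance slda
#' @export
glance.slda <- function(x, ...) {
  tibble::tibble(
    n = x$n, d = x$d, shrinkage_gamma = x$shrinkage_gamma,
    nu = x$nu, bias = x$bias
  )
}
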