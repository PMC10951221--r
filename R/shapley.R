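#' Shapley values of a fitted classifier
#'
#' Attributes each subject's model output (positive-class score) to the
#' input features as Shapley values: the average marginal contribution of
#' a feature over all coalitions of the remaining features, with
#' out-of-coalition features replaced by background observations
#' (interventional expectation over the background rows). With
#' `<= max_exact` features every coalition is enumerated, which satisfies
#' local accuracy exactly: per subject, `base_value + sum(phi)` equals the
#' model's output. Larger subsets use a seeded permutation-sampling
#' estimator.
#'
#' @param model A fitted classifier from `fit_classifier()`, or any
#'   object usable via `predict_fun`.
#' @param X Matrix of subjects to explain (columns = the model's
#'   features).
#' @param background Matrix of background rows (typically the training
#'   rows); non-empty.
#' @param predict_fun `function(model, X) -> numeric scores`; defaults to
#'   the package's positive-class score.
#' @param max_exact Largest feature count for exact enumeration
#'   (default 16).
#' @param nsim Permutations per subject for the sampling estimator
#'   (default 256).
#' @param seed Seed for the sampling estimator.
#' @return A `shapley_result`: list with `phi` (subjects x features),
#'   `base_value` (mean background score), `mean_abs_phi` (per-feature
#'   mean absolute value), `top_feature`.
#' @export
shapley_values <- function(model, X, background,
                           predict_fun = predict_scores,
                           max_exact = 16L, nsim = 256L, seed = 1L) {
  X <- as.matrix(X)
  background <- as.matrix(background)
  if (nrow(background) < 1L) stop("shapley_values: empty background")
  p <- ncol(X)
  phi <- if (p <= max_exact)
    shapley_exact(model, X, background, predict_fun)
  else
    shapley_sampling(model, X, background, predict_fun, nsim, seed)
  colnames(phi) <- colnames(X)
  mean_abs <- colMeans(abs(phi))
  structure(list(
    phi = phi,
    base_value = mean(predict_fun(model, background)),
    mean_abs_phi = mean_abs,
    top_feature = colnames(X)[which.max(mean_abs)]),
    class = "shapley_result")
}

#' @export
print.shapley_result <- function(x, ...) {
  cat(sprintf("<shapley_result> %d subjects x %d features | top: %s\n",
              nrow(x$phi), ncol(x$phi), x$top_feature))
  invisible(x)
}

# Exact enumeration. v(S) for subject i = mean over background rows of the
# model output with in-coalition features from subject i and the rest from
# the background row.
shapley_exact <- function(model, X, background, predict_fun) {
  p <- ncol(X)
  n <- nrow(X)
  nb <- nrow(background)
  n_sets <- 2L^p
  # value function per coalition (rows = subjects)
  V <- matrix(NA_real_, nrow = n, ncol = n_sets)
  for (s in 0:(n_sets - 1L)) {
    members <- which(bitwAnd(s, 2L^(seq_len(p) - 1L)) > 0L)
    big <- background[rep(seq_len(nb), times = n), , drop = FALSE]
    if (length(members) > 0L) {
      rows <- rep(seq_len(n), each = nb)
      big[, members] <- X[rows, members, drop = FALSE]
    }
    sc <- predict_fun(model, big)
    V[, s + 1L] <- colMeans(matrix(sc, nrow = nb))
  }
  fact <- factorial(0:p)
  phi <- matrix(0, nrow = n, ncol = p)
  for (j in seq_len(p)) {
    bit <- 2L^(j - 1L)
    for (s in 0:(n_sets - 1L)) {
      if (bitwAnd(s, bit) > 0L) next
      size <- sum(bitwAnd(s, 2L^(seq_len(p) - 1L)) > 0L)
      w <- fact[size + 1L] * fact[p - size] / fact[p + 1L]
      phi[, j] <- phi[, j] + w * (V[, s + bit + 1L] - V[, s + 1L])
    }
  }
  phi
}

# Permutation-sampling estimator (Castro-style): for each sampled feature
# order, accumulate the marginal contribution of each feature as it joins.
shapley_sampling <- function(model, X, background, predict_fun, nsim,
                             seed) {
  set.seed(seed)
  p <- ncol(X)
  n <- nrow(X)
  nb <- nrow(background)
  phi <- matrix(0, nrow = n, ncol = p)
  for (sim in seq_len(nsim)) {
    ord <- sample.int(p)
    rows <- rep(seq_len(n), each = nb)
    big <- background[rep(seq_len(nb), times = n), , drop = FALSE]
    prev <- colMeans(matrix(predict_fun(model, big), nrow = nb))
    for (j in ord) {
      big[, j] <- X[rows, j]
      cur <- colMeans(matrix(predict_fun(model, big), nrow = nb))
      phi[, j] <- phi[, j] + (cur - prev)
      prev <- cur
    }
  }
  phi / nsim
}
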