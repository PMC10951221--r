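#' Features common to at least `min_models` optimal subsets
#'
#' @param selection_results List of [sequential_forward_selection()]
#'   results (or plain character vectors of selected features), one per
#'   classifier architecture.
#' @param min_models Minimum number of subsets a feature must appear in
#'   (default 3 of 5).
#' @return Character vector of common feature names, ordered by how many
#'   subsets they appear in (ties by first appearance).
#' @export
common_features <- function(selection_results, min_models = 3L) {
  subsets <- lapply(selection_results, function(s)
    if (inherits(s, "selection_result")) s$optimal_subset else
      as.character(s))
  counts <- table(factor(unlist(lapply(subsets, unique)),
                         levels = unique(unlist(subsets))))
  names(counts)[counts >= min_models][
    order(-counts[counts >= min_models])]
}

#' Key features: common features that top a model's Shapley ranking
#'
#' The key-feature set is the intersection-derived list of unique feature
#' names that are common features (in >= 3 of 5 optimal subsets) in some
#' analysis *and* the single top Shapley feature of some model.
#'
#' @param common Character vector (or list of vectors, one per task-set
#'   analysis) of common features.
#' @param shapley_results List of [shapley_values()] results (or plain
#'   top-feature names).
#' @return A `key_feature_set`: list with `common`, `top_shapley`, `key`.
#' @export
key_features <- function(common, shapley_results) {
  common_all <- unique(unlist(common))
  tops <- unique(vapply(shapley_results, function(s)
    if (inherits(s, "shapley_result")) s$top_feature else as.character(s),
    ""))
  structure(list(common = common_all, top_shapley = tops,
                 key = intersect(common_all, tops)),
            class = "key_feature_set")
}

#' @export
print.key_feature_set <- function(x, ...) {
  cat(sprintf(
    "<key_feature_set> %d common | %d top-Shapley | %d key\n",
    length(x$common), length(x$top_shapley), length(x$key)))
  if (length(x$key)) cat(paste(" -", x$key, collapse = "\n"), "\n")
  invisible(x)
}

#' Subjects misclassified by at least `min_models` architectures
#'
#' Uses the out-of-fold predictions of each architecture's [evaluate()]
#' report, so every subject has exactly one prediction per architecture.
#'
#' @param cv_reports List of `cv_report` objects (one per architecture).
#' @param min_models Threshold (default 3 of 5).
#' @return Character vector of subject ids.
#' @export
misclassified_subjects <- function(cv_reports, min_models = 3L) {
  wrong <- lapply(cv_reports, function(r) {
    pr <- r$predictions
    unique(as.character(pr$subject[pr$pred != pr$truth]))
  })
  counts <- table(unlist(wrong))
  names(counts)[counts >= min_models]
}

#' Per-group z-scores of selected features
#'
#' Each feature is standardised by the pooled (all-subject) mean and SD;
#' the reported value is the mean standardised value within each group.
#' For two balanced groups the z-scores are opposite-signed.
#'
#' @param X Feature matrix.
#' @param y Factor of group labels.
#' @param features Column names to report (default all).
#' @return Matrix groups x features of mean within-group z-scores.
#' @export
group_zscores <- function(X, y, features = colnames(X)) {
  X <- as.matrix(X)[, features, drop = FALSE]
  y <- droplevels(as.factor(y))
  mu <- colMeans(X)
  sdv <- apply(X, 2L, stats::sd)
  Z <- sweep(sweep(X, 2L, mu), 2L, ifelse(sdv > 0, sdv, 1), "/")
  out <- t(vapply(levels(y), function(cl)
    colMeans(Z[y == cl, , drop = FALSE]), numeric(ncol(Z))))
  if (ncol(Z) == 1L) {
    out <- matrix(out, ncol = 1L, dimnames = list(levels(y), features))
  }
  out
}

#' Pearson correlation matrix across selected features
#'
#' @param X Feature matrix.
#' @param features Column names (default all).
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
feature_correlation <- function(X, features = colnames(X)) {
  stats::cor(as.matrix(X)[, features, drop = FALSE])
}
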