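#' ANOVA F pre-filter
#'
#' Computes, per feature, the one-way ANOVA F statistic between the label
#' groups (ratio of between-group to within-group mean squares) and its
#' p-value, and retains features with `p <= alpha`. Features with zero
#' between- and within-group variance carry no information and are skipped
#' with a warning.
#'
#' @param X Numeric feature matrix (subjects x features), no missing
#'   values (impute first, see [impute_features()]).
#' @param y Factor of class labels (at least 2 per class).
#' @param alpha Retention threshold on the p-value (default 0.05).
#' @return A data.frame `feature`, `F`, `p`, `retained`, ordered as the
#'   input columns.
#' @export
f_prefilter <- function(X, y, alpha = 0.05) {
  X <- as.matrix(X)
  y <- droplevels(as.factor(y))
  g <- nlevels(y)
  n <- nrow(X)
  if (g < 2L) stop("f_prefilter: need at least two classes")
  if (min(table(y)) < 2L) stop("f_prefilter: need >= 2 subjects per class")
  grand <- colMeans(X)
  ssb <- ssw <- numeric(ncol(X))
  for (cl in levels(y)) {
    Xi <- X[y == cl, , drop = FALSE]
    mi <- colMeans(Xi)
    ssb <- ssb + nrow(Xi) * (mi - grand)^2
    ssw <- ssw + colSums(sweep(Xi, 2L, mi)^2)
  }
  msb <- ssb / (g - 1L)
  msw <- ssw / (n - g)
  Fv <- ifelse(msw > 0, msb / msw, ifelse(msb > 0, Inf, NA_real_))
  p <- stats::pf(Fv, g - 1L, n - g, lower.tail = FALSE)
  p[is.infinite(Fv)] <- 0
  degenerate <- is.na(Fv)
  if (any(degenerate))
    warning("f_prefilter: ", sum(degenerate),
            " feature(s) constant within and between groups; skipped")
  data.frame(feature = colnames(X), F = Fv, p = p,
             retained = !degenerate & !is.na(p) & p <= alpha,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Greedy forward sequential feature selection on CV F1
#'
#' Starting from the empty set, repeatedly appends the candidate feature
#' that maximises the k-fold cross-validated F1 score of the classifier at
#' its default hyperparameters, until all candidates have been added (or
#' `max_features` reached). The optimal subset is the path prefix with the
#' highest CV F1. Ties are broken by column order. One fold partition,
#' fixed up front, is reused for every candidate evaluation so path scores
#' are comparable.
#'
#' @param X Numeric feature matrix of pre-filter survivors.
#' @param y Two-level factor of labels.
#' @param spec A [model_spec()] (default hyperparameters are used during
#'   the path; tune afterwards with [grid_tune()]).
#' @param k CV folds (default 5).
#' @param seed Seed for the fold partition (ignored when `fold` given).
#' @param fold Optional fold assignment shared across architectures.
#' @param max_features Cap on the path length (default all candidates).
#' @return A `selection_result`: list with `path` (data.frame `feature`,
#'   `cv_f1` after each addition), `optimal_subset`, `optimal_f1`.
#' @export
sequential_forward_selection <- function(X, y, spec, k = 5L, seed = 1L,
                                         fold = NULL,
                                         max_features = Inf) {
  X <- as.matrix(X)
  if (ncol(X) < 1L) stop("sequential_forward_selection: no candidates")
  if (is.null(fold)) fold <- stratified_folds(y, k, seed)
  remaining <- colnames(X)
  chosen <- character(0)
  path_f1 <- numeric(0)
  while (length(remaining) > 0L && length(chosen) < max_features) {
    scores <- vapply(remaining, function(f)
      cv_f1(spec, X[, c(chosen, f), drop = FALSE], y, fold), 0)
    best <- which.max(scores)            # first max = column-order ties
    chosen <- c(chosen, remaining[best])
    path_f1 <- c(path_f1, scores[best])
    remaining <- remaining[-best]
  }
  opt <- which.max(path_f1)
  structure(list(
    path = data.frame(feature = chosen, cv_f1 = unname(path_f1),
                      stringsAsFactors = FALSE),
    optimal_subset = chosen[seq_len(opt)],
    optimal_f1 = unname(path_f1[opt])),
    class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf(
    "<selection_result> path length %d | optimal subset %d (CV F1 %.3f)\n",
    nrow(x$path), length(x$optimal_subset), x$optimal_f1))
  invisible(x)
}

#' Grid-search hyperparameter tuning
#'
#' Exhaustively evaluates every combination of the grid by k-fold CV F1 on
#' the given feature subset and returns the spec updated to the best
#' combination. Ties go to the first combination in grid order (the order
#' of [default_grids()], varying the first parameter fastest).
#'
#' @param spec A [model_spec()].
#' @param X Feature matrix restricted to the optimal subset (non-empty).
#' @param y Two-level factor.
#' @param grid Named list of candidate vectors; default the architecture's
#'   entry in [default_grids()].
#' @param k,seed,fold As in [sequential_forward_selection()].
#' @return The tuned `model_spec`, with the grid CV F1 in attribute
#'   `"cv_f1"`.
#' @export
grid_tune <- function(spec, X, y, grid = NULL, k = 5L, seed = 1L,
                      fold = NULL) {
  X <- as.matrix(X)
  if (ncol(X) < 1L) stop("grid_tune: empty feature subset")
  if (is.null(grid)) grid <- default_grids()[[spec$architecture]]
  if (length(grid) == 0L) stop("grid_tune: empty grid")
  if (is.null(fold)) fold <- stratified_folds(y, k, seed)
  combos <- expand.grid(grid, stringsAsFactors = FALSE,
                        KEEP.OUT.ATTRS = FALSE)
  scores <- vapply(seq_len(nrow(combos)), function(i) {
    s <- model_spec(spec$architecture, as.list(combos[i, , drop = FALSE]),
                    seed = spec$seed)
    cv_f1(s, X, y, fold)
  }, 0)
  best <- which.max(scores)
  tuned <- model_spec(spec$architecture,
                      as.list(combos[best, , drop = FALSE]),
                      seed = spec$seed)
  attr(tuned, "cv_f1") <- scores[best]
  tuned
}

#' Compare task-set conditions on fold-level metrics
#'
#' For each pair of task-set conditions, models the fold-level metric with
#' task set and classifier architecture as fixed effects (architecture as
#' a blocking factor, folds paired across architectures) and reports the
#' task-set p-value against the Bonferroni-corrected threshold for the
#' three pairwise comparisons, 0.05/3 (0.017 at 3 s.f.).
#'
#' @param fold_metrics Data.frame with columns `task_set`, `architecture`,
#'   `fold`, `value` — one row per CV fold per architecture per task-set
#'   condition (see [run_all()]).
#' @param alpha Family significance level before correction (default
#'   0.05).
#' @return Data.frame with one row per condition pair: `pair`, `estimate`
#'   (mean metric difference, second minus first), `p`, `threshold`,
#'   `significant`.
#' @export
compare_task_conditions <- function(fold_metrics, alpha = 0.05) {
  needed <- c("task_set", "architecture", "fold", "value")
  if (!all(needed %in% names(fold_metrics)))
    stop("compare_task_conditions: need columns ",
         paste(needed, collapse = ", "))
  sets <- unique(fold_metrics$task_set)
  pairs <- utils::combn(sets, 2L, simplify = FALSE)
  threshold <- alpha / 3
  rows <- lapply(pairs, function(pr) {
    d <- fold_metrics[fold_metrics$task_set %in% pr, ]
    counts <- table(d$task_set, d$architecture)
    counts <- counts[rowSums(counts) > 0, , drop = FALSE]
    if (length(unique(as.vector(counts))) != 1L)
      stop("compare_task_conditions: unbalanced fold counts for pair ",
           paste(pr, collapse = " vs "))
    d$task_set <- factor(d$task_set, levels = pr)
    fit <- if (length(unique(d$architecture)) > 1L)
      stats::lm(value ~ task_set + architecture, data = d)
    else stats::lm(value ~ task_set, data = d)
    an <- stats::anova(fit)
    p <- an["task_set", "Pr(>F)"]
    est <- mean(d$value[d$task_set == pr[2L]]) -
      mean(d$value[d$task_set == pr[1L]])
    data.frame(pair = paste(pr[1L], "vs", pr[2L]), estimate = est,
               p = p, threshold = threshold,
               significant = is.finite(p) & p < threshold,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
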