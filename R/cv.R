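#' Stratified k-fold assignment
#'
#' Shuffles each class independently (seeded) and deals its members
#' round-robin into folds, so fold class proportions match the cohort as
#' closely as integer counts allow. Every subject lands in exactly one
#' fold.
#'
#' @param y Two-level factor of class labels.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return Integer vector of fold ids in `1:k`, one per subject.
#' @export
stratified_folds <- function(y, k = 5L, seed = 1L) {
  if (length(y) < k)
    stop("stratified_folds: fewer subjects (", length(y),
         ") than folds (", k, ")")
  if (min(table(y)) < k)
    stop("stratified_folds: a class has fewer than k = ", k,
         " members; every test fold must contain both classes")
  set.seed(seed)
  fold <- integer(length(y))
  for (cl in levels(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Binary classification metrics
#'
#' Accuracy, precision, recall, F1 (harmonic mean of precision and
#' recall) and Cohen's kappa of predicted versus true labels. The second
#' factor level is the positive class; precision/recall/F1 with an empty
#' denominator are 0.
#'
#' @param truth,pred Factors with identical 2-level codings.
#' @return Named numeric vector `accuracy`, `precision`, `recall`, `f1`,
#'   `kappa`.
#' @export
classification_metrics <- function(truth, pred) {
  stopifnot(identical(levels(truth), levels(pred)))
  pos <- levels(truth)[2L]
  tp <- sum(pred == pos & truth == pos)
  fp <- sum(pred == pos & truth != pos)
  fn <- sum(pred != pos & truth == pos)
  acc <- mean(pred == truth)
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  rec <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  # chance-corrected agreement
  n <- length(truth)
  pe <- sum(vapply(levels(truth), function(l)
    sum(truth == l) * sum(pred == l), 0)) / n^2
  kappa <- if (pe < 1) (acc - pe) / (1 - pe) else 0
  c(accuracy = acc, precision = prec, recall = rec, f1 = f1, kappa = kappa)
}

# Mean k-fold CV F1 of a spec on X, given a fold assignment.
cv_f1 <- function(spec, X, y, fold) {
  f1s <- vapply(sort(unique(fold)), function(kf) {
    tr <- fold != kf
    m <- fit_classifier(spec, X[tr, , drop = FALSE], y[tr])
    classification_metrics(y[!tr],
                           predict_labels(m, X[!tr, , drop = FALSE]))[["f1"]]
  }, 0)
  mean(f1s)
}

#' Stratified cross-validated evaluation
#'
#' Fits the classifier on each training fold and scores the held-out fold:
#' per-fold accuracy, precision, recall, F1 and kappa with their means and
#' standard errors; a fold-averaged ROC curve (vertical averaging of the
#' per-fold step curves on a common 101-point FPR grid) with mean AUC and
#' its SEM; and the out-of-fold prediction for every subject.
#'
#' @param spec A [model_spec()].
#' @param X Numeric feature matrix (subjects x features), typically an
#'   optimal subset of a normalized [build_feature_table()].
#' @param y Two-level factor; second level is the positive class.
#' @param k Folds (default 5).
#' @param seed Seed for the fold assignment (ignored when `fold` given).
#' @param fold Optional precomputed fold assignment, so several
#'   architectures can share one partition for paired comparisons.
#' @param preprocess Optional `function(X, train_rows)` returning a
#'   transformed copy of `X` fit only on the training rows (leakage-safe
#'   per-fold normalization/filtering); `NULL` evaluates `X` as given.
#' @return A `cv_report`: list with `folds`, `metrics` (per-fold matrix),
#'   `summary` (mean and SEM per metric), `roc` (data.frame `fpr`,
#'   `mean_tpr`), `auc_mean`, `auc_sem`, `predictions` (data.frame
#'   `subject`, `fold`, `truth`, `pred`, `score`).
#' @export
evaluate <- function(spec, X, y, k = 5L, seed = 1L, fold = NULL,
                     preprocess = NULL) {
  X <- as.matrix(X)
  if (is.null(fold)) fold <- stratified_folds(y, k, seed)
  ks <- sort(unique(fold))
  for (kf in ks)
    if (nlevels(droplevels(y[fold == kf])) < 2L)
      stop("evaluate: test fold ", kf, " contains a single class")
  fpr_grid <- seq(0, 1, length.out = 101L)
  metrics <- NULL
  tprs <- NULL
  aucs <- numeric(0)
  preds <- list()
  for (kf in ks) {
    tr <- fold != kf
    Xk <- if (is.null(preprocess)) X else preprocess(X, which(tr))
    m <- fit_classifier(spec, Xk[tr, , drop = FALSE], y[tr])
    te <- which(!tr)
    lab <- predict_labels(m, Xk[te, , drop = FALSE])
    sc <- predict_scores(m, Xk[te, , drop = FALSE])
    metrics <- rbind(metrics, classification_metrics(y[te], lab))
    rc <- fold_roc(y[te], sc, fpr_grid)
    tprs <- rbind(tprs, rc$tpr)
    aucs <- c(aucs, rc$auc)
    preds[[length(preds) + 1L]] <- data.frame(
      subject = if (!is.null(rownames(X))) rownames(X)[te] else te,
      fold = kf, truth = y[te], pred = lab, score = sc,
      stringsAsFactors = FALSE)
  }
  sem <- function(v) stats::sd(v) / sqrt(length(v))
  structure(list(
    folds = fold,
    metrics = metrics,
    summary = rbind(mean = colMeans(metrics), sem = apply(metrics, 2L, sem)),
    roc = data.frame(fpr = fpr_grid, mean_tpr = colMeans(tprs)),
    auc_mean = mean(aucs), auc_sem = sem(aucs),
    predictions = do.call(rbind, preds)),
    class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf(
    "<cv_report> %d folds | AUC %.3f +/- %.3f | F1 %.3f | acc %.3f\n",
    length(unique(x$folds)), x$auc_mean, x$auc_sem,
    x$summary["mean", "f1"], x$summary["mean", "accuracy"]))
  invisible(x)
}

# One fold's ROC: AUC via pROC, TPR interpolated on the FPR grid
# (step-function convention: highest sensitivity attained at FPR <= f).
fold_roc <- function(truth, score, fpr_grid) {
  if (length(unique(score)) < 2L)
    return(list(auc = 0.5, tpr = fpr_grid))
  r <- pROC::roc(response = truth, predictor = score,
                 levels = levels(truth), direction = "<", quiet = TRUE)
  fpr <- 1 - r$specificities
  tpr <- r$sensitivities
  o <- order(fpr, tpr)
  fpr <- fpr[o]; tpr <- tpr[o]
  tpr_at <- vapply(fpr_grid, function(f) max(tpr[fpr <= f + 1e-12], 0), 0)
  list(auc = as.numeric(pROC::auc(r)), tpr = tpr_at)
}
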