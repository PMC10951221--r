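#' Run one classification experiment on one task set
#'
#' Executes the full selection-classification-interpretation stack on a
#' cohort feature table: restrict to the task set, impute missing markers,
#' min-max normalize, ANOVA F pre-filter, forward sequential feature
#' selection per architecture, grid tuning, stratified cross-validated
#' evaluation, and interpretation (common features, per-model top Shapley
#' features, misclassification, z-scores, correlations). One stratified
#' fold partition is shared by all architectures so comparisons are
#' paired.
#'
#' Two leakage modes are provided. `"global"` (default) fits the
#' min-max scaler and the pre-filter once on all subjects before
#' cross-validation, replicating the single global scaling of the
#' reference analysis. `"leakage_safe"` re-fits the scaler inside every
#' evaluation fold on its training rows only (the selected subset is
#' still from the global path), giving less optimistic metrics.
#'
#' @param table A [build_feature_table()] result covering the subjects to
#'   classify.
#' @param labels Two-level factor (or coercible) aligned with
#'   `table$meta`; second level is the positive class.
#' @param task_set `"static"`, `"active"` or `"static_active"`.
#' @param specs Named list of [model_spec()]s (default all five
#'   architectures).
#' @param alpha Pre-filter threshold (default 0.05).
#' @param k CV folds (default 5).
#' @param seed Seed controlling folds and stochastic fits.
#' @param max_features SFS path cap (default 10; `Inf` for the full
#'   path).
#' @param tune Run [grid_tune()] after subset selection? Default `TRUE`.
#' @param shapley Compute per-model Shapley values? Default `TRUE`.
#' @param leakage `"global"` or `"leakage_safe"`.
#' @return An `experiment_result`: list with `task_set`, `prefilter`,
#'   `selection` (per architecture), `tuned_specs`, `reports`, `common`,
#'   `shapley` (per architecture), `top_shapley`, `misclassified`,
#'   `zscores`, `correlations`, `labels`, `seed`.
#' @export
run_experiment <- function(table, labels,
                           task_set = c("static_active", "static",
                                        "active"),
                           specs = default_model_specs(),
                           alpha = 0.05, k = 5L, seed = 1L,
                           max_features = 10L, tune = TRUE,
                           shapley = TRUE,
                           leakage = c("global", "leakage_safe")) {
  task_set <- match.arg(task_set)
  leakage <- match.arg(leakage)
  y <- droplevels(as.factor(labels))
  if (nlevels(y) != 2L)
    stop("run_experiment: labels must have exactly two classes")

  tab <- feature_table_subset(table, task_set)
  tab <- impute_features(tab)
  raw <- tab$x
  norm <- minmax_normalize(tab)$x

  pre <- f_prefilter(norm, y, alpha = alpha)
  survivors <- pre$feature[pre$retained]
  if (length(survivors) == 0L)
    stop("run_experiment: the pre-filter removed every feature (stage: ",
         task_set, " pre-filter)")
  Xs <- norm[, survivors, drop = FALSE]

  fold <- stratified_folds(y, k, seed)
  preprocess <- if (leakage == "leakage_safe") {
    function(X, train_rows) {
      ft <- structure(list(x = raw[, colnames(X), drop = FALSE],
                           meta = NULL), class = "feature_table")
      minmax_normalize(ft, fit_rows = train_rows)$x
    }
  } else NULL

  selection <- list()
  tuned <- list()
  reports <- list()
  shapleys <- list()
  for (nm in names(specs)) {
    sel <- sequential_forward_selection(Xs, y, specs[[nm]], k = k,
                                        fold = fold,
                                        max_features = max_features)
    selection[[nm]] <- sel
    sub <- sel$optimal_subset
    sp <- if (tune)
      grid_tune(specs[[nm]], Xs[, sub, drop = FALSE], y, fold = fold)
    else specs[[nm]]
    tuned[[nm]] <- sp
    reports[[nm]] <- evaluate(sp, Xs[, sub, drop = FALSE], y, k = k,
                              fold = fold, preprocess = preprocess)
    if (shapley) {
      m <- fit_classifier(sp, Xs[, sub, drop = FALSE], y)
      shapleys[[nm]] <- shapley_values(
        m, Xs[, sub, drop = FALSE], Xs[, sub, drop = FALSE],
        seed = seed)
    }
  }

  common <- common_features(selection)
  structure(list(
    task_set = task_set, leakage = leakage,
    prefilter = pre,
    selection = selection, tuned_specs = tuned, reports = reports,
    common = common,
    shapley = shapleys,
    top_shapley = if (shapley)
      vapply(shapleys, `[[`, "", "top_feature") else character(0),
    misclassified = misclassified_subjects(reports),
    zscores = if (length(common) > 0L)
      group_zscores(norm, y, common) else NULL,
    correlations = if (length(common) > 1L)
      feature_correlation(norm, common) else NULL,
    labels = y, seed = seed),
    class = "experiment_result")
}

#' @export
print.experiment_result <- function(x, ...) {
  aucs <- vapply(x$reports, `[[`, 0, "auc_mean")
  cat(sprintf(
    "<experiment_result> %s | %d survivors | common: %d | AUC %s\n",
    x$task_set, sum(x$prefilter$retained), length(x$common),
    paste(sprintf("%s %.2f", names(aucs), aucs), collapse = ", ")))
  invisible(x)
}

#' Run the full classification x task-set grid
#'
#' Runs [run_experiment()] for every classification (a named list of
#' label factors, e.g. PD vs controls and fallers vs non-fallers) crossed
#' with the three task sets, intersects each classification's common and
#' top-Shapley features into its key-feature set, and assembles fold-level
#' metrics for [compare_task_conditions()].
#'
#' @param table A [build_feature_table()] over all subjects.
#' @param classifications Named list; each element is a vector of labels
#'   aligned with `table$meta` in which `NA` drops a subject from that
#'   classification.
#' @param task_sets Task sets to run (default all three).
#' @param metric Metric summarised into `fold_metrics` (default `"f1"`).
#' @param ... Passed to [run_experiment()].
#' @return A `run_all_result`: list with `experiments` (nested
#'   classification -> task set), `key` (per classification, a
#'   [key_features()] set over its three task-set analyses), `summary`
#'   (data.frame of mean +/- SEM metrics per cell), `fold_metrics`, and
#'   `comparisons` (per classification, [compare_task_conditions()] on
#'   the fold-level metric).
#' @export
run_all <- function(table, classifications,
                    task_sets = c("static", "active", "static_active"),
                    metric = "f1", ...) {
  experiments <- list()
  key <- list()
  summary_rows <- list()
  fold_rows <- list()
  comparisons <- list()
  for (cname in names(classifications)) {
    labels <- classifications[[cname]]
    keep <- !is.na(labels)
    if (sum(keep) == 0L) {
      experiments[[cname]] <- list()
      key[cname] <- list(NULL)
      next
    }
    sub_table <- structure(
      list(x = table$x[keep, , drop = FALSE],
           meta = table$meta[keep, , drop = FALSE]),
      class = "feature_table")
    y <- droplevels(as.factor(labels[keep]))
    experiments[[cname]] <- list()
    for (ts in task_sets) {
      ex <- run_experiment(sub_table, y, task_set = ts, ...)
      experiments[[cname]][[ts]] <- ex
      for (nm in names(ex$reports)) {
        r <- ex$reports[[nm]]
        summary_rows[[length(summary_rows) + 1L]] <- data.frame(
          classification = cname, task_set = ts, architecture = nm,
          metric_mean = r$summary["mean", metric],
          metric_sem = r$summary["sem", metric],
          auc_mean = r$auc_mean, auc_sem = r$auc_sem,
          stringsAsFactors = FALSE)
        fold_rows[[length(fold_rows) + 1L]] <- data.frame(
          classification = cname, task_set = ts, architecture = nm,
          fold = seq_len(nrow(r$metrics)), value = r$metrics[, metric],
          stringsAsFactors = FALSE)
      }
    }
    key[[cname]] <- key_features(
      lapply(experiments[[cname]], `[[`, "common"),
      unlist(lapply(experiments[[cname]], `[[`, "shapley"),
             recursive = FALSE))
  }
  fold_metrics <- do.call(rbind, fold_rows)
  for (cname in names(classifications)) {
    fm <- fold_metrics[fold_metrics$classification == cname, ]
    comparisons[[cname]] <- if (nrow(fm) > 0L &&
                                length(unique(fm$task_set)) > 1L)
      compare_task_conditions(fm) else NULL
  }
  structure(list(experiments = experiments, key = key,
                 summary = do.call(rbind, summary_rows),
                 fold_metrics = fold_metrics,
                 comparisons = comparisons),
            class = "run_all_result")
}

#' @export
print.run_all_result <- function(x, ...) {
  cat("<run_all_result>\n")
  print(x$summary, digits = 3)
  invisible(x)
}

#' Standard classification label sets from cohort metadata
#'
#' Builds the three label factors of the study design from a
#' [subject_meta()] table: PD vs young controls, PD vs age-matched
#' controls, and PD fallers vs PD non-fallers (subjects outside a
#' comparison are `NA`). Positive class is PD (resp. faller).
#'
#' @param meta Data.frame with `group` and `faller` columns.
#' @return Named list of three label factors.
#' @export
classification_labels <- function(meta) {
  lab <- function(keep, y, lev) {
    out <- factor(rep(NA_character_, nrow(meta)), levels = lev)
    out[keep] <- y[keep]
    out
  }
  pd <- meta$group == "pd"
  list(
    pd_vs_young = lab(pd | meta$group == "young_control",
                      ifelse(pd, "pd", "control"), c("control", "pd")),
    pd_vs_age_matched = lab(pd | meta$group == "age_matched_control",
                            ifelse(pd, "pd", "control"),
                            c("control", "pd")),
    faller_vs_nonfaller = lab(pd & !is.na(meta$faller),
                              ifelse(!is.na(meta$faller) & meta$faller,
                                     "faller", "nonfaller"),
                              c("nonfaller", "faller")))
}
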