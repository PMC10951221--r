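#' Compute the full 60-feature vector for one foot and task
#'
#' Concatenates the 19 positional, 21 dynamic and 20 spectral features of a
#' COP trajectory. Measures undefined on the input (too few valid frames,
#' degenerate limits) carry `NA` markers, never silent zeros.
#'
#' @param traj A `cop_trajectory`.
#' @return Named numeric vector of length 60.
#' @export
compute_foot_features <- function(traj) {
  c(positional_features(traj), dynamic_features(traj),
    frequency_features(traj))
}

#' Combine per-foot features across feet
#'
#' `combine_average()` is the across-feet mean, per feature:
#' \eqn{(L + R)/2}. `combine_asymmetry()` is the absolute difference
#' relative to the sum: \eqn{|L - R| / (L + R)}; it lies in `[0, 1]`
#' whenever both inputs are non-negative. A zero denominator yields 0 when
#' both sides are exactly 0 (no asymmetry in an absent quantity) and `NA`
#' otherwise. Signed features can make the denominator negative; the ratio
#' is still computed as defined, and the names of affected features are
#' attached as attribute `"flagged_denominator"`.
#'
#' @param left,right Named 60-feature vectors from
#'   [compute_foot_features()].
#' @return Named numeric vector of the same length; `NA` where either side
#'   is `NA`.
#' @export
combine_average <- function(left, right) {
  stopifnot(identical(names(left), names(right)))
  (left + right) / 2
}

#' @rdname combine_average
#' @export
combine_asymmetry <- function(left, right) {
  stopifnot(identical(names(left), names(right)))
  denom <- left + right
  out <- abs(left - right) / denom
  zero_both <- !is.na(denom) & denom == 0 &
    !is.na(left) & left == 0 & !is.na(right) & right == 0
  out[zero_both] <- 0
  out[!is.na(denom) & denom == 0 & !zero_both] <- NA_real_
  flagged <- names(out)[!is.na(denom) & denom < 0]
  if (length(flagged) > 0L) attr(out, "flagged_denominator") <- flagged
  out
}

#' Build the cohort feature table
#'
#' For every subject and task, both feet's recordings are (optionally)
#' anti-alias down-sampled to `target_rate`, converted to COP trajectories
#' and reduced to 60-feature vectors; the across-feet average and asymmetry
#' combinations give 120 columns per task (720 for all six). For the
#' one-foot stance task (`OF`) only the weight-bearing foot is considered:
#' the left-stance segments of the trial yield the "left" vector and the
#' right-stance segments the "right" vector, which are then combined as a
#' between-stance average/asymmetry.
#'
#' Column names are structured as `<cop_type>|<task>|<feature>` with
#' `cop_type` in `average`/`asymmetric`. Subjects missing a task carry `NA`
#' in its columns; subjects with no usable recording for a task are flagged
#' with a warning.
#'
#' @param recordings List of [insole_recording()] objects covering the
#'   cohort.
#' @param meta Data.frame from [subject_meta()] with one row per subject.
#' @param geom A [zone_geometry()].
#' @param tasks Tasks to include (default all six).
#' @param target_rate Common analysis rate in Hz (default 12); recordings
#'   at a higher rate are anti-alias down-sampled first, per
#'   [antialias_downsample()].
#' @return A `feature_table`: list with `x` (numeric matrix, one row per
#'   subject, structured column names) and `meta`.
#' @export
build_feature_table <- function(recordings, meta,
                                geom = default_zone_geometry(),
                                tasks = all_tasks(), target_rate = 12) {
  tasks <- intersect(all_tasks(), tasks)
  subjects <- meta$subject_id
  cols <- feature_table_columns(tasks)
  x <- matrix(NA_real_, nrow = length(subjects), ncol = length(cols),
              dimnames = list(subjects, cols))
  key <- function(r) paste(r$subject_id, r$task, r$foot, sep = "\r")
  index <- stats::setNames(seq_along(recordings),
                           vapply(recordings, key, ""))
  for (s in subjects) {
    for (tk in tasks) {
      il <- index[paste(s, tk, "left", sep = "\r")]
      ir <- index[paste(s, tk, "right", sep = "\r")]
      if (is.na(il) && is.na(ir)) next
      if (is.na(il) || is.na(ir)) {
        warning("build_feature_table: subject ", s, " task ", tk,
                " has only one foot recorded; task skipped")
        next
      }
      rl <- recordings[[il]]; rr <- recordings[[ir]]
      if (rl$sampling_rate > target_rate)
        rl <- antialias_downsample(rl, target_rate)
      if (rr$sampling_rate > target_rate)
        rr <- antialias_downsample(rr, target_rate)
      fv <- task_foot_vectors(rl, rr, geom)
      if (is.null(fv)) {
        warning("build_feature_table: subject ", s, " task ", tk,
                " unusable; skipped")
        next
      }
      avg <- combine_average(fv$left, fv$right)
      asym <- combine_asymmetry(fv$left, fv$right)
      x[s, paste("average", tk, names(avg), sep = "|")] <- avg
      x[s, paste("asymmetric", tk, names(asym), sep = "|")] <- asym
    }
  }
  structure(list(x = x, meta = meta), class = "feature_table")
}

# The left/right 60-feature vectors for one subject-task; for OF these are
# the weight-bearing-foot vectors of the left- and right-stance halves.
task_foot_vectors <- function(rec_left, rec_right, geom) {
  if (rec_left$task == "OF") {
    seg <- tryCatch(segment_one_foot(rec_left, rec_right),
                    error = function(e) NULL)
    if (is.null(seg)) return(NULL)
    tl <- tryCatch(compute_cop(rec_left, geom), error = function(e) NULL)
    tr <- tryCatch(compute_cop(rec_right, geom), error = function(e) NULL)
    if (is.null(tl) || is.null(tr)) return(NULL)
    list(left = compute_foot_features(restrict_trajectory(tl, seg$left)),
         right = compute_foot_features(restrict_trajectory(tr, seg$right)))
  } else {
    tl <- tryCatch(compute_cop(rec_left, geom), error = function(e) NULL)
    tr <- tryCatch(compute_cop(rec_right, geom), error = function(e) NULL)
    if (is.null(tl) || is.null(tr)) return(NULL)
    list(left = compute_foot_features(tl),
         right = compute_foot_features(tr))
  }
}

#' @rdname build_feature_table
#' @param x,... Print method arguments.
#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d subjects x %d features (%s)\n",
              nrow(x$x), ncol(x$x),
              paste(unique(sub("^[^|]+\\|([^|]+)\\|.*$", "\\1",
                               colnames(x$x))), collapse = ", ")))
  invisible(x)
}

# Structured column names for a task subset.
feature_table_columns <- function(tasks) {
  unlist(lapply(tasks, function(tk)
    c(paste("average", tk, feature_names(), sep = "|"),
      paste("asymmetric", tk, feature_names(), sep = "|"))))
}

#' Restrict a feature table to a task set
#'
#' @param table A `feature_table`.
#' @param task_set `"static"`, `"active"` or `"static_active"`.
#' @return A `feature_table` with only the matching columns.
#' @export
feature_table_subset <- function(table, task_set) {
  tasks <- task_set_tasks(task_set)
  col_task <- sub("^[^|]+\\|([^|]+)\\|.*$", "\\1", colnames(table$x))
  structure(list(x = table$x[, col_task %in% tasks, drop = FALSE],
                 meta = table$meta), class = "feature_table")
}

#' Impute missing feature values by column medians
#'
#' Missing markers (tasks a subject could not complete, degenerate-limit
#' features) are replaced by the column median over available subjects;
#' columns that are entirely missing are set to 0 with a warning.
#'
#' @param table A `feature_table`.
#' @return The imputed `feature_table`.
#' @export
impute_features <- function(table) {
  x <- table$x
  for (j in seq_len(ncol(x))) {
    na <- is.na(x[, j])
    if (!any(na)) next
    if (all(na)) {
      warning("impute_features: column ", colnames(x)[j],
              " is entirely missing; set to 0")
      x[, j] <- 0
    } else x[na, j] <- stats::median(x[!na, j])
  }
  table$x <- x
  table
}

#' Min-max normalize a feature table
#'
#' Per column, maps `x` to `(x - min) / (max - min)` with the minimum and
#' maximum taken over `fit_rows` (default all subjects, replicating a
#' single global scaling; pass the training rows of a fold for a
#' leakage-safe variant). Values of rows outside `fit_rows` may fall
#' outside `[0, 1]` and are not clipped unless `clip = TRUE`. Constant
#' columns map to 0.
#'
#' @param table A `feature_table`.
#' @param fit_rows Row indices (or subject ids) the scaler is fit on;
#'   `NULL` for all.
#' @param clip Clip the result into `[0, 1]`? Default `FALSE`.
#' @return The normalized `feature_table`.
#' @export
minmax_normalize <- function(table, fit_rows = NULL, clip = FALSE) {
  x <- table$x
  rows <- if (is.null(fit_rows)) seq_len(nrow(x))
          else if (is.character(fit_rows)) match(fit_rows, rownames(x))
          else fit_rows
  lo <- apply(x[rows, , drop = FALSE], 2L, min, na.rm = TRUE)
  hi <- apply(x[rows, , drop = FALSE], 2L, max, na.rm = TRUE)
  span <- hi - lo
  const <- !is.finite(span) | span == 0
  for (j in seq_len(ncol(x))) {
    x[, j] <- if (const[j]) 0 else (x[, j] - lo[j]) / span[j]
  }
  if (clip) x <- pmin(pmax(x, 0), 1)
  table$x <- x
  table
}
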