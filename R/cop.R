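#' Compute a per-foot center-of-pressure trajectory
#'
#' The COP at each frame is the force-weighted centroid of the 8 zone
#' coordinates:
#' \deqn{COP_{ML} = \sum_i F_i D_{ML,i} / \sum_i F_i, \qquad
#'       COP_{AP} = \sum_i F_i D_{AP,i} / \sum_i F_i.}
#' Frames whose total force falls below `force_threshold` (swing phases in
#' gait, a lifted foot in one-foot stance) have an undefined centroid and
#' are marked invalid; they are excluded from all downstream feature
#' computations rather than interpolated or zero-filled.
#'
#' @param rec An [insole_recording()].
#' @param geom A [zone_geometry()] whose zone order matches the force
#'   columns.
#' @param force_threshold Minimum total force for a frame to be valid.
#'   The default `NULL` uses 5% of the recording's median total force.
#' @return A `cop_trajectory`: list with numeric `ml`, `ap` (mm; `NA` where
#'   invalid), logical `valid`, and `sampling_rate`, `foot`, `task`,
#'   `subject_id` carried over from the recording.
#' @export
compute_cop <- function(rec, geom = default_zone_geometry(),
                        force_threshold = NULL) {
  stopifnot(inherits(rec, "insole_recording"))
  if (nrow(geom) != 8L) stop("compute_cop: geometry must have 8 zones")
  total <- rowSums(rec$forces)
  if (is.null(force_threshold))
    force_threshold <- 0.05 * stats::median(total)
  valid <- total >= force_threshold & total > 0
  if (!any(valid))
    stop("compute_cop: no frame reaches the force threshold in recording ",
         rec$subject_id, "/", rec$task, "/", rec$foot)
  ml <- ap <- rep(NA_real_, length(total))
  ml[valid] <- drop(rec$forces[valid, , drop = FALSE] %*% geom$ml) /
    total[valid]
  ap[valid] <- drop(rec$forces[valid, , drop = FALSE] %*% geom$ap) /
    total[valid]
  structure(
    list(ml = ml, ap = ap, valid = valid,
         sampling_rate = rec$sampling_rate, foot = rec$foot,
         task = rec$task, subject_id = rec$subject_id),
    class = "cop_trajectory")
}

#' @export
print.cop_trajectory <- function(x, ...) {
  cat(sprintf(
    "<cop_trajectory> %s | %s foot | %d/%d valid frames @ %g Hz\n",
    x$task, x$foot, sum(x$valid), length(x$valid), x$sampling_rate))
  invisible(x)
}

# Build a trajectory directly from coordinate series (used by the synthetic
# generator's latent COP and by tests); all frames valid unless masked.
cop_trajectory <- function(ml, ap, sampling_rate, valid = NULL,
                           foot = "left", task = "EO", subject_id = "synth") {
  stopifnot(length(ml) == length(ap))
  if (is.null(valid)) valid <- rep(TRUE, length(ml))
  ml[!valid] <- NA_real_
  ap[!valid] <- NA_real_
  structure(
    list(ml = as.numeric(ml), ap = as.numeric(ap), valid = valid,
         sampling_rate = sampling_rate, foot = foot, task = task,
         subject_id = subject_id),
    class = "cop_trajectory")
}

#' Segment single-foot stance periods of a two-foot trial
#'
#' For the one-foot stance task the subject stands on the left foot, then on
#' the right; the lifted foot may briefly touch the ground to regain
#' balance. A frame belongs to a left-stance segment when the left total
#' force is at or above threshold while the right is below it (and
#' symmetrically). Touch-downs of the lifted foot interrupt the condition
#' and split the segment. Segments shorter than `min_segment` frames are
#' discarded.
#'
#' @param rec_left,rec_right The two feet of the same trial, frame-aligned.
#' @param force_threshold Per-foot force threshold; default `NULL` uses 5%
#'   of that foot's median total force over its loaded half (see
#'   [compute_cop()]).
#' @param min_segment Minimum segment length in frames (default 5).
#' @return List with `left` and `right`: each an integer matrix with columns
#'   `start`, `end` of half-open 1-based frame intervals `[start, end)`.
#' @export
segment_one_foot <- function(rec_left, rec_right, force_threshold = NULL,
                             min_segment = 5L) {
  stopifnot(inherits(rec_left, "insole_recording"),
            inherits(rec_right, "insole_recording"))
  if (nrow(rec_left$forces) != nrow(rec_right$forces))
    stop("segment_one_foot: feet have different frame counts")
  tl <- rowSums(rec_left$forces)
  tr <- rowSums(rec_right$forces)
  thr_l <- if (is.null(force_threshold))
    0.05 * stats::median(tl[tl > 0]) else force_threshold
  thr_r <- if (is.null(force_threshold))
    0.05 * stats::median(tr[tr > 0]) else force_threshold
  left_mask <- tl >= thr_l & tr < thr_r
  right_mask <- tr >= thr_r & tl < thr_l
  left <- mask_to_intervals(left_mask, min_segment)
  right <- mask_to_intervals(right_mask, min_segment)
  if (nrow(left) == 0L && nrow(right) == 0L)
    stop("segment_one_foot: no single-foot stance found in trial ",
         rec_left$subject_id)
  list(left = left, right = right)
}

# Runs of TRUE as half-open [start, end) 1-based intervals, dropping runs
# shorter than min_len.
mask_to_intervals <- function(mask, min_len = 1L) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_len
  cbind(start = starts[keep], end = ends[keep] + 1L)
}

# Restrict a trajectory to a set of frame intervals: frames outside become
# invalid (runs are kept separate by the NA gaps).
restrict_trajectory <- function(traj, intervals) {
  keep <- rep(FALSE, length(traj$valid))
  for (i in seq_len(nrow(intervals)))
    keep[intervals[i, "start"]:(intervals[i, "end"] - 1L)] <- TRUE
  cop_trajectory(ifelse(keep, traj$ml, NA_real_),
                 ifelse(keep, traj$ap, NA_real_),
                 traj$sampling_rate, valid = traj$valid & keep,
                 foot = traj$foot, task = traj$task,
                 subject_id = traj$subject_id)
}
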