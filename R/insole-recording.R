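#' Balance-task labels
#'
#' Six tasks are recognised: three static (quiet stance eyes open `EO`,
#' quiet stance eyes closed `EC`, quiet one-foot stance `OF`) and three
#' active (`GAIT` walk-turn-walk, `FR` functional reach, `BO` bend over).
#'
#' @return Character vector of the six task labels.
#' @export
all_tasks <- function() c("EO", "EC", "OF", "GAIT", "FR", "BO")

#' @rdname all_tasks
#' @export
static_tasks <- function() c("EO", "EC", "OF")

#' @rdname all_tasks
#' @export
active_tasks <- function() c("GAIT", "FR", "BO")

#' Tasks belonging to a named task set
#'
#' @param task_set One of `"static"`, `"active"`, `"static_active"`.
#' @return Character vector of task labels.
#' @export
task_set_tasks <- function(task_set) {
  switch(match.arg(task_set, c("static", "active", "static_active")),
         static = static_tasks(),
         active = active_tasks(),
         static_active = all_tasks())
}

#' A single-foot insole recording
#'
#' One recording holds the raw stream from one insole during one balance
#' task: a strictly increasing time stamp per frame and 8 non-negative zone
#' forces per frame, plus the nominal sampling rate.
#'
#' @param subject_id Subject identifier (string).
#' @param task Task label, one of [all_tasks()].
#' @param foot `"left"` or `"right"`.
#' @param timestamps Numeric vector of frame times in seconds, strictly
#'   increasing.
#' @param forces Numeric matrix with one row per frame and exactly 8
#'   columns of non-negative zone forces (arbitrary but consistent force
#'   units).
#' @param sampling_rate Nominal sampling rate in Hz. The study hardware
#'   streams at 50 or 12 Hz; any positive rate is accepted, other rates with
#'   a warning.
#' @return An `insole_recording` object.
#' @export
insole_recording <- function(subject_id, task, foot, timestamps, forces,
                             sampling_rate) {
  task <- match.arg(task, all_tasks())
  foot <- match.arg(foot, c("left", "right"))
  forces <- as.matrix(forces)
  if (ncol(forces) != 8L)
    stop("insole_recording: forces must have exactly 8 zone columns, got ",
         ncol(forces))
  if (nrow(forces) != length(timestamps))
    stop("insole_recording: timestamps length (", length(timestamps),
         ") must equal the number of force frames (", nrow(forces), ")")
  neg <- which(forces < 0, arr.ind = TRUE)
  if (nrow(neg) > 0L)
    stop("insole_recording: negative force at frame ", neg[1L, 1L],
         ", zone ", neg[1L, 2L])
  if (length(timestamps) > 1L) {
    dt <- diff(timestamps)
    if (any(dt <= 0))
      stop("insole_recording: timestamps must be strictly increasing ",
           "(violation at frame ", which(dt <= 0)[1L] + 1L, ")")
    med_dt <- stats::median(dt)
    if (abs(med_dt - 1 / sampling_rate) > 0.1 / sampling_rate)
      warning("insole_recording: median inter-sample interval ",
              signif(med_dt, 4), " s deviates >10% from 1/sampling_rate")
  }
  if (!isTRUE(sampling_rate > 0))
    stop("insole_recording: sampling_rate must be positive")
  if (!sampling_rate %in% c(50, 12))
    warning("insole_recording: sampling_rate ", sampling_rate,
            " Hz is not one of the study rates (50, 12)")
  structure(
    list(subject_id = as.character(subject_id), task = task, foot = foot,
         timestamps = as.numeric(timestamps),
         forces = unname(forces), sampling_rate = as.numeric(sampling_rate)),
    class = "insole_recording")
}

#' @export
print.insole_recording <- function(x, ...) {
  cat(sprintf(
    "<insole_recording> subject %s | task %s | %s foot | %d frames @ %g Hz\n",
    x$subject_id, x$task, x$foot, nrow(x$forces), x$sampling_rate))
  invisible(x)
}

#' Subject metadata
#'
#' @param subject_id Subject identifier.
#' @param group Cohort group: `"young_control"`, `"age_matched_control"` or
#'   `"pd"`.
#' @param faller Logical: self-reported at least one fall in the past year.
#'   Only meaningful (and only allowed `TRUE`) for the `pd` group; `NA` for
#'   unknown.
#' @return A one-row data.frame; vectors of equal length give several rows.
#' @export
subject_meta <- function(subject_id, group, faller = NA) {
  ok_groups <- c("young_control", "age_matched_control", "pd")
  if (!all(group %in% ok_groups))
    stop("subject_meta: group must be one of ",
         paste(ok_groups, collapse = ", "))
  meta <- data.frame(subject_id = as.character(subject_id),
                     group = group, faller = as.logical(faller),
                     stringsAsFactors = FALSE)
  bad <- !is.na(meta$faller) & meta$faller & meta$group != "pd"
  if (any(bad))
    stop("subject_meta: faller = TRUE is only defined for the pd group (",
         paste(meta$subject_id[bad], collapse = ", "), ")")
  meta
}
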