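#' Read insole recordings from a long-format CSV
#'
#' The on-disk dialect is long format, one row per frame per foot, with
#' columns `subject`, `task`, `foot`, `rate`, `time`, `f1` ... `f8`. Rows
#' are grouped into one [insole_recording()] per (subject, task, foot),
#' preserving within-group row order as frame order.
#'
#' @param path Path to a CSV file written by [write_insole_csv()] or
#'   following the same dialect.
#' @return A list of `insole_recording` objects.
#' @export
read_insole_csv <- function(path) {
  if (!file.exists(path)) stop("read_insole_csv: no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("subject", "task", "foot", "rate", "time", paste0("f", 1:8))
  missing <- setdiff(needed, names(df))
  if (length(missing) > 0L)
    stop("read_insole_csv: missing column(s): ",
         paste(missing, collapse = ", "))
  if (nrow(df) == 0L) return(list())
  key <- interaction(df$subject, df$task, df$foot, drop = TRUE, sep = "\r")
  groups <- split(df, key)
  recs <- lapply(groups, function(g) {
    insole_recording(subject_id = g$subject[1L], task = g$task[1L],
                     foot = g$foot[1L], timestamps = g$time,
                     forces = as.matrix(g[, paste0("f", 1:8)]),
                     sampling_rate = g$rate[1L])
  })
  names(recs) <- NULL
  # stable, human-predictable order
  ord <- order(vapply(recs, `[[`, "", "subject_id"),
               match(vapply(recs, `[[`, "", "task"), all_tasks()),
               match(vapply(recs, `[[`, "", "foot"), c("left", "right")))
  recs[ord]
}

#' Write insole recordings to a long-format CSV
#'
#' Inverse of [read_insole_csv()]: deterministic column order and full
#' double precision, so a write/read round trip reproduces every field.
#'
#' @param recordings A list of [insole_recording()] objects (or a single
#'   one).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_insole_csv <- function(recordings, path) {
  if (inherits(recordings, "insole_recording")) recordings <- list(recordings)
  rows <- lapply(recordings, function(r) {
    f <- as.data.frame(r$forces)
    names(f) <- paste0("f", 1:8)
    cbind(data.frame(subject = r$subject_id, task = r$task, foot = r$foot,
                     rate = r$sampling_rate, time = r$timestamps,
                     stringsAsFactors = FALSE), f)
  })
  out <- if (length(rows) > 0L) do.call(rbind, rows) else
    stats::setNames(as.data.frame(matrix(nrow = 0, ncol = 13)),
                    c("subject", "task", "foot", "rate", "time",
                      paste0("f", 1:8)))
  ok <- tryCatch({
    utils::write.csv(format(out, digits = 17, trim = TRUE, scientific = FALSE),
                     path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("write_insole_csv: cannot write ", path, ": ",
                        conditionMessage(ok))
  invisible(path)
}

#' Anti-alias filter and down-sample a recording
#'
#' Each of the 8 force channels is low-pass filtered with an IIR
#' anti-aliasing filter and then decimated to the target rate. The filter is
#' an order-8 Butterworth at 0.4 x target rate, applied forward-backward
#' (zero phase) so COP dynamics are not phase-distorted; forward-backward
#' application squares the magnitude response, giving ~96 dB/octave roll-off.
#' Filtered forces are clipped at 0 to preserve non-negativity. If timestamps
#' are jittered the channels are first linearly interpolated onto a uniform
#' grid at the nominal input rate (spectral estimates downstream assume
#' uniform sampling).
#'
#' @param rec An [insole_recording()].
#' @param target_rate Target sampling rate in Hz; must not exceed the
#'   recording's rate. The study pipeline uses 12 Hz.
#' @return An `insole_recording` at `target_rate`. Returned unchanged when
#'   the rates already agree.
#' @export
antialias_downsample <- function(rec, target_rate = 12) {
  stopifnot(inherits(rec, "insole_recording"))
  if (target_rate > rec$sampling_rate)
    stop("antialias_downsample: target_rate (", target_rate,
         ") exceeds recording rate (", rec$sampling_rate, ")")
  if (target_rate == rec$sampling_rate) return(rec)

  fs_in <- rec$sampling_rate
  t0 <- rec$timestamps[1L]
  n_in <- nrow(rec$forces)
  # uniform grid at the nominal input rate (identity for jitter-free input)
  t_in <- t0 + (seq_len(n_in) - 1L) / fs_in
  f_in <- rec$forces
  if (max(abs(rec$timestamps - t_in)) > 1e-9) {
    f_in <- apply(rec$forces, 2L, function(col)
      stats::approx(rec$timestamps, col, xout = t_in, rule = 2)$y)
  }

  bf <- signal::butter(4, (0.4 * target_rate) / (fs_in / 2), type = "low")
  filt <- apply(f_in, 2L, function(col) filtfilt_padded(bf, col))
  filt[filt < 0] <- 0

  t_out <- seq(from = t0, to = t_in[n_in], by = 1 / target_rate)
  f_out <- apply(filt, 2L, function(col)
    stats::approx(t_in, col, xout = t_out, rule = 2)$y)

  insole_recording(rec$subject_id, rec$task, rec$foot,
                   timestamps = t_out, forces = f_out,
                   sampling_rate = target_rate)
}

# Zero-phase filtering with odd-reflection padding at both ends, so DC and
# slow trends pass without start-up transients (filtfilt alone starts from
# zero state).
filtfilt_padded <- function(bf, x) {
  n <- length(x)
  p <- min(n - 1L, 200L)
  if (p < 1L) return(as.numeric(signal::filtfilt(bf, x)))
  head_pad <- 2 * x[1L] - x[(p + 1L):2L]
  tail_pad <- 2 * x[n] - x[(n - 1L):(n - p)]
  y <- as.numeric(signal::filtfilt(bf, c(head_pad, x, tail_pad)))
  y[(p + 1L):(p + n)]
}
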