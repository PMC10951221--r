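#' Dynamic sway features
#'
#' Twenty-one measures of local COP displacement. Velocities are central
#' finite differences at the trajectory's sampling rate; invalid-frame gaps
#' break the difference chain, so each contiguous run of valid frames is
#' differentiated independently and the per-run results are pooled.
#'
#' * `mean_velocity[_ml/_ap]` — mean resultant speed and mean absolute
#'   per-axis velocity (mm/s).
#' * `total_excursion` — summed path length (mm).
#' * `peak_velocity_ml/_ap`, `velocity_sd_ml/_ap` — per-axis velocity
#'   extremes and SDs.
#' * `zero_crossing_velocity_ml/_ap` — number of sign changes of the
#'   per-axis COP velocity.
#' * `sway_area_per_second` — area swept per second by the vector from the
#'   mean point to the COP (mm^2/s), summed triangle areas over time.
#' * `phase_plane_ml/_ap` — phase-plane parameter
#'   \eqn{\sqrt{\sigma^2_{pos} + \sigma^2_{vel}}}.
#' * `length_over_area` — total excursion / 95% ellipse area (1/mm).
#' * `fractal_dimension` — \eqn{\log N / \log(N d / L)} with \eqn{d} the
#'   planar diameter and \eqn{L} the total excursion.
#' * `mean_frequency[_ml/_ap]` — mean speed / (2 pi x mean distance); for a
#'   sinusoid this recovers its frequency (Hz).
#' * `mean_peak_sway_density` — mean of the sway-density peaks, where the
#'   sway density at a sample is the time (s) spent by consecutive samples
#'   within a 3 mm circle around it; `mean_distance_peak_sway_density` and
#'   `mean_time_peak_sway_density` are the mean spatial (mm) and temporal
#'   (s) separation of successive peaks. The sway-density curve is smoothed
#'   with a 0.5 s moving average before peak extraction.
#'
#' @param traj A `cop_trajectory`.
#' @param sway_density_radius Radius of the sway-density circle in mm
#'   (default 3).
#' @return Named numeric vector of the 21 dynamic features; `NA` markers
#'   where a measure is undefined (fewer than 3 valid frames in any run, or
#'   a degenerate limit with no analytic value).
#' @export
dynamic_features <- function(traj, sway_density_radius = 3) {
  out <- stats::setNames(rep(NA_real_, 21L), dynamic_feature_names())
  fs <- traj$sampling_rate
  runs <- valid_runs(traj, min_len = 3L)
  if (length(runs) == 0L) return(out)

  x_all <- traj$ml[traj$valid]
  y_all <- traj$ap[traj$valid]
  mx <- mean(x_all); my <- mean(y_all)

  vx <- vy <- numeric(0)
  totex <- 0
  sway_tri <- 0
  for (idx in runs) {
    x <- traj$ml[idx]; y <- traj$ap[idx]
    vx <- c(vx, central_diff(x, fs))
    vy <- c(vy, central_diff(y, fs))
    totex <- totex + sum(sqrt(diff(x)^2 + diff(y)^2))
    cx <- x - mx; cy <- y - my
    n <- length(x)
    sway_tri <- sway_tri +
      sum(abs(cx[-n] * cy[-1L] - cx[-1L] * cy[-n])) / 2
  }
  v <- sqrt(vx^2 + vy^2)
  t_total <- length(x_all) / fs

  out["mean_velocity"] <- mean(v)
  out["mean_velocity_ml"] <- mean(abs(vx))
  out["mean_velocity_ap"] <- mean(abs(vy))
  out["total_excursion"] <- totex
  out["peak_velocity_ml"] <- max(abs(vx))
  out["peak_velocity_ap"] <- max(abs(vy))
  out["velocity_sd_ml"] <- stats::sd(vx)
  out["velocity_sd_ap"] <- stats::sd(vy)
  out["zero_crossing_velocity_ml"] <- count_zero_crossings(vx)
  out["zero_crossing_velocity_ap"] <- count_zero_crossings(vy)
  out["sway_area_per_second"] <- sway_tri / t_total
  out["phase_plane_ml"] <- sqrt(stats::var(x_all) + stats::var(vx))
  out["phase_plane_ap"] <- sqrt(stats::var(y_all) + stats::var(vy))

  ell_area <- positional_features(traj)[["ellipse_area"]]
  out["length_over_area"] <-
    if (isTRUE(ell_area > 0)) totex / ell_area else NA_real_
  d <- planar_diameter(x_all - mx, y_all - my)
  n_all <- length(x_all)
  out["fractal_dimension"] <-
    if (totex > 0 && d > 0) log(n_all) / log(n_all * d / totex) else NA_real_

  mdist <- mean(sqrt((x_all - mx)^2 + (y_all - my)^2))
  mdist_x <- mean(abs(x_all - mx))
  mdist_y <- mean(abs(y_all - my))
  out["mean_frequency"] <-
    if (mdist > 0) mean(v) / (2 * pi * mdist) else NA_real_
  out["mean_frequency_ml"] <-
    if (mdist_x > 0) mean(abs(vx)) / (2 * pi * mdist_x) else NA_real_
  out["mean_frequency_ap"] <-
    if (mdist_y > 0) mean(abs(vy)) / (2 * pi * mdist_y) else NA_real_

  sd_feats <- sway_density_features(traj, runs, sway_density_radius)
  out["mean_peak_sway_density"] <- sd_feats$mean_peak
  out["mean_distance_peak_sway_density"] <- sd_feats$mean_dist
  out["mean_time_peak_sway_density"] <- sd_feats$mean_time
  out
}

# Contiguous runs of valid frames, as index vectors.
valid_runs <- function(traj, min_len = 1L) {
  iv <- mask_to_intervals(traj$valid, min_len)
  lapply(seq_len(nrow(iv)), function(i) iv[i, "start"]:(iv[i, "end"] - 1L))
}

# Central differences in the interior, one-sided at the ends.
central_diff <- function(x, fs) {
  n <- length(x)
  if (n < 3L) return(diff(x) * fs)
  c(x[2L] - x[1L],
    (x[3:n] - x[1:(n - 2L)]) / 2,
    x[n] - x[n - 1L]) * fs
}

# Sign changes of a series, ignoring exact zeros.
count_zero_crossings <- function(v) {
  s <- sign(v)
  s <- s[s != 0]
  if (length(s) < 2L) return(0)
  sum(diff(s) != 0)
}

sway_density_features <- function(traj, runs, radius) {
  fs <- traj$sampling_rate
  peak_vals <- numeric(0)
  peak_dists <- numeric(0)
  peak_times <- numeric(0)
  for (idx in runs) {
    x <- traj$ml[idx]; y <- traj$ap[idx]
    n <- length(x)
    sd_curve <- numeric(n)
    r2 <- radius^2
    for (i in seq_len(n)) {
      cnt <- 0L
      j <- i + 1L
      while (j <= n && (x[j] - x[i])^2 + (y[j] - y[i])^2 <= r2) {
        cnt <- cnt + 1L; j <- j + 1L
      }
      j <- i - 1L
      while (j >= 1L && (x[j] - x[i])^2 + (y[j] - y[i])^2 <= r2) {
        cnt <- cnt + 1L; j <- j - 1L
      }
      sd_curve[i] <- cnt / fs
    }
    sd_smooth <- moving_average(sd_curve, max(1L, round(0.5 * fs)))
    pk <- local_maxima(sd_smooth)
    if (length(pk) > 0L) {
      peak_vals <- c(peak_vals, sd_smooth[pk])
      if (length(pk) > 1L) {
        peak_dists <- c(peak_dists,
                        sqrt(diff(x[pk])^2 + diff(y[pk])^2))
        peak_times <- c(peak_times, diff(pk) / fs)
      }
    }
  }
  list(mean_peak = if (length(peak_vals)) mean(peak_vals) else NA_real_,
       mean_dist = if (length(peak_dists)) mean(peak_dists) else NA_real_,
       mean_time = if (length(peak_times)) mean(peak_times) else NA_real_)
}

moving_average <- function(x, k) {
  k <- min(k, length(x))
  if (k <= 1L) return(x)
  sm <- as.numeric(stats::filter(x, rep(1 / k, k), sides = 2))
  # shrink the window at the edges instead of dropping them
  na <- which(is.na(sm))
  for (i in na) {
    h <- (k - 1L) %/% 2L
    lo <- max(1L, i - h); hi <- min(length(x), i + h)
    sm[i] <- mean(x[lo:hi])
  }
  sm
}

# Strict-rise / non-strict-fall local maxima; plateaus yield their first
# sample. Endpoints are not peaks.
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  which(x[2:(n - 1L)] > x[1:(n - 2L)] & x[2:(n - 1L)] >= x[3:n]) + 1L
}
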