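#' Positional sway features
#'
#' Nineteen dispersion/position statistics of the COP point cloud, requiring
#' no knowledge of its dynamics. Coordinates are in mm. Except for the two
#' mean values, all measures are computed on the mean-centered trajectory:
#'
#' * `mean_value_ml`, `mean_value_ap` — raw trajectory means.
#' * `mean_distance[_ml/_ap]` — mean resultant distance from the mean point,
#'   and mean absolute deviation per axis.
#' * `rms_radius`, `rms_ml`, `rms_ap` — RMS resultant distance and per-axis
#'   RMS deviation.
#' * `range_resultant` — largest distance between any two COP points
#'   (planar diameter); `range_ml`, `range_ap` — per-axis ranges.
#' * `max_distance` — largest distance from the mean point.
#' * `ellipse_area/major_axis/minor_axis/orientation` — 95% confidence
#'   ellipse under a bivariate-Gaussian assumption: area
#'   \eqn{\pi\,\chi^2_{0.95,2}\sqrt{\det\Sigma}} with axes
#'   \eqn{\sqrt{\chi^2_{0.95,2}\lambda_i}} and orientation the major-axis
#'   angle from the ML axis in degrees.
#' * `amplitude_ratio` — range ML / range AP (0 when both vanish).
#' * `iqr_ml`, `iqr_ap` — per-axis interquartile ranges.
#'
#' @param traj A `cop_trajectory` (see [compute_cop()]).
#' @return Named numeric vector of the 19 positional features; all `NA`
#'   with fewer than 2 valid frames.
#' @export
positional_features <- function(traj) {
  out <- stats::setNames(rep(NA_real_, 19L), positional_feature_names())
  x <- traj$ml[traj$valid]
  y <- traj$ap[traj$valid]
  n <- length(x)
  if (n < 2L) return(out)

  out["mean_value_ml"] <- mean(x)
  out["mean_value_ap"] <- mean(y)
  cx <- x - mean(x)
  cy <- y - mean(y)
  r <- sqrt(cx^2 + cy^2)

  out["mean_distance"] <- mean(r)
  out["mean_distance_ml"] <- mean(abs(cx))
  out["mean_distance_ap"] <- mean(abs(cy))
  out["rms_radius"] <- sqrt(mean(r^2))
  out["rms_ml"] <- sqrt(mean(cx^2))
  out["rms_ap"] <- sqrt(mean(cy^2))
  out["range_ml"] <- diff(range(cx))
  out["range_ap"] <- diff(range(cy))
  out["range_resultant"] <- planar_diameter(cx, cy)
  out["max_distance"] <- max(r)

  ell <- confidence_ellipse(cx, cy)
  out["ellipse_area"] <- ell$area
  out["ellipse_major_axis"] <- ell$major
  out["ellipse_minor_axis"] <- ell$minor
  out["ellipse_orientation"] <- ell$orientation

  out["amplitude_ratio"] <-
    if (out["range_ap"] > 0) out["range_ml"] / out["range_ap"]
    else if (out["range_ml"] == 0) 0 else NA_real_
  out["iqr_ml"] <- stats::IQR(cx)
  out["iqr_ap"] <- stats::IQR(cy)
  out
}

# Largest pairwise distance; restricted to convex-hull vertices for speed.
planar_diameter <- function(x, y) {
  if (length(x) > 3L) {
    h <- unique(grDevices::chull(x, y))
    # chull degenerates for collinear clouds; fall back to all points
    if (length(h) >= 2L) { x <- x[h]; y <- y[h] }
  }
  max(stats::dist(cbind(x, y)), 0)
}

# 95% confidence ellipse of a centered 2-D point cloud.
confidence_ellipse <- function(cx, cy, level = 0.95) {
  q <- stats::qchisq(level, df = 2)
  sxx <- mean(cx^2); syy <- mean(cy^2); sxy <- mean(cx * cy)
  det <- max(sxx * syy - sxy^2, 0)
  e <- eigen(matrix(c(sxx, sxy, sxy, syy), 2L), symmetric = TRUE)
  lam <- pmax(e$values, 0)
  orient <- if (lam[1L] > 0) {
    v <- e$vectors[, 1L]
    atan2(v[2L], v[1L]) * 180 / pi
  } else 0
  # fold to (-90, 90]: an axis has no direction
  if (orient > 90) orient <- orient - 180
  if (orient <= -90) orient <- orient + 180
  list(area = pi * q * sqrt(det),
       major = sqrt(q * lam[1L]),
       minor = sqrt(q * lam[2L]),
       orientation = orient)
}
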