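#' Canonical posturography feature inventory
#'
#' Sixty measures are computed per foot and task, partitioned into 19
#' positional, 21 dynamic and 20 spectral features. The inventory follows
#' the classical stabilometry literature (Prieto-style positional and
#' spectral sets plus the sway-density family): positional features describe
#' the dispersion of the COP point cloud, dynamic features its local
#' displacements and velocities, spectral features its power spectral
#' density per axis.
#'
#' @return Character vector of 60 feature names (`positional_feature_names`
#'   etc. return the three parts).
#' @export
feature_names <- function() {
  c(positional_feature_names(), dynamic_feature_names(),
    spectral_feature_names())
}

#' @rdname feature_names
#' @export
positional_feature_names <- function() {
  c("mean_value_ml", "mean_value_ap",
    "mean_distance", "mean_distance_ml", "mean_distance_ap",
    "rms_radius", "rms_ml", "rms_ap",
    "range_resultant", "range_ml", "range_ap",
    "max_distance",
    "ellipse_area", "ellipse_major_axis", "ellipse_minor_axis",
    "ellipse_orientation",
    "amplitude_ratio", "iqr_ml", "iqr_ap")
}

#' @rdname feature_names
#' @export
dynamic_feature_names <- function() {
  c("mean_velocity", "mean_velocity_ml", "mean_velocity_ap",
    "total_excursion",
    "peak_velocity_ml", "peak_velocity_ap",
    "velocity_sd_ml", "velocity_sd_ap",
    "zero_crossing_velocity_ml", "zero_crossing_velocity_ap",
    "sway_area_per_second",
    "phase_plane_ml", "phase_plane_ap",
    "length_over_area", "fractal_dimension",
    "mean_frequency", "mean_frequency_ml", "mean_frequency_ap",
    "mean_peak_sway_density", "mean_distance_peak_sway_density",
    "mean_time_peak_sway_density")
}

#' @rdname feature_names
#' @export
spectral_feature_names <- function() {
  base <- c("total_power", "power_freq_50", "power_freq_95",
            "centroid_freq", "freq_dispersion", "freq_mode",
            "freq_quotient", "energy_below_05", "energy_05_2",
            "energy_above_2")
  c(paste0(base, "_ml"), paste0(base, "_ap"))
}
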