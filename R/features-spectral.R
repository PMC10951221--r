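#' Spectral sway features
#'
#' Twenty measures (10 per axis) of the COP power spectral density,
#' estimated by Welch's method: Hann window of `min(128, floor(N/2))`
#' samples, 50% overlap, per-segment linear detrend, one-sided scaling so
#' the PSD integrates to the signal variance. Welch segments are taken
#' within each valid run and their periodograms pooled; when every run is
#' shorter than the window (gait stance phases) the valid samples are
#' concatenated and the spectrum estimated on the concatenation, the
#' per-segment detrend absorbing junction offsets.
#'
#' Per axis (`_ml`, `_ap`):
#' * `total_power` — integrated PSD (mm^2).
#' * `power_freq_50`, `power_freq_95` — frequencies below which 50% / 95%
#'   of the power lies (median and 95% power frequency, Hz).
#' * `centroid_freq` — \eqn{\sqrt{\mu_2/\mu_0}} of the PSD moments (Hz).
#' * `freq_dispersion` — \eqn{\sqrt{1 - \mu_1^2/(\mu_0\mu_2)}}
#'   (unitless, 0 for a pure tone).
#' * `freq_mode` — frequency of the largest PSD bin, DC excluded (Hz).
#' * `freq_quotient` — `power_freq_95 / power_freq_50` (unitless).
#' * `energy_below_05`, `energy_05_2`, `energy_above_2` — band power below
#'   0.5 Hz, between 0.5 and 2 Hz, and above 2 Hz, as fractions of total
#'   power.
#'
#' @param traj A `cop_trajectory` with at least 32 valid frames in some run.
#' @return Named numeric vector of the 20 spectral features; `NA` markers
#'   when no run is long enough or the spectrum is degenerate (zero power).
#' @export
frequency_features <- function(traj) {
  out <- stats::setNames(rep(NA_real_, 20L), spectral_feature_names())
  fs <- traj$sampling_rate
  runs <- valid_runs(traj)
  n_valid <- sum(traj$valid)
  if (n_valid < 32L) return(out)
  for (axis in c("ml", "ap")) {
    series <- lapply(runs, function(idx) traj[[axis]][idx])
    window <- min(128L, floor(n_valid / 2))
    psd <- welch_psd(series, fs, window = window)
    if (is.null(psd))  # every run shorter than the window (e.g. gait
      # stance phases): estimate on the concatenated valid samples
      psd <- welch_psd(list(unlist(series)), fs, window = window)
    if (is.null(psd)) next
    out[paste0(spectral_axis_names(), "_", axis)] <-
      psd_summaries(psd$freq, psd$power)
  }
  out
}

spectral_axis_names <- function() {
  c("total_power", "power_freq_50", "power_freq_95", "centroid_freq",
    "freq_dispersion", "freq_mode", "freq_quotient", "energy_below_05",
    "energy_05_2", "energy_above_2")
}

#' Welch power spectral density
#'
#' @param series A numeric vector, or a list of numeric vectors (runs that
#'   segments must not straddle).
#' @param fs Sampling rate (Hz).
#' @param window Segment length in samples (Hann window); segments overlap
#'   by 50%.
#' @return List with `freq` (Hz) and `power` (one-sided PSD, units^2/Hz)
#'   such that `sum(power) * fs / window` approximates the variance, or
#'   `NULL` when no run admits a full segment.
#' @export
welch_psd <- function(series, fs, window = 128L) {
  if (!is.list(series)) series <- list(series)
  window <- as.integer(window)
  if (window < 8L) return(NULL)
  hop <- max(1L, window %/% 2L)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(window) / (window + 1))  # Hann
  u <- sum(w^2)
  acc <- NULL
  nseg <- 0L
  for (x in series) {
    n <- length(x)
    if (n < window) next
    starts <- seq(1L, n - window + 1L, by = hop)
    for (s in starts) {
      seg <- x[s:(s + window - 1L)]
      seg <- stats::residuals(stats::lm.fit(
        cbind(1, seq_len(window)), seg))       # linear detrend
      ft <- stats::fft(seg * w)
      p <- Mod(ft[seq_len(window %/% 2L + 1L)])^2 / (fs * u)
      # one-sided: double everything except DC (and Nyquist for even n)
      dbl <- rep(2, length(p)); dbl[1L] <- 1
      if (window %% 2L == 0L) dbl[length(p)] <- 1
      p <- p * dbl
      acc <- if (is.null(acc)) p else acc + p
      nseg <- nseg + 1L
    }
  }
  if (nseg == 0L) return(NULL)
  list(freq = (0:(window %/% 2L)) * fs / window, power = acc / nseg)
}

# The 10 per-axis summaries from a PSD.
psd_summaries <- function(freq, power) {
  df <- freq[2L] - freq[1L]
  total <- sum(power) * df
  out <- stats::setNames(rep(NA_real_, 10L), spectral_axis_names())
  if (total < 1e-14) total <- 0      # detrend residue on constant input
  out["total_power"] <- total
  if (total <= 0) return(out)
  cum <- cumsum(power) * df / total
  out["power_freq_50"] <- freq[which(cum >= 0.5)[1L]]
  out["power_freq_95"] <- freq[which(cum >= 0.95)[1L]]
  m0 <- sum(power); m1 <- sum(freq * power); m2 <- sum(freq^2 * power)
  out["centroid_freq"] <- sqrt(m2 / m0)
  out["freq_dispersion"] <- sqrt(max(0, 1 - m1^2 / (m0 * m2)))
  out["freq_mode"] <- freq[-1L][which.max(power[-1L])]
  out["freq_quotient"] <- if (out["power_freq_50"] > 0)
    out["power_freq_95"] / out["power_freq_50"] else NA_real_
  out["energy_below_05"] <- sum(power[freq < 0.5]) * df / total
  out["energy_05_2"] <- sum(power[freq >= 0.5 & freq <= 2]) * df / total
  out["energy_above_2"] <- sum(power[freq > 2]) * df / total
  out
}
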