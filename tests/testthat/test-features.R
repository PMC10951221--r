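test_that("feature bank has the 19/21/20 partition and is deterministic", {
  expect_length(positional_feature_names(), 19)
  expect_length(dynamic_feature_names(), 21)
  expect_length(spectral_feature_names(), 20)
  expect_length(feature_names(), 60)
  expect_false(anyDuplicated(feature_names()) > 0)
  traj <- sway_traj()
  expect_identical(compute_foot_features(traj), compute_foot_features(traj))
  expect_named(compute_foot_features(traj), feature_names())
})

test_that("positional features: degenerate and symmetric cases", {
  const <- make_traj(rep(2.5, 50), rep(-1, 50))
  fv <- positional_features(const)
  expect_equal(fv[["mean_value_ml"]], 2.5)
  expect_equal(fv[["mean_value_ap"]], -1)
  expect_equal(fv[["rms_radius"]], 0)
  expect_equal(fv[["ellipse_area"]], 0)
  expect_false(anyNA(fv))   # all positional defined in the static limit

  alt <- make_traj(rep(c(-1, 1), 25), rep(0, 50))
  fa <- positional_features(alt)
  expect_equal(fa[["mean_value_ml"]], 0)
  expect_equal(fa[["rms_radius"]], 1)
  expect_equal(fa[["range_ml"]], 2)

  short <- make_traj(1, 1)
  expect_true(all(is.na(positional_features(short))))
})

test_that("95% confidence ellipse area matches the bivariate-Gaussian
           closed form", {
  set.seed(101)
  sigma <- 3
  traj <- make_traj(rnorm(10000, 0, sigma), rnorm(10000, 0, sigma))
  area <- positional_features(traj)[["ellipse_area"]]
  expected <- pi * qchisq(0.95, 2) * sigma^2    # pi * 5.991 * sigma^2
  expect_lt(abs(area - expected) / expected, 0.03)
})

test_that("zero-crossing count of a 1 Hz sine over 30 s at 12 Hz is
           59 +/- 1", {
  t <- (0:359) / 12
  traj <- make_traj(sin(2 * pi * t), rep(0, 360))
  zc <- dynamic_features(traj)[["zero_crossing_velocity_ml"]]
  expect_gte(zc, 58)
  expect_lte(zc, 60)
  # and the hybrid mean frequency recovers ~1 Hz
  mf <- dynamic_features(traj)[["mean_frequency_ml"]]
  expect_lt(abs(mf - 1), 0.05)
})

test_that("constant trajectory has zero velocity and zero crossings", {
  fv <- dynamic_features(make_traj(rep(1, 100), rep(2, 100)))
  expect_equal(fv[["mean_velocity"]], 0)
  expect_equal(fv[["zero_crossing_velocity_ml"]], 0)
  expect_equal(fv[["zero_crossing_velocity_ap"]], 0)
  expect_equal(fv[["total_excursion"]], 0)
  expect_true(is.na(fv[["length_over_area"]]))
})

test_that("sway area per second of a circle matches pi r^2 x rev/s", {
  r <- 10; f0 <- 0.5; fs <- 50
  t <- (0:(20 * fs - 1)) / fs
  traj <- make_traj(r * cos(2 * pi * f0 * t), r * sin(2 * pi * f0 * t),
                    fs = fs)
  sw <- dynamic_features(traj)[["sway_area_per_second"]]
  expected <- pi * r^2 * f0
  expect_lt(abs(sw - expected) / expected, 0.02)
})

test_that("sway density: a slow dense trajectory yields peaks in time
           units", {
  set.seed(3)
  # very slow drift: nearly all samples stay within 3 mm of each other
  traj <- make_traj(cumsum(rnorm(360, 0, 0.05)),
                    cumsum(rnorm(360, 0, 0.05)))
  fv <- dynamic_features(traj)
  expect_gt(fv[["mean_peak_sway_density"]], 0)
  # peak sway density cannot exceed the trial duration
  expect_lte(fv[["mean_peak_sway_density"]], 30)
})

test_that("spectral features recover a sinusoid's frequency and band", {
  t <- (0:359) / 12
  traj <- make_traj(2 * sin(2 * pi * 2 * t), 2 * sin(2 * pi * 1.5 * t))
  fv <- frequency_features(traj)
  bin <- 12 / min(128, 180)
  expect_lt(abs(fv[["freq_mode_ml"]] - 2), bin + 1e-9)
  expect_lt(abs(fv[["freq_mode_ap"]] - 1.5), bin + 1e-9)
  # 1.5 Hz is interior to [0.5, 2]: nearly all energy in that band
  expect_gte(fv[["energy_05_2_ap"]], 0.95)
  # 2 Hz sits on the band edge: energy concentrated in [0.5, 2 + leakage]
  psd <- welch_psd(traj$ml, 12, window = 128)
  frac <- sum(psd$power[psd$freq >= 0.5 & psd$freq <= 2.2]) /
    sum(psd$power)
  expect_gte(frac, 0.95)
})

test_that("Welch total power satisfies Parseval against signal variance", {
  sigma <- 2
  rel_err <- sapply(1:50, function(s) {
    set.seed(s)
    x <- rnorm(360, 0, sigma)
    traj <- make_traj(x, x)
    tp <- frequency_features(traj)[["total_power_ml"]]
    tp / sigma^2 - 1
  })
  expect_lt(abs(mean(rel_err)), 0.1)
  # and each draw against its own brute-force DFT variance oracle
  set.seed(99)
  x <- rnorm(512, 0, sigma)
  dft <- fft(x - mean(x))
  parseval_var <- sum(Mod(dft)^2) / length(x)^2
  tp <- frequency_features(make_traj(x, x))[["total_power_ml"]]
  expect_lt(abs(tp - parseval_var) / parseval_var, 0.15)
})

test_that("constant signal has zero total power and missing mode", {
  fv <- frequency_features(make_traj(rep(5, 100), rep(5, 100)))
  expect_equal(fv[["total_power_ml"]], 0)
  expect_true(is.na(fv[["freq_mode_ml"]]))
  expect_true(is.na(fv[["power_freq_50_ml"]]))
})

test_that("translation shifts the means and nothing else", {
  traj <- sway_traj(seed = 5)
  shifted <- make_traj(traj$ml + 7, traj$ap - 3)
  f0 <- compute_foot_features(traj)
  f1 <- compute_foot_features(shifted)
  expect_equal(f1[["mean_value_ml"]], f0[["mean_value_ml"]] + 7)
  expect_equal(f1[["mean_value_ap"]], f0[["mean_value_ap"]] - 3)
  rest <- setdiff(feature_names(), c("mean_value_ml", "mean_value_ap"))
  expect_equal(f1[rest], f0[rest], tolerance = 1e-9)
})

test_that("across-feet combinations follow the average and asymmetry
           formulas", {
  v <- setNames(runif(60, 1, 5), feature_names())
  expect_equal(combine_average(v, v), v)
  expect_equal(unname(combine_average(v * 0 + 2, v * 0 + 4)), rep(3, 60))
  expect_equal(unname(combine_asymmetry(v, v)), rep(0, 60))
  l <- v * 0 + 3; r <- v * 0 + 1
  expect_equal(unname(combine_asymmetry(l, r)), rep(0.5, 60))
  expect_equal(unname(combine_asymmetry(v * 0 + 2, v * 0)), rep(1, 60))
  # random pairs: element-wise oracle and [0, 1] range for non-negatives
  set.seed(6)
  a <- setNames(runif(60), feature_names())
  b <- setNames(runif(60), feature_names())
  expect_equal(combine_average(a, b), (a + b) / 2)
  asym <- combine_asymmetry(a, b)
  expect_equal(asym, abs(a - b) / (a + b), ignore_attr = TRUE)
  expect_true(all(asym >= 0 & asym <= 1))
  # zero/zero -> 0; negative denominator flagged
  z <- a; z[1] <- 0
  zb <- b; zb[1] <- 0
  expect_equal(unname(combine_asymmetry(z, zb)[1]), 0)
  neg <- a; neg[2] <- -5
  flagged <- attr(combine_asymmetry(neg, b), "flagged_denominator")
  expect_true(feature_names()[2] %in% flagged)
})

test_that("features agree between a 50 Hz band-limited recording and its
           12 Hz down-sample", {
  set.seed(12)
  geom <- default_zone_geometry()
  p <- task_params(sway_sd_ml = 2, sway_sd_ap = 3)
  sim <- simulate_cop_trajectory("EO", p, geom, fs = 50)
  f <- render_zone_forces(sim$ml, sim$ap, sim$total, geom)
  rec50 <- insole_recording("s", "EO", "left",
                            (seq_along(sim$ml) - 1) / 50, f, 50)
  rec12 <- antialias_downsample(rec50, 12)
  f50 <- compute_foot_features(compute_cop(rec50, geom))
  f12 <- compute_foot_features(compute_cop(rec12, geom))
  # positional summaries are rate-insensitive for band-limited sway
  for (nm in c("mean_value_ml", "mean_value_ap", "rms_ml", "rms_ap",
               "ellipse_area"))
    expect_lt(abs(f12[[nm]] - f50[[nm]]) /
                max(abs(f50[[nm]]), 1), 0.1)
})
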