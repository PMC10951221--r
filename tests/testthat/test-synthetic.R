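test_that("static simulation hits the configured mean and SD", {
  set.seed(20)
  p <- task_params(ml_offset = 0, sway_sd_ml = 2, sway_sd_ap = 2,
                   trial_duration = 30)
  geom <- default_zone_geometry()
  sim <- simulate_cop_trajectory("EO", p, geom, fs = 50)
  n <- length(sim$ml)
  expect_equal(n, 1500)
  # mean within 3 standard errors of the configured center
  center <- mean(geom$ml)
  se <- 2 / sqrt(n / 25)   # heavily autocorrelated: effective n ~ n/25
  expect_lt(abs(mean(sim$ml) - center), 3 * se + 0.5)
  expect_lt(abs(sd(sim$ml) - 2) / 2, 0.15)
})

test_that("noiseless functional-reach template is the closed form", {
  p <- task_params(trial_duration = 6)
  geom <- default_zone_geometry()
  sim <- simulate_cop_trajectory("FR", p, geom, fs = 50, noise = FALSE)
  t <- (seq_along(sim$ap) - 1) / 50
  expect_equal(sim$ap, mean(geom$ap) + 60 * sin(pi * t / 6)^2,
               tolerance = 1e-12)
  expect_equal(sim$ml, rep(mean(geom$ml), length(t)), tolerance = 1e-12)
})

test_that("same seed gives identical simulations", {
  p <- task_params(trial_duration = 5)
  run <- function() {
    set.seed(77)
    simulate_cop_trajectory("EC", p)
  }
  expect_identical(run(), run())
  c1 <- simulate_cohort(c(control = 2, pd = 2), seed = 5, tasks = "EO")
  c2 <- simulate_cohort(c(control = 2, pd = 2), seed = 5, tasks = "EO")
  expect_identical(c1$recordings, c2$recordings)
})

test_that("parameter validation rejects degenerate configurations", {
  expect_error(task_params(sway_sd_ml = 0), "positive")
  expect_error(task_params(low_band_gain = -1), "positive")
  expect_error(task_params(trial_duration = 2), "at least 5")
  expect_error(task_params(ml_offset = Inf), "finite")
  expect_error(simulate_cohort(c(control = 1, pd = 5)), "at least 2")
  expect_error(simulate_cohort(c(bogus = 3)), "match the effect config")
})

test_that("rendering inverts the COP computation to 1e-6 mm", {
  set.seed(30)
  geom <- default_zone_geometry()
  # 1000 random interior points (sampled inside an inset box of the hull)
  ml <- runif(1000, -8, 12)
  ap <- runif(1000, 60, 200)
  total <- runif(1000, 200, 800)
  f <- render_zone_forces(ml, ap, total, geom)
  expect_true(all(f >= 0))
  expect_equal(rowSums(f), total, tolerance = 1e-12)
  rec <- insole_recording("s", "EO", "left", (0:999) / 50, f, 50)
  traj <- compute_cop(rec, geom, force_threshold = 1)
  expect_lt(max(abs(traj$ml - ml)), 1e-6)
  expect_lt(max(abs(traj$ap - ap)), 1e-6)
})

test_that("rendering handles hull vertices and conserves mass exactly", {
  geom <- default_zone_geometry()
  # at a zone's own coordinates the force concentrates around that zone
  f <- render_zone_forces(geom$ml[1], geom$ap[1], 500, geom)
  rec_cop <- sum(f * geom$ml) / sum(f)
  expect_lt(abs(rec_cop - geom$ml[1]), 1e-6)
  expect_equal(sum(f), 500, tolerance = 1e-9)
  # centroid with a fixed total
  fc <- render_zone_forces(mean(geom$ml), mean(geom$ap), 700, geom)
  expect_equal(sum(fc), 700)
  # outside-hull targets are projected and flagged
  fo <- render_zone_forces(1000, 1000, 100, geom)
  expect_equal(attr(fo, "projected"), 1L)
  expect_true(all(fo >= 0))
})

test_that("feature extraction on rendered recordings matches the latent
           trajectory", {
  set.seed(40)
  geom <- default_zone_geometry()
  p <- task_params(sway_sd_ml = 3, sway_sd_ap = 4)
  sim <- simulate_cop_trajectory("EO", p, geom, fs = 12)
  f <- render_zone_forces(sim$ml, sim$ap, sim$total, geom)
  rec <- insole_recording("s", "EO", "left",
                          (seq_along(sim$ml) - 1) / 12, f, 12)
  fv_rendered <- compute_foot_features(compute_cop(rec, geom))
  fv_latent <- compute_foot_features(make_traj(sim$ml, sim$ap, fs = 12))
  expect_equal(fv_rendered, fv_latent, tolerance = 1e-6)
})

test_that("null cohort asymmetric features are near zero only when feet
           are identical in distribution, not per draw", {
  coh <- simulate_cohort(c(control = 2, pd = 2), seed = 9, tasks = "EO")
  tab <- build_feature_table(coh$recordings, coh$meta, tasks = "EO")
  # with asymmetry_gain = 1 the two feet share parameters; the asymmetry
  # of the stochastic features stays small but nonzero
  asym_rms <- tab$x[, "asymmetric|EO|rms_ml"]
  expect_true(all(asym_rms < 0.35))
})

test_that("injected effects push the targeted features apart", {
  eff <- preset_effects("pd_vs_control")
  coh <- simulate_cohort(c(control = 6, pd = 6), eff, seed = 13,
                         tasks = "EO")
  tab <- build_feature_table(coh$recordings, coh$meta, tasks = "EO")
  ml <- tab$x[, "average|EO|mean_value_ml"]
  grp <- coh$meta$label
  expect_gt(mean(ml[grp == "pd"]) - mean(ml[grp == "control"]), 4)
})

test_that("gait recordings alternate stance and swing per foot", {
  coh <- simulate_cohort(c(control = 2, pd = 2), seed = 3, tasks = "GAIT")
  rec <- coh$recordings[[1]]
  tot <- rowSums(rec$forces)
  expect_true(any(tot == 0))            # swing phases
  expect_gt(mean(tot > 0), 0.4)         # stance a bit over half the cycle
  expect_lt(mean(tot > 0), 0.75)
})
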