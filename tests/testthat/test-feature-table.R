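cohort_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      coh <- simulate_cohort(
        c(control = 2, pd = 2),
        effect_config(control = list(), pd = list()),
        seed = 21)
      cache <<- list(coh = coh,
                     tab = suppressWarnings(build_feature_table(
                       coh$recordings, coh$meta)))
    }
    cache
  }
})

test_that("the six-task table has 120 columns per task, 720 total", {
  fx <- cohort_fixture()
  tab <- fx$tab
  expect_equal(dim(tab$x), c(4, 720))
  col_task <- sub("^[^|]+\\|([^|]+)\\|.*$", "\\1", colnames(tab$x))
  expect_equal(as.vector(table(col_task)[all_tasks()]), rep(120L, 6))
  col_type <- sub("^([^|]+)\\|.*$", "\\1", colnames(tab$x))
  expect_equal(sum(col_type == "average"), 360)
  expect_equal(sum(col_type == "asymmetric"), 360)
  # static-only view: 3 x 120
  expect_equal(ncol(feature_table_subset(tab, "static")$x), 360)
  expect_equal(ncol(feature_table_subset(tab, "active")$x), 360)
  expect_equal(ncol(feature_table_subset(tab, "static_active")$x), 720)
})

test_that("identical feet make all asymmetric columns zero", {
  coh <- simulate_cohort(c(control = 2, pd = 2), seed = 33, tasks = "EO")
  # duplicate the left foot onto the right so L == R exactly
  recs <- lapply(coh$recordings, function(r) {
    if (r$foot == "right") {
      src <- Filter(function(q) q$subject_id == r$subject_id &
                      q$task == r$task & q$foot == "left",
                    coh$recordings)[[1]]
      insole_recording(r$subject_id, r$task, "right", src$timestamps,
                       src$forces, src$sampling_rate)
    } else r
  })
  tab <- build_feature_table(recs, coh$meta, tasks = "EO")
  asym <- tab$x[, grepl("^asymmetric", colnames(tab$x))]
  expect_lt(max(abs(asym), na.rm = TRUE), 1e-9)
})

test_that("a subject with a single foot for a task is skipped with a
           warning", {
  coh <- simulate_cohort(c(control = 2, pd = 2), seed = 34, tasks = "EO")
  recs <- coh$recordings[-2]   # drop one right foot
  expect_warning(tab <- build_feature_table(recs, coh$meta, tasks = "EO"),
                 "only one foot")
  dropped <- coh$recordings[[2]]$subject_id
  expect_true(all(is.na(tab$x[dropped, ])))
  expect_false(anyNA(tab$x[setdiff(rownames(tab$x), dropped),
                           "average|EO|mean_value_ml"]))
})

test_that("one-foot stance features come from the weight-bearing foot", {
  fx <- cohort_fixture()
  tab <- fx$tab
  # OF columns populated from the stance halves
  expect_false(anyNA(tab$x[, "average|OF|mean_value_ml"]))
  expect_false(anyNA(tab$x[, "asymmetric|OF|rms_ml"]))
})

test_that("min-max normalization maps fit rows into [0, 1] and is not
           clipped out of sample", {
  X <- matrix(c(2, 4, 6, 5, 5, 5), ncol = 2,
              dimnames = list(c("a", "b", "c"), c("v", "const")))
  tab <- structure(list(x = X, meta = NULL), class = "feature_table")
  norm <- minmax_normalize(tab)
  expect_equal(unname(norm$x[, "v"]), c(0, 0.5, 1))
  expect_equal(unname(norm$x[, "const"]), c(0, 0, 0))
  # fit on two rows, apply to a third outside the range
  norm2 <- minmax_normalize(tab, fit_rows = c("a", "b"))
  expect_equal(unname(norm2$x[, "v"]), c(0, 1, 2))
  norm3 <- minmax_normalize(tab, fit_rows = c("a", "b"), clip = TRUE)
  expect_equal(unname(norm3$x[, "v"]), c(0, 1, 1))
})

test_that("normalized non-constant columns attain 0 and 1", {
  fx <- cohort_fixture()
  tab <- minmax_normalize(suppressWarnings(impute_features(fx$tab)))
  rng <- apply(tab$x, 2, range)
  nonconst <- apply(tab$x, 2, function(c) diff(range(c)) > 0)
  expect_true(all(abs(rng[1, nonconst]) < 1e-12))
  expect_true(all(abs(rng[2, nonconst] - 1) < 1e-12))
  expect_true(all(tab$x >= 0 & tab$x <= 1))
})

test_that("median imputation fills missing markers", {
  X <- matrix(c(1, NA, 3, NA, NA, NA), ncol = 2,
              dimnames = list(NULL, c("a", "b")))
  tab <- structure(list(x = X, meta = NULL), class = "feature_table")
  out <- suppressWarnings(impute_features(tab))
  expect_equal(unname(out$x[2, "a"]), 2)
  expect_equal(unname(out$x[, "b"]), c(0, 0, 0))
  expect_warning(impute_features(tab), "entirely missing")
})
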