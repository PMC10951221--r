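test_that("ANOVA F matches hand arithmetic on the printed toy", {
  # class A {1,2,3}, class B {4,5,6}: MSB = 13.5, MSW = 1 -> F = 13.5
  X <- matrix(c(1, 2, 3, 4, 5, 6), ncol = 1,
              dimnames = list(NULL, "toy"))
  y <- factor(rep(c("a", "b"), each = 3))
  res <- f_prefilter(X, y)
  expect_equal(res$F, 13.5)
  expect_equal(res$p, 0.0213, tolerance = 1e-2)
  expect_true(res$retained)
  # cross-check against stats::aov as an independent route
  p_aov <- summary(stats::aov(X[, 1] ~ y))[[1]]["y", "Pr(>F)"]
  expect_equal(res$p, p_aov, tolerance = 1e-12)
})

test_that("a feature identical across classes is removed; degenerate
           constants are skipped", {
  X <- cbind(same = rep(c(1, 2), 6), const = rep(5, 12))
  y <- factor(rep(c("a", "b"), each = 6))
  expect_warning(res <- f_prefilter(X, y), "constant within and between")
  expect_false(res$retained[res$feature == "same"])
  expect_false(res$retained[res$feature == "const"])
})

test_that("under the null the pre-filter retains ~5% of features", {
  frac <- sapply(1:50, function(s) {
    set.seed(s)
    X <- matrix(rnorm(80 * 200), 80,
                dimnames = list(NULL, paste0("f", 1:200)))
    y <- factor(rep(c("a", "b"), each = 40))
    mean(f_prefilter(X, y)$retained)
  })
  expect_lt(abs(mean(frac) - 0.05), 0.02)
})

test_that("SFS picks a perfect separator first and matches the
           brute-force oracle", {
  set.seed(8)
  n <- 20
  X <- matrix(rnorm(n * 6), n,
              dimnames = list(paste0("s", 1:n),
                              c(paste0("n", 1:5), "sep")))
  y <- factor(rep(c("a", "b"), each = n / 2))
  X[, "sep"] <- ifelse(y == "b", 3, -3) + rnorm(n, 0, 0.1)
  spec <- model_spec("lr")
  sel <- sequential_forward_selection(X, y, spec, k = 5, seed = 2)
  expect_equal(sel$path$feature[1], "sep")
  expect_equal(sel$optimal_f1, 1)
  expect_equal(sel$optimal_subset, sel$path$feature[
    seq_len(which.max(sel$path$cv_f1))])

  # oracle equivalence on a small 3-candidate problem
  X3 <- X[, c("n1", "sep", "n2")]
  fold <- stratified_folds(y, 5, seed = 11)
  sel3 <- sequential_forward_selection(X3, y, spec, fold = fold)
  oracle <- sfs_oracle(X3, y, spec, fold)
  expect_equal(sel3$path$feature, oracle$path)
  expect_equal(sel3$path$cv_f1, oracle$f1, tolerance = 1e-12)
})

test_that("duplicated columns break ties by column order", {
  d <- separable_matrix(n_per_class = 8, p_noise = 1, delta = 5)
  X <- cbind(first = d$X[, "signal"], second = d$X[, "signal"],
             noise = d$X[, "noise1"])
  sel <- sequential_forward_selection(X, d$y, model_spec("gnb"),
                                      k = 4, seed = 1)
  expect_equal(sel$path$feature[1], "first")
})

test_that("grid tuning returns the best combination deterministically", {
  # two tight clusters per class: 1-NN wins over large k
  set.seed(14)
  X <- rbind(matrix(rnorm(30, 0, 0.2), ncol = 2),
             matrix(rnorm(30, 3, 0.2), ncol = 2))
  colnames(X) <- c("x1", "x2")
  y <- factor(rep(c("a", "b"), each = 15))
  X[1:2, ] <- X[1:2, ] + 3    # a few class-a points inside cluster b
  tuned <- grid_tune(model_spec("knn"), X, y,
                     grid = list(k = c(1, 13)), seed = 5)
  expect_equal(tuned$params$k, 1)
  # a single-point grid is returned unchanged
  t1 <- grid_tune(model_spec("svm"), X, y,
                  grid = list(cost = 1, kernel = "linear"), seed = 5)
  expect_equal(t1$params$cost, 1)
  expect_equal(t1$params$kernel, "linear")
  # determinism
  t2 <- grid_tune(model_spec("rf"), X, y, seed = 5)
  t3 <- grid_tune(model_spec("rf"), X, y, seed = 5)
  expect_identical(t2$params, t3$params)
  expect_error(grid_tune(model_spec("svm"), X[, 0], y), "empty feature")
})

test_that("task-set comparison flags a large uniform shift and not the
           null", {
  set.seed(22)
  base <- expand.grid(architecture = c("svm", "rf", "lr", "knn", "gnb"),
                      fold = 1:5, stringsAsFactors = FALSE)
  null_df <- rbind(
    cbind(base, task_set = "static", value = 0.8 + rnorm(25, 0, 0.02)),
    cbind(base, task_set = "static_active",
          value = 0.8 + rnorm(25, 0, 0.02)))
  cmp <- compare_task_conditions(null_df)
  expect_equal(cmp$threshold, 0.05 / 3)
  expect_equal(round(cmp$threshold, 3), 0.017)
  expect_false(cmp$significant)

  shift_df <- null_df
  shift_df$value[shift_df$task_set == "static_active"] <-
    shift_df$value[shift_df$task_set == "static_active"] + 0.2
  cmp2 <- compare_task_conditions(shift_df)
  expect_true(cmp2$significant)
  expect_lt(cmp2$p, 0.017)
  expect_gt(cmp2$estimate, 0.15)

  # unbalanced inputs are refused
  expect_error(compare_task_conditions(null_df[-1, ]), "unbalanced")
})
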