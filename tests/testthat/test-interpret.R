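test_that("common features follow the >=3-of-5 rule and a counting
           oracle", {
  subsets <- list(c("a", "b"), c("a", "c"), c("a", "b"), c("d"),
                  c("b", "d"))
  cf <- common_features(subsets)
  expect_true("a" %in% cf)    # in 3 subsets
  expect_true("b" %in% cf)    # in 3 subsets
  expect_false("c" %in% cf)   # 1
  expect_false("d" %in% cf)   # 2: boundary exclusion
  # randomized oracle
  set.seed(31)
  for (rep in 1:10) {
    subs <- replicate(5, sample(letters[1:8], sample(2:5, 1)),
                      simplify = FALSE)
    counts <- table(unlist(lapply(subs, unique)))
    expect_setequal(common_features(subs),
                    names(counts)[counts >= 3])
  }
})

test_that("Shapley values satisfy the null-player, local-accuracy and
           linear-model axioms", {
  set.seed(41)
  X <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("x1", "x2")))
  bg <- matrix(rnorm(60), 30, 2, dimnames = list(NULL, c("x1", "x2")))
  # additive model f(x) = 2 x1 + 3 x2
  lin <- function(model, X) 2 * X[, 1] + 3 * X[, 2]
  sh <- shapley_values(NULL, X, bg, predict_fun = lin)
  expect_equal(sh$phi[, 1], 2 * (X[, 1] - mean(bg[, 1])),
               tolerance = 1e-10)
  expect_equal(sh$phi[, 2], 3 * (X[, 2] - mean(bg[, 2])),
               tolerance = 1e-10)
  # local accuracy: base + sum(phi) = model output
  expect_equal(sh$base_value + rowSums(sh$phi), lin(NULL, X),
               tolerance = 1e-6)
  # null player: a model ignoring x2 gives phi_2 = 0 exactly
  only1 <- function(model, X) sin(X[, 1])
  sh0 <- shapley_values(NULL, X, bg, predict_fun = only1)
  expect_equal(unname(sh0$phi[, 2]), rep(0, 20))
  expect_equal(sh0$top_feature, "x1")
})

test_that("local accuracy holds for a real fitted classifier", {
  d <- separable_matrix(n_per_class = 8, p_noise = 2, delta = 3)
  m <- soleposture:::fit_classifier(model_spec("gnb"), d$X, d$y)
  sh <- shapley_values(m, d$X[1:5, ], d$X)
  out <- unname(soleposture:::predict_scores(m, d$X[1:5, ]))
  expect_equal(sh$base_value + rowSums(sh$phi), out, tolerance = 1e-6)
})

test_that("the sampling estimator agrees with exact enumeration", {
  set.seed(51)
  X <- matrix(rnorm(15), 5, 3, dimnames = list(NULL, paste0("x", 1:3)))
  bg <- matrix(rnorm(30), 10, 3, dimnames = list(NULL, paste0("x", 1:3)))
  f <- function(model, X) X[, 1] * X[, 2] + X[, 3]^2
  exact <- shapley_values(NULL, X, bg, predict_fun = f)
  sampled <- shapley_values(NULL, X, bg, predict_fun = f,
                            max_exact = 0, nsim = 2000, seed = 9)
  expect_equal(sampled$phi, exact$phi, tolerance = 0.1)
})

test_that("key features are the common x top-Shapley intersection", {
  kf <- key_features(list(c("a", "b"), c("c")), list("b", "c", "z"))
  expect_setequal(kf$key, c("b", "c"))
  expect_true(all(kf$key %in% kf$common))
  expect_true(all(kf$key %in% kf$top_shapley))
  kf0 <- key_features(c("a", "b"), list("z"))
  expect_length(kf0$key, 0)
})

test_that("misclassified subjects follow the >=3-of-5 out-of-fold rule", {
  mk_report <- function(wrong_ids) {
    pr <- data.frame(subject = paste0("s", 1:10), fold = 1,
                     truth = factor(rep("a", 10), levels = c("a", "b")),
                     pred = factor(ifelse(paste0("s", 1:10) %in% wrong_ids,
                                          "b", "a"), levels = c("a", "b")),
                     score = 0)
    structure(list(predictions = pr), class = "cv_report")
  }
  reports <- list(mk_report(c("s1", "s2")), mk_report("s1"),
                  mk_report(c("s1", "s2")), mk_report("s3"),
                  mk_report("s2"))
  out <- misclassified_subjects(reports)
  expect_setequal(out, c("s1", "s2"))   # s1: 3, s2: 3 (boundary), s3: 1
  perfect <- replicate(5, mk_report(character(0)), simplify = FALSE)
  expect_length(misclassified_subjects(perfect), 0)
})

test_that("group z-scores use pooled standardisation and oppose for
           balanced groups", {
  X <- matrix(c(-1, -1, -1, 1, 1, 1), ncol = 1,
              dimnames = list(NULL, "f"))
  y <- factor(rep(c("a", "b"), each = 3))
  z <- group_zscores(X, y)
  expect_equal(z["a", "f"], -z["b", "f"])
  expect_equal(unname(z["b", "f"]), 1 / sd(X[, 1]), tolerance = 1e-12)
  # identical groups -> ~0
  X0 <- matrix(rep(c(1, 2, 3), 2), ncol = 1, dimnames = list(NULL, "f"))
  z0 <- group_zscores(X0, y)
  expect_equal(max(abs(z0)), 0)
})

test_that("feature correlations are a valid Pearson matrix", {
  set.seed(61)
  X <- cbind(a = rnorm(200), b = rnorm(200))
  X <- cbind(X, c = 2 * X[, "a"] + 0)
  r <- feature_correlation(X)
  expect_equal(diag(r), c(a = 1, b = 1, c = 1))
  expect_equal(r, t(r))
  expect_equal(unname(r["a", "c"]), 1)
  expect_lt(abs(r["a", "b"]), 0.2)
})
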