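#' Classifier specification
#'
#' The five binary classifier families of the analysis stack: support
#' vector machine (`"svm"`), random forest (`"rf"`), logistic regression
#' (`"lr"`, ridge-penalised), K-nearest neighbours (`"knn"`) and Gaussian
#' naive Bayes (`"gnb"`).
#'
#' @param architecture One of `"svm"`, `"rf"`, `"lr"`, `"knn"`, `"gnb"`.
#' @param params Named list of hyperparameters overriding the defaults
#'   (see [default_grids()] for the tunable names).
#' @param seed Integer seed used for any stochastic fitting (random
#'   forest).
#' @return A `model_spec`.
#' @export
model_spec <- function(architecture = c("svm", "rf", "lr", "knn", "gnb"),
                       params = list(), seed = 1L) {
  architecture <- match.arg(architecture)
  p <- utils::modifyList(default_params(architecture), params)
  structure(list(architecture = architecture, params = p,
                 seed = as.integer(seed)),
            class = "model_spec")
}

#' @rdname model_spec
#' @export
default_model_specs <- function(seed = 1L) {
  archs <- c("svm", "rf", "lr", "knn", "gnb")
  stats::setNames(lapply(archs, model_spec, seed = seed), archs)
}

default_params <- function(architecture) {
  switch(architecture,
    svm = list(cost = 1, kernel = "radial"),
    rf = list(ntree = 100, nodesize = 1),
    lr = list(lambda = 0.01),
    knn = list(k = 5),
    gnb = list(var_smoothing = 1e-9))
}

#' Default hyperparameter grids
#'
#' The tuning grids searched by [grid_tune()]. The reference analysis does
#' not publish its grids, so these are package defaults, chosen to bracket
#' the common operating points of each family; all are overridable.
#'
#' @return Named list architecture -> named list of candidate vectors.
#' @export
default_grids <- function() {
  list(
    svm = list(cost = c(0.1, 1, 10), kernel = c("linear", "radial")),
    rf = list(ntree = c(100, 300), nodesize = c(1, 5)),
    lr = list(lambda = c(0.01, 0.1, 1)),
    knn = list(k = c(3, 5, 7, 9)),
    gnb = list(var_smoothing = c(1e-9, 1e-7)))
}

# ---- uniform fit / predict interface -------------------------------------
# y is a 2-level factor; the second level is the positive class. Scores are
# monotone in the positive-class probability.

fit_classifier <- function(spec, X, y) {
  stopifnot(is.factor(y), nlevels(y) == 2L)
  X <- as.matrix(X)
  p <- spec$params
  set.seed(spec$seed)
  fit <- switch(spec$architecture,
    svm = {
      m <- e1071::svm(X, y, cost = p$cost, kernel = p$kernel,
                      scale = FALSE, probability = FALSE)
      # orient decision values toward the positive (second) class
      dv <- attr(stats::predict(m, X, decision.values = TRUE),
                 "decision.values")
      pos <- levels(y)[2L]
      flip <- mean(dv[y == pos]) < mean(dv[y != pos])
      list(model = m, flip = flip)
    },
    rf = randomForest::randomForest(
      X, y, ntree = p$ntree, nodesize = p$nodesize),
    lr = {
      # glmnet needs >= 2 columns; a constant dummy never gets weight
      X2 <- cbind(X, `.dummy` = 0)
      glmnet::glmnet(X2, y, family = "binomial", alpha = 0,
                     lambda = p$lambda)
    },
    knn = list(X = X, y = y, k = p$k),
    gnb = fit_gnb(X, y, p$var_smoothing))
  structure(list(spec = spec, fit = fit, levels = levels(y),
                 features = colnames(X)),
            class = "fitted_classifier")
}

predict_scores <- function(object, X) {
  X <- as.matrix(X)
  pos <- object$levels[2L]
  f <- object$fit
  switch(object$spec$architecture,
    svm = {
      dv <- attr(stats::predict(f$model, X, decision.values = TRUE),
                 "decision.values")
      as.numeric(if (f$flip) -dv else dv)
    },
    rf = unname(stats::predict(f, X, type = "prob")[, pos]),
    lr = as.numeric(stats::predict(f, cbind(X, `.dummy` = 0),
                                   type = "response")),
    knn = {
      pr <- class::knn(f$X, X, f$y, k = min(f$k, nrow(f$X)), prob = TRUE)
      win <- attr(pr, "prob")
      ifelse(pr == pos, win, 1 - win)
    },
    gnb = predict_gnb(f, X)$posterior)
}

predict_labels <- function(object, X) {
  X <- as.matrix(X)
  f <- object$fit
  lab <- switch(object$spec$architecture,
    svm = as.character(stats::predict(f$model, X)),
    rf = as.character(stats::predict(f, X)),
    lr = object$levels[1L + (predict_scores(object, X) > 0.5)],
    knn = as.character(class::knn(f$X, X, f$y,
                                  k = min(f$k, nrow(f$X)))),
    gnb = predict_gnb(f, X)$class)
  factor(lab, levels = object$levels)
}

# Gaussian naive Bayes with sklearn-style variance smoothing (a fraction
# of the largest feature variance added to every per-class variance).
fit_gnb <- function(X, y, var_smoothing = 1e-9) {
  classes <- levels(y)
  eps <- var_smoothing * max(apply(X, 2L, stats::var), 1e-12)
  stats_by_class <- lapply(classes, function(cl) {
    Xi <- X[y == cl, , drop = FALSE]
    v <- apply(Xi, 2L, stats::var)
    v[is.na(v)] <- 0          # single-observation class in a tiny fold
    list(mean = colMeans(Xi), var = v + eps,
         prior = nrow(Xi) / nrow(X))
  })
  names(stats_by_class) <- classes
  list(classes = classes, stats = stats_by_class)
}

predict_gnb <- function(f, X) {
  loglik <- vapply(f$classes, function(cl) {
    s <- f$stats[[cl]]
    v <- pmax(s$var, 1e-300)
    rowSums(-0.5 * (log(2 * pi * v)[col(X)] +
                      sweep(X, 2L, s$mean)^2 / v[col(X)])) + log(s$prior)
  }, numeric(nrow(X)))
  if (!is.matrix(loglik)) loglik <- matrix(loglik, nrow = 1L)
  shift <- apply(loglik, 1L, max)
  post <- exp(loglik - shift)
  post <- post / rowSums(post)
  list(class = f$classes[max.col(post, ties.method = "first")],
       posterior = unname(post[, 2L]))
}
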