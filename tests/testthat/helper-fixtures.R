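# Shared fixtures, built in code.

# A square 4-zone-like geometry is not allowed (8 zones required); this is
# a compact symmetric 8-zone layout handy for hand-computable centroids.
symmetric_geometry <- function() {
  zone_geometry(ml = c(-10, 10, -10, 10, -10, 10, -10, 10),
                ap = c(200, 200, 140, 140, 80, 80, 20, 20))
}

# Recording with constant force c on every zone.
constant_recording <- function(n = 100, fs = 50, value = 50,
                               task = "EO", foot = "left",
                               subject = "s1") {
  insole_recording(subject, task, foot, (seq_len(n) - 1) / fs,
                   matrix(value, n, 8), fs)
}

# Trajectory straight from coordinate series (all frames valid).
make_traj <- function(ml, ap, fs = 12, ...) {
  soleposture:::cop_trajectory(ml, ap, fs, ...)
}

# Small latent sway trajectory for feature tests.
sway_traj <- function(n = 360, fs = 12, seed = 1, sd_ml = 3, sd_ap = 4) {
  set.seed(seed)
  make_traj(stats::rnorm(n, 0, sd_ml), stats::rnorm(n, 0, sd_ap), fs)
}

# Tiny two-class feature matrix with one separating feature among noise.
separable_matrix <- function(n_per_class = 10, p_noise = 5, delta = 4,
                             seed = 1) {
  set.seed(seed)
  n <- 2 * n_per_class
  X <- matrix(stats::rnorm(n * (p_noise + 1)), n,
              dimnames = list(paste0("s", 1:n),
                              c("signal", paste0("noise", 1:p_noise))))
  y <- factor(rep(c("a", "b"), each = n_per_class), levels = c("a", "b"))
  X[y == "b", "signal"] <- X[y == "b", "signal"] + delta
  list(X = X, y = y)
}

# Brute-force greedy SFS oracle: recomputes every candidate's CV F1 from
# scratch at each step (independent of the package's path bookkeeping).
sfs_oracle <- function(X, y, spec, fold) {
  remaining <- colnames(X)
  chosen <- character(0)
  f1s <- numeric(0)
  while (length(remaining) > 0) {
    sc <- sapply(remaining, function(f) {
      cols <- c(chosen, f)
      mean(sapply(sort(unique(fold)), function(kf) {
        tr <- fold != kf
        m <- soleposture:::fit_classifier(spec, X[tr, cols, drop = FALSE],
                                          y[tr])
        pr <- soleposture:::predict_labels(m, X[!tr, cols, drop = FALSE])
        soleposture::classification_metrics(y[!tr], pr)[["f1"]]
      }))
    })
    i <- which.max(sc)
    chosen <- c(chosen, remaining[i])
    f1s <- c(f1s, sc[i])
    remaining <- remaining[-i]
  }
  list(path = chosen, f1 = unname(f1s))
}
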