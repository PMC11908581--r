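# Independent oracles and fixture builders used across the suite.

# O(n^2) silhouette by the literal definition: per-point loops, no shared
# code with the implementation.
silhouette_oracle <- function(x, labels) {
  x <- as.matrix(x)
  n <- nrow(x)
  d <- function(i, j) sqrt(sum((x[i, ] - x[j, ])^2))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- setdiff(which(labels == labels[i]), i)
    if (length(own) == 0L) {
      s[i] <- 0
      next
    }
    a <- mean(vapply(own, function(j) d(i, j), numeric(1)))
    bs <- vapply(setdiff(unique(labels), labels[i]), function(cl) {
      mean(vapply(which(labels == cl), function(j) d(i, j), numeric(1)))
    }, numeric(1))
    b <- min(bs)
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# Exhaustive-partition minimum WCSS: enumerates all k^n label assignments
# (only sensible for small n) and returns the global minimum of the k-means
# objective.
wcss_bruteforce <- function(x, k) {
  x <- as.matrix(x)
  n <- nrow(x)
  grid <- as.matrix(expand.grid(rep(list(seq_len(k)), n)))
  best <- Inf
  for (r in seq_len(nrow(grid))) {
    lab <- grid[r, ]
    if (length(unique(lab)) < k) next
    w <- 0
    for (cl in seq_len(k)) {
      pts <- x[lab == cl, , drop = FALSE]
      ctr <- colMeans(pts)
      w <- w + sum(sweep(pts, 2, ctr)^2)
    }
    best <- min(best, w)
  }
  best
}

# Noiseless single-peak chromatogram on a dense grid.
gaussian_chrom <- function(apex = 10, height = 100, sigma = 0.1, tau = 0,
                           from = 5, to = 15, by = 0.002, intercept = 0,
                           slope = 0) {
  render_chromatogram(run_spec(
    time_start = from, time_end = to, sampling_interval = by,
    peaks = list(peak_spec("p", apex, height, sigma, tau)),
    baseline_intercept = intercept, baseline_slope = slope, noise_sd = 0))
}

# Reverse the time axis of a chromatogram (mirror image around the window
# centre), keeping time strictly increasing.
mirror_chromatogram <- function(chrom) {
  tibble::tibble(
    time_min = min(chrom$time_min) + max(chrom$time_min) -
      rev(chrom$time_min),
    intensity = rev(chrom$intensity))
}

# Piecewise-linear triangular peak: rises t_rise..t_apex, falls
# t_apex..t_fall.
triangle_chrom <- function(t_rise = 9, t_apex = 10, t_fall = 13, height = 2,
                           from = 5, to = 15, by = 0.005) {
  tt <- seq(from, to, by = by)
  y <- numeric(length(tt))
  up <- tt >= t_rise & tt <= t_apex
  dn <- tt > t_apex & tt <= t_fall
  y[up] <- height * (tt[up] - t_rise) / (t_apex - t_rise)
  y[dn] <- height * (t_fall - tt[dn]) / (t_fall - t_apex)
  tibble::tibble(time_min = tt, intensity = y)
}

# Predictor stub whose predictions are read from a column of the data;
# lets the evaluation metrics be tested against hand-computed values.
mock_predictor <- function(col = "pred") {
  structure(list(col = col), class = "chromaqc_mock_predictor")
}
predict.chromaqc_mock_predictor <- function(object, newdata, ...) {
  newdata[[object$col]]
}
registerS3method("predict", "chromaqc_mock_predictor",
                 predict.chromaqc_mock_predictor, envir = asNamespace("stats"))

# Small hand-built quality table for dataset/validation tests.
toy_quality_table <- function(n = 12, seed = 42) {
  withr::with_seed(seed, tibble::tibble(
    compound_id = sprintf("c%02d", seq_len(n)),
    delta_tr = rnorm(n, 0, 0.05),
    snr = runif(n, 5, 500),
    skewness = runif(n, 0.9, 2.5),
    peak_area = runif(n, 10, 2000),
    length = sample(5:20, n, replace = TRUE),
    sulfur_count = sample(0:4, n, replace = TRUE),
    tr = runif(n, 3, 12)
  ))
}
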