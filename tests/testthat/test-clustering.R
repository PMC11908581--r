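test_that("PCA variance ratios behave on degenerate and isotropic data", {
  x <- cbind(a = rnorm(50), b = 0)
  x[, 2] <- 2 * x[, 1]                      # perfectly collinear
  red <- pca_reduce(x, n_components = 1)
  expect_equal(red$variance_ratios[1], 1, tolerance = 1e-9)

  set.seed(5)
  iso <- matrix(rnorm(20000), ncol = 2)
  red2 <- pca_reduce(iso, n_components = 2)
  expect_equal(unname(red2$variance_ratios), c(0.5, 0.5), tolerance = 0.05)
  expect_equal(sum(red2$variance_ratios), 1, tolerance = 1e-9)

  expect_error(pca_reduce(x, n_components = 2), class = "chromaqc_rank_error")
})

test_that("the cumulative-variance rule picks the smallest sufficient m", {
  # three orthogonal directions with sd ratios giving ~ (0.7, 0.2, 0.1)
  set.seed(11)
  n <- 4000
  base <- cbind(rnorm(n, sd = sqrt(0.7)), rnorm(n, sd = sqrt(0.2)),
                rnorm(n, sd = sqrt(0.1)))
  red <- pca_reduce(base, variance_threshold = 0.8)
  expect_equal(red$n_components, 2)
  expect_gte(sum(red$variance_ratios[1:2]), 0.8)
  red_all <- pca_reduce(base, variance_threshold = 1)
  expect_equal(red_all$n_components, 3)
})

test_that("scores are centred projections onto the principal axes", {
  set.seed(3)
  x <- matrix(rnorm(60), ncol = 3)
  red <- pca_reduce(x, n_components = 3)
  recon <- red$scores %*% t(red$loadings[, 1:3])
  expect_equal(recon, sweep(x, 2, colMeans(x)), ignore_attr = TRUE)
})

test_that("WCSS hits its closed-form anchors", {
  set.seed(21)
  x <- matrix(rnorm(40), ncol = 2)
  curve <- wcss_curve(x, k_range = c(1, nrow(x)), seed = 1)
  expect_equal(curve$wcss[curve$k == 1], sum(scale(x, scale = FALSE)^2))
  expect_equal(curve$wcss[curve$k == nrow(x)], 0, tolerance = 1e-12)

  rect <- rbind(c(0, 0), c(0, 1), c(10, 0), c(10, 1))
  expect_equal(wcss_curve(rect, k_range = 2, seed = 1)$wcss, 1.0)
  expect_error(wcss_curve(rect, k_range = 5), class = "chromaqc_parameter_error")
})

test_that("k-means attains the exhaustive-partition optimum on small data", {
  set.seed(77)
  for (rep in 1:5) {
    x <- matrix(rnorm(16), ncol = 2)
    for (k in 2:3) {
      fit <- kmeans_fit(x, k, seed = rep, n_init = 50)
      expect_equal(fit$wcss, wcss_bruteforce(x, k), tolerance = 1e-9)
    }
  }
})

test_that("k-means agrees with the reference implementation and recovers blobs", {
  set.seed(41)
  centers <- rbind(c(0, 0), c(12, 0), c(0, 12))
  x <- do.call(rbind, lapply(1:3, function(i) {
    sweep(matrix(rnorm(80, sd = 0.5), ncol = 2), 2, centers[i, ], "+")
  }))
  truth <- rep(1:3, each = 40)
  fit <- kmeans_fit(x, 3, seed = 2)
  ref <- stats::kmeans(x, 3, nstart = 10, iter.max = 100)
  expect_equal(fit$wcss, ref$tot.withinss, tolerance = 1e-6)
  skip_if_not_installed("mclust")
  expect_gte(mclust::adjustedRandIndex(fit$labels, truth), 0.99)
})

test_that("k-means handles degenerate inputs and is seed-deterministic", {
  same <- matrix(rep(c(1, 2), 5), ncol = 2, byrow = TRUE)
  fit <- kmeans_fit(same, 1, seed = 1)
  expect_equal(unname(fit$centroids[1, ]), c(1, 2))
  expect_equal(fit$wcss, 0)

  rect <- rbind(c(0, 0), c(0, 1), c(10, 0), c(10, 1))
  fit2 <- kmeans_fit(rect, 2, seed = 3)
  cents <- fit2$centroids[order(fit2$centroids[, 1]), ]
  expect_equal(unname(cents), rbind(c(0, 0.5), c(10, 0.5)))

  set.seed(6)
  x <- matrix(rnorm(60), ncol = 2)
  expect_identical(kmeans_fit(x, 3, seed = 9), kmeans_fit(x, 3, seed = 9))
  expect_error(kmeans_fit(x, 0), class = "chromaqc_parameter_error")
  expect_error(kmeans_fit(x, 31), class = "chromaqc_parameter_error")
})

test_that("labels are stable (up to permutation) under row shuffling", {
  skip_if_not_installed("mclust")
  set.seed(10)
  x <- rbind(matrix(rnorm(40, 0, 0.4), ncol = 2),
             matrix(rnorm(40, 6, 0.4), ncol = 2))
  fit_a <- kmeans_fit(x, 2, seed = 4)
  perm <- sample(nrow(x))
  fit_b <- kmeans_fit(x[perm, ], 2, seed = 4)
  expect_equal(mclust::adjustedRandIndex(fit_a$labels[perm], fit_b$labels), 1)
})

test_that("the elbow is the curvature maximum of the WCSS curve", {
  curve <- tibble::tibble(k = 1:5, wcss = c(100, 95, 30, 28, 27))
  expect_equal(select_k_elbow(curve), 3L)

  set.seed(12)
  centers <- rbind(c(0, 0), c(10, 0), c(0, 10))
  x <- do.call(rbind, lapply(1:3, function(i) {
    sweep(matrix(rnorm(60, sd = 0.5), ncol = 2), 2, centers[i, ], "+")
  }))
  curve2 <- wcss_curve(x, 1:7, seed = 5)
  expect_equal(select_k_elbow(curve2), 3L)
  expect_true(all(diff(curve2$wcss) <= 1e-9))

  linear <- tibble::tibble(k = 1:6, wcss = seq(100, 0, length.out = 6))
  expect_error(select_k_elbow(linear), class = "chromaqc_no_elbow_error")
  expect_error(select_k_elbow(curve[1:3, ]), class = "chromaqc_parameter_error")
})

test_that("silhouette matches its definition oracle and reference bounds", {
  # two point masses: a = 0, b = d > 0 -> 1
  x <- rbind(c(0, 0), c(0, 0), c(5, 5), c(5, 5))
  expect_equal(silhouette_validate(x, c(1, 1, 2, 2)), 1)
  expect_error(silhouette_validate(x, rep(1, 4)),
               class = "chromaqc_parameter_error")

  set.seed(31)
  for (rep in 1:10) {
    n <- sample(6:20, 1)
    x <- matrix(rnorm(2 * n), ncol = 2)
    k <- sample(2:3, 1)
    lab <- sample(rep_len(seq_len(k), n))
    expect_equal(silhouette_validate(x, lab), silhouette_oracle(x, lab),
                 tolerance = 1e-9)
  }

  skip_if_not_installed("cluster")
  set.seed(32)
  x <- matrix(rnorm(100), ncol = 2)
  lab <- sample(rep_len(1:3, 50))
  ref <- mean(cluster::silhouette(lab, dist(x))[, 3])
  expect_equal(silhouette_validate(x, lab), ref, tolerance = 1e-9)
})

test_that("random labels on isotropic data score near zero", {
  set.seed(33)
  x <- matrix(rnorm(1000), ncol = 2)
  lab <- sample(rep_len(1:3, 500))
  expect_lt(abs(silhouette_validate(x, lab)), 0.1)
})

test_that("relabelling orders clusters by descending mean SNR", {
  labels <- c(1, 1, 2, 2, 3, 3)
  snr <- c(5, 7, 100, 120, 40, 45)
  out <- relabel_by_snr(labels, snr)
  expect_equal(out, c(3, 3, 1, 1, 2, 2))
})

test_that("tidiers return one row per cluster / component", {
  set.seed(2)
  x <- matrix(rnorm(80), ncol = 2)
  fit <- kmeans_fit(x, 2, seed = 1)
  td <- tidy(fit)
  expect_equal(nrow(td), 2)
  expect_equal(sum(td$size), nrow(x))
  expect_equal(glance(fit)$k, 2)

  red <- pca_reduce(x, 2)
  expect_equal(nrow(tidy(red)), 2)
  expect_equal(glance(red)$explained_variance, 1, tolerance = 1e-9)
})
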