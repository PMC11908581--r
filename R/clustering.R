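# PCA reduction and quality-sensitive k-means clustering with elbow-selected
# k and silhouette validation.

#' Reduce a feature matrix with principal component analysis
#'
#' Projects the centred matrix onto its leading principal axes. The number
#' of retained components is either fixed (`n_components`) or chosen as the
#' smallest count whose cumulative variance ratio reaches
#' `variance_threshold`. The variance ratio of a component is its
#' eigenvalue divided by the sum of all eigenvalues.
#'
#' @param x Numeric matrix (rows = compounds, columns = features), e.g. the
#'   output of [apply_preprocess()].
#' @param n_components Fixed number of components (default 2, which keeps
#'   the cluster space directly plottable).
#' @param variance_threshold If given (in (0, 1]), overrides `n_components`
#'   with the cumulative-variance rule.
#' @return A `quality_pca` object: `scores` (n x m), `variance_ratios` (all
#'   components), `loadings`, `n_components`, `center`.
#' @export
pca_reduce <- function(x, n_components = 2, variance_threshold = NULL) {
  x <- as.matrix(x)
  if (any(!is.finite(x))) {
    stop_chromaqc("PCA input must be finite.", "chromaqc_parameter_error")
  }
  pc <- prcomp(x, center = TRUE, scale. = FALSE)
  ratios <- pc$sdev^2 / sum(pc$sdev^2)
  rank <- sum(pc$sdev > max(pc$sdev) * 1e-12)
  if (!is.null(variance_threshold)) {
    if (variance_threshold <= 0 || variance_threshold > 1) {
      stop_chromaqc("`variance_threshold` must be in (0, 1].",
                    "chromaqc_parameter_error")
    }
    n_components <- which(cumsum(ratios) >= variance_threshold - 1e-12)[1]
  }
  if (n_components > rank || n_components > nrow(x) - 1) {
    stop_chromaqc("Requested more components than the matrix rank supports.",
                  "chromaqc_rank_error")
  }
  structure(
    list(scores = pc$x[, seq_len(n_components), drop = FALSE],
         variance_ratios = ratios,
         loadings = pc$rotation,
         n_components = n_components,
         center = pc$center),
    class = "quality_pca"
  )
}

#' @export
print.quality_pca <- function(x, ...) {
  cat(sprintf("PCA reduction: %d components, cumulative variance %.1f%%\n",
              x$n_components,
              100 * sum(x$variance_ratios[seq_len(x$n_components)])))
  invisible(x)
}

# k-means++ initial centres (Arthur & Vassilvitskii): first centre uniform,
# subsequent centres sampled proportional to squared distance to the
# nearest chosen centre.
kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  i <- sample.int(n, 1L)
  centers[1L, ] <- x[i, ]
  if (k > 1L) {
    d2 <- rowSums(sweep(x, 2, centers[1L, ])^2)
    for (j in 2:k) {
      if (sum(d2) <= 0) {
        i <- sample.int(n, 1L)
      } else {
        i <- sample.int(n, 1L, prob = d2)
      }
      centers[j, ] <- x[i, ]
      d2 <- pmin(d2, rowSums(sweep(x, 2, centers[j, ])^2))
    }
  }
  centers
}

# Squared Euclidean distances from every row of x to every centre.
dist2_to_centers <- function(x, centers) {
  xx <- rowSums(x^2)
  cc <- rowSums(centers^2)
  outer(xx, cc, "+") - 2 * x %*% t(centers)
}

lloyd_once <- function(x, k, max_iter, tol) {
  centers <- kmeanspp_init(x, k)
  wcss_prev <- Inf
  labels_prev <- rep(0L, nrow(x))
  labels <- rep(1L, nrow(x))
  for (iter in seq_len(max_iter)) {
    d2 <- dist2_to_centers(x, centers)
    labels <- max.col(-d2, ties.method = "first")
    # repair empty clusters: give each the point farthest from its centre
    for (j in which(tabulate(labels, k) == 0L)) {
      far <- which.max(d2[cbind(seq_len(nrow(x)), labels)])
      labels[far] <- j
      d2[far, ] <- 0
    }
    for (j in seq_len(k)) {
      centers[j, ] <- colMeans(x[labels == j, , drop = FALSE])
    }
    wcss <- sum((x - centers[labels, , drop = FALSE])^2)
    if (identical(labels, labels_prev)) break  # exact Lloyd fixed point
    if (is.finite(wcss_prev) && tol > 0 &&
        (wcss_prev - wcss) <= tol * max(wcss_prev, .Machine$double.eps) &&
        iter > 1L) {
      break
    }
    labels_prev <- labels
    wcss_prev <- wcss
  }
  list(labels = labels, centers = centers,
       wcss = sum((x - centers[labels, , drop = FALSE])^2))
}

#' Fit k-means with k-means++ seeding
#'
#' Lloyd iterations from k-means++ starting centres, keeping the best
#' (lowest within-cluster sum of squares) of `n_init` restarts. Runs are
#' deterministic under a fixed seed; empty clusters are repaired by
#' reassigning the point farthest from its current centre. Labels are
#' 1-based cluster indices.
#'
#' @param scores Numeric matrix of coordinates (typically PCA scores).
#' @param k Number of clusters (1 <= k <= n).
#' @param seed Integer seed.
#' @param n_init Number of restarts (default 10).
#' @param max_iter Maximum Lloyd iterations per restart (default 300).
#' @param tol Relative WCSS-change convergence tolerance (default 1e-4).
#' @return A `quality_kmeans` object: `k`, `labels`, `centroids`, `wcss`,
#'   `seed`.
#' @export
kmeans_fit <- function(scores, k, seed = 1L, n_init = 10L, max_iter = 300L,
                       tol = 1e-4) {
  x <- as.matrix(scores)
  if (!is.numeric(k) || length(k) != 1L || k <= 0 || k != round(k)) {
    stop_chromaqc("`k` must be a positive integer.",
                  "chromaqc_parameter_error")
  }
  if (k > nrow(x)) {
    stop_chromaqc("`k` cannot exceed the number of rows.",
                  "chromaqc_parameter_error")
  }
  best <- NULL
  for (init in seq_len(n_init)) {
    fit <- with_seed(derive_seed(seed, init), lloyd_once(x, k, max_iter, tol))
    if (is.null(best) || fit$wcss < best$wcss) best <- fit
  }
  structure(
    list(k = as.integer(k), labels = best$labels, centroids = best$centers,
         wcss = best$wcss, seed = as.integer(seed)),
    class = "quality_kmeans"
  )
}

#' @export
print.quality_kmeans <- function(x, ...) {
  cat(sprintf("k-means fit: k = %d, WCSS = %.4g, sizes = %s\n", x$k, x$wcss,
              paste(tabulate(x$labels, x$k), collapse = "/")))
  invisible(x)
}

#' Within-cluster sum of squares over a range of k
#'
#' Fits [kmeans_fit()] for each `k` and records the minimised WCSS; the
#' resulting curve feeds the elbow selection.
#'
#' @inheritParams kmeans_fit
#' @param k_range Integer vector of candidate k values (default 1:8).
#' @return Tibble with columns `k` and `wcss` (non-increasing in `k`).
#' @export
wcss_curve <- function(scores, k_range = 1:8, seed = 1L, n_init = 10L,
                       max_iter = 300L, tol = 1e-4) {
  x <- as.matrix(scores)
  if (any(k_range > nrow(x)) || any(k_range < 1)) {
    stop_chromaqc("`k_range` must lie within [1, n].",
                  "chromaqc_parameter_error")
  }
  wcss <- vapply(sort(unique(as.integer(k_range))), function(k) {
    kmeans_fit(x, k, seed = derive_seed(seed, 1000L + k), n_init = n_init,
               max_iter = max_iter, tol = tol)$wcss
  }, numeric(1))
  tibble(k = sort(unique(as.integer(k_range))), wcss = wcss)
}

#' Select k at the elbow of the WCSS curve
#'
#' The elbow is the k with the largest discrete curvature, i.e. the largest
#' second forward difference `wcss[k-1] - 2*wcss[k] + wcss[k+1]`; ties go to
#' the smallest k. A curve with no positive curvature (monotone linear
#' decrease) has no elbow and raises an error carrying the curvature
#' diagnostics.
#'
#' @param curve Tibble from [wcss_curve()] with at least 4 points.
#' @return The selected k (integer).
#' @export
select_k_elbow <- function(curve) {
  if (!is.data.frame(curve) || !all(c("k", "wcss") %in% names(curve)) ||
      nrow(curve) < 4L) {
    stop_chromaqc("`curve` needs columns k, wcss and at least 4 points.",
                  "chromaqc_parameter_error")
  }
  curve <- curve[order(curve$k), ]
  w <- curve$wcss
  kk <- curve$k
  d2 <- w[seq_len(nrow(curve) - 2L)] - 2 * w[seq(2, nrow(curve) - 1L)] +
    w[seq(3, nrow(curve))]
  if (max(d2) <= 0) {
    stop_chromaqc("No elbow: the WCSS curve has no positive curvature.",
                  "chromaqc_no_elbow_error",
                  curvature = setNames(d2, kk[seq(2, nrow(curve) - 1L)]))
  }
  as.integer(kk[seq(2, nrow(curve) - 1L)][which.max(d2)])
}

#' Mean silhouette score of a clustering
#'
#' For each point, `a` is its mean distance to the other members of its own
#' cluster and `b` the smallest mean distance to any other cluster; the
#' point's silhouette is `(b - a) / max(a, b)` and singleton-cluster points
#' score 0. Returns the mean over all points (in [-1, 1]).
#'
#' @param scores Numeric coordinate matrix (same space as the clustering).
#' @param labels Integer cluster labels (k >= 2, all clusters non-empty).
#' @return Mean silhouette width.
#' @export
silhouette_validate <- function(scores, labels) {
  x <- as.matrix(scores)
  labels <- as.integer(labels)
  k <- length(unique(labels))
  if (k < 2L) {
    stop_chromaqc("Silhouette needs at least 2 clusters.",
                  "chromaqc_parameter_error")
  }
  n <- nrow(x)
  d <- as.matrix(stats::dist(x))
  sizes <- table(factor(labels, levels = sort(unique(labels))))
  lev <- as.integer(names(sizes))
  # mean distance from each point to each cluster
  md <- vapply(lev, function(cl) {
    rowSums(d[, labels == cl, drop = FALSE]) / sum(labels == cl)
  }, numeric(n))
  s <- numeric(n)
  for (i in seq_len(n)) {
    ci <- match(labels[i], lev)
    ni <- sizes[[ci]]
    if (ni == 1L) {
      s[i] <- 0
      next
    }
    a <- md[i, ci] * ni / (ni - 1)   # exclude the point itself
    b <- min(md[i, -ci])
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

#' Re-index cluster labels by descending mean SNR
#'
#' Cluster indices from k-means are arbitrary; re-indexing by the cluster
#' mean SNR (cluster 1 = highest) makes reports stable across seeds.
#'
#' @param labels Integer cluster labels.
#' @param snr Per-row SNR values.
#' @return Integer labels with 1 the highest-SNR cluster.
#' @export
relabel_by_snr <- function(labels, snr) {
  means <- tapply(snr, labels, mean)
  ord <- names(sort(means, decreasing = TRUE))
  match(as.character(labels), ord)
}
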