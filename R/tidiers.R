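# broom-style tidiers for the fitted objects.

#' Tidy a k-means quality clustering
#'
#' One row per cluster with its size and centroid coordinates.
#'
#' @param x A `quality_kmeans`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.quality_kmeans <- function(x, ...) {
  cent <- as_tibble(x$centroids, .name_repair = ~paste0("dim", seq_along(.x)))
  dplyr::bind_cols(
    tibble(cluster = seq_len(x$k), size = tabulate(x$labels, x$k)),
    cent
  )
}

#' @rdname tidy.quality_kmeans
#' @export
glance.quality_kmeans <- function(x, ...) {
  tibble(k = x$k, wcss = x$wcss, seed = x$seed)
}

#' Tidy a PCA reduction
#'
#' One row per principal component with its variance ratio.
#'
#' @param x A `quality_pca`.
#' @param ... Unused.
#' @return A tibble with `component`, `variance_ratio`,
#'   `cumulative_variance`, `retained`.
#' @export
tidy.quality_pca <- function(x, ...) {
  tibble(component = seq_along(x$variance_ratios),
         variance_ratio = x$variance_ratios,
         cumulative_variance = cumsum(x$variance_ratios),
         retained = seq_along(x$variance_ratios) <= x$n_components)
}

#' @rdname tidy.quality_pca
#' @export
glance.quality_pca <- function(x, ...) {
  tibble(n_components = x$n_components,
         explained_variance = sum(x$variance_ratios[seq_len(x$n_components)]))
}

#' Tidy a grid-searched regressor
#'
#' The full cross-validation trace, one row per grid configuration.
#'
#' @param x A `cluster_regressor`.
#' @param ... Unused.
#' @return The `cv_results` tibble.
#' @export
tidy.cluster_regressor <- function(x, ...) {
  x$cv_results
}

#' @rdname tidy.cluster_regressor
#' @export
glance.cluster_regressor <- function(x, ...) {
  dplyr::bind_cols(tibble(model_family = x$model_family),
                   as_tibble(x$best_params))
}

#' Tidy a per-cluster evaluation set
#'
#' @param x A `cluster_evaluation_set`.
#' @param ... Unused.
#' @return The evaluations tibble (one row per modelled cluster).
#' @export
tidy.cluster_evaluation_set <- function(x, ...) {
  x$evaluations
}

#' @rdname tidy.cluster_evaluation_set
#' @export
glance.cluster_evaluation_set <- function(x, ...) {
  tibble(n_modelled = nrow(x$evaluations), n_skipped = nrow(x$skipped))
}
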