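# ggplot2 figures for the main result types.

#' Scatter of cluster assignments in PCA space
#'
#' @param scores PCA score matrix (at least 2 columns).
#' @param labels Cluster labels.
#' @return A ggplot.
#' @export
plot_cluster_scatter <- function(scores, labels) {
  df <- tibble(PC1 = scores[, 1],
               PC2 = if (ncol(scores) >= 2) scores[, 2] else 0,
               cluster = factor(labels))
  ggplot2::ggplot(df, ggplot2::aes(.data$PC1, .data$PC2,
                                   colour = .data$cluster)) +
    ggplot2::geom_point(alpha = 0.7, size = 1.6) +
    ggplot2::labs(x = "PC1", y = "PC2", colour = "cluster",
                  title = "Quality clusters in principal-component space") +
    ggplot2::theme_minimal()
}

#' Elbow plot of the WCSS curve
#'
#' @param curve Tibble from [wcss_curve()].
#' @param k_selected Optional k to highlight.
#' @return A ggplot.
#' @export
plot_wcss <- function(curve, k_selected = NULL) {
  p <- ggplot2::ggplot(curve, ggplot2::aes(.data$k, .data$wcss)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "k", y = "within-cluster sum of squares",
                  title = "Elbow curve") +
    ggplot2::theme_minimal()
  if (!is.null(k_selected)) {
    p <- p + ggplot2::geom_vline(xintercept = k_selected, linetype = 2,
                                 colour = "red")
  }
  p
}

#' Observed versus predicted retention time per cluster
#'
#' @param report A `quality_run_report` with fitted per-cluster models.
#' @return A faceted ggplot, or `NULL` when no cluster was modelled.
#' @export
plot_observed_predicted <- function(report) {
  models <- report$evaluation$models
  if (length(models) == 0L) return(NULL)
  df <- purrr::map_dfr(names(models), function(nm) {
    cl <- as.integer(sub("cluster_", "", nm))
    rows <- report$table[report$labels == cl, , drop = FALSE]
    tibble(cluster = paste("cluster", cl), observed = rows$tr,
           predicted = predict(models[[nm]], rows))
  })
  ggplot2::ggplot(df, ggplot2::aes(.data$observed, .data$predicted)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey60") +
    ggplot2::geom_point(alpha = 0.6, size = 1.4) +
    ggplot2::facet_wrap(~cluster, scales = "free") +
    ggplot2::labs(x = "observed tR (min)", y = "predicted tR (min)",
                  title = "Observed vs predicted retention time") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.quality_kmeans <- function(object, scores, ...) {
  plot_cluster_scatter(scores, object$labels)
}

#' @export
autoplot.quality_run_report <- function(object, ...) {
  plot_cluster_scatter(object$pca$scores, object$labels)
}

#' Plot a chromatogram
#'
#' @param chrom Chromatogram tibble.
#' @return A ggplot.
#' @export
plot_chromatogram <- function(chrom) {
  validate_chromatogram(chrom)
  ggplot2::ggplot(chrom, ggplot2::aes(.data$time_min, .data$intensity)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (min)", y = "intensity") +
    ggplot2::theme_minimal()
}
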