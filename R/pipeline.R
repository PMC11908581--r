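# End-to-end pipeline: simulate/ingest -> measure -> assemble -> preprocess
# -> PCA -> elbow -> silhouette -> k-means -> per-cluster evaluation ->
# ranking -> report.

#' Build a pipeline configuration
#'
#' Exactly one input mode must be active:
#' * `simulate` - generate a synthetic cohort (list with `n_compounds`,
#'   optional `tier_mixture`, `sigma`, `tr_noise_sd`);
#' * `chromatograms` - a tibble with columns `compound_id`, `run1`, `run2`
#'   (paths to chromatogram CSVs), `window_lo`, `window_hi`, plus a
#'   `metadata` tibble;
#' * `quality_table` - a pre-computed quality table (tibble or CSV path).
#'
#' @param simulate,chromatograms,quality_table Input-mode payloads (give
#'   exactly one).
#' @param seed Master seed for every random stage.
#' @param x Height fraction for skewness/width measurement.
#' @param features Clustering feature names.
#' @param n_components Fixed PCA dimension (`NULL` to use
#'   `variance_threshold`).
#' @param variance_threshold Cumulative-variance PCA rule (used when
#'   `n_components` is `NULL`).
#' @param k_range Candidate k values for the elbow scan.
#' @param k Fixed number of clusters; `NULL` (default) selects k by elbow.
#' @param model Regressor family: `"gb"` or `"svr"`.
#' @param n_estimators GB boosting-round candidates (reduced grids pass 100).
#' @param test_fraction,cv_folds,min_cluster_size Evaluation settings.
#' @param plots Whether [run_quality_pipeline()] writes figures.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(simulate = NULL, chromatograms = NULL,
                            quality_table = NULL, seed = 1L, x = 0.5,
                            features = quality_feature_names(),
                            n_components = 2, variance_threshold = NULL,
                            k_range = 1:8, k = NULL,
                            model = c("gb", "svr"),
                            n_estimators = c(100, 500, 1000),
                            test_fraction = 0.2, cv_folds = 5L,
                            min_cluster_size = 10L, plots = FALSE) {
  model <- match.arg(model)
  modes <- c(simulate = !is.null(simulate),
             chromatograms = !is.null(chromatograms),
             quality_table = !is.null(quality_table))
  if (sum(modes) != 1L) {
    stop_chromaqc("Exactly one input mode (simulate / chromatograms / quality_table) must be given.",
                  "chromaqc_validation_error")
  }
  structure(
    list(mode = names(modes)[modes], simulate = simulate,
         chromatograms = chromatograms, quality_table = quality_table,
         seed = as.integer(seed), x = x, features = features,
         n_components = n_components, variance_threshold = variance_threshold,
         k_range = k_range, k = k, model = model,
         n_estimators = n_estimators, test_fraction = test_fraction,
         cv_folds = as.integer(cv_folds),
         min_cluster_size = as.integer(min_cluster_size), plots = plots),
    class = "pipeline_config"
  )
}

ingest_stage <- function(config) {
  if (config$mode == "simulate") {
    sim <- config$simulate
    cohort <- simulate_cohort(
      n_compounds = sim$n_compounds,
      tier_mixture = sim$tier_mixture %||% c(high = 1 / 3, medium = 1 / 3,
                                             low = 1 / 3),
      tier_profiles = sim$tier_profiles %||% default_tier_profiles(),
      seed = config$seed,
      sigma = sim$sigma %||% 0.06,
      tr_noise_sd = sim$tr_noise_sd %||% 0.01)
    measurements <- measure_cohort(cohort, x = config$x)
    metadata <- cohort$truth[, c("compound_id", "length", "sulfur_count")]
    list(measurements = measurements, metadata = metadata,
         truth = cohort$truth)
  } else if (config$mode == "chromatograms") {
    spec <- config$chromatograms
    runs <- spec$runs
    measurements <- purrr::map_dfr(seq_len(nrow(runs)), function(i) {
      measure_peak(read_chromatogram_csv(runs$run1[i]),
                   read_chromatogram_csv(runs$run2[i]),
                   runs$compound_id[i],
                   window = c(runs$window_lo[i], runs$window_hi[i]),
                   x = config$x)
    })
    list(measurements = measurements, metadata = spec$metadata, truth = NULL)
  } else {
    qt <- config$quality_table
    if (is.character(qt)) qt <- read_quality_csv(qt)
    list(measurements = NULL, metadata = NULL, truth = NULL, table = qt)
  }
}

#' Run the full quality-evaluation pipeline
#'
#' Executes every stage in order and, if `out_dir` is given, persists each
#' stage's output as a plain-text artifact (CSV/JSON). Re-running the same
#' configuration writes byte-identical artifacts.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed); `NULL` skips
#'   writing.
#' @return A `quality_run_report` list with the table, clustering evidence,
#'   evaluations, ranking and feedback.
#' @export
run_quality_pipeline <- function(config, out_dir = NULL) {
  if (!inherits(config, "pipeline_config")) {
    stop_chromaqc("`config` must come from pipeline_config().",
                  "chromaqc_validation_error")
  }
  stage <- function(name, expr) {
    tryCatch(expr, chromaqc_error = function(e) {
      stop_chromaqc(sprintf("[stage %s] %s", name, conditionMessage(e)),
                    class = class(e)[1])
    })
  }

  ing <- stage("ingest", ingest_stage(config))
  table <- if (!is.null(ing$table)) ing$table else
    stage("assemble", assemble_quality_table(ing$measurements, ing$metadata))
  table <- stage("clean", drop_incomplete(table, config$features))

  transform <- stage("preprocess",
                     fit_preprocess(table, config$features))
  mat <- apply_preprocess(transform, table)

  pca <- stage("pca", pca_reduce(mat, n_components = config$n_components,
                                 variance_threshold = config$variance_threshold))

  curve <- stage("elbow", wcss_curve(pca$scores, config$k_range,
                                     seed = config$seed))
  k <- config$k %||% stage("elbow", select_k_elbow(curve))

  km <- stage("kmeans", kmeans_fit(pca$scores, k, seed = config$seed))
  labels <- relabel_by_snr(km$labels, table$snr)
  sil <- if (k >= 2) stage("silhouette",
                           silhouette_validate(pca$scores, labels)) else NA_real_

  grid <- if (config$model == "gb") gb_grid(config$n_estimators) else svr_grid()
  evaluation <- stage("evaluate",
    evaluate_clusters(table, labels, grid,
                      test_fraction = config$test_fraction,
                      cv_folds = config$cv_folds, seed = config$seed,
                      min_size = config$min_cluster_size,
                      features = config$features))
  ranking <- if (nrow(evaluation$evaluations) > 0)
    stage("rank", rank_clusters(evaluation$evaluations)) else NULL

  report <- structure(
    list(config = config, table = table, transform = transform, pca = pca,
         wcss = curve, k = k, kmeans = km, labels = labels,
         mean_silhouette = sil, evaluation = evaluation, ranking = ranking,
         truth = ing$truth,
         feedback = feedback_section(evaluation, ranking)),
    class = "quality_run_report"
  )
  if (!is.null(out_dir)) {
    write_report(report, out_dir)
  }
  report
}

# Narrative feedback: which quality measurements most separate the
# best-ranked from the worst-ranked cluster, as standardized effect sizes
# (mean difference over pooled spread) computed from the ClusterSummary
# tables only.
feedback_section <- function(evaluation, ranking) {
  if (is.null(ranking) || nrow(ranking) < 2L) {
    return(list(
      comparable = FALSE,
      message = "Fewer than two clusters were modelled; no cluster comparison is possible."))
  }
  best <- evaluation$summaries[[paste0("cluster_", ranking$cluster[1])]]
  worst <- evaluation$summaries[[paste0("cluster_",
                                        ranking$cluster[nrow(ranking)])]]
  feats <- intersect(best$variable, quality_feature_names())
  ratios <- purrr::map_dfr(feats, function(v) {
    b <- best$mean[best$variable == v]
    w <- worst$mean[worst$variable == v]
    pooled <- mean(c(best$std[best$variable == v],
                     worst$std[worst$variable == v]), na.rm = TRUE)
    if (!is.finite(pooled) || pooled == 0) pooled <- .Machine$double.eps
    tibble(variable = v, best_mean = b, worst_mean = w,
           separation = abs(b - w) / pooled)
  })
  ratios <- dplyr::arrange(ratios, dplyr::desc(.data$separation))
  list(comparable = TRUE, separating_features = ratios,
       top_features = head(ratios$variable, 2),
       message = sprintf(
           "Features separating the best from the worst cluster most strongly: %s.",
           paste(head(ratios$variable, 2), collapse = ", ")))
}

#' @export
print.quality_run_report <- function(x, ...) {
  cat("Quality-evaluation run\n")
  cat(sprintf("  rows: %d   k: %d   mean silhouette: %s\n", nrow(x$table),
              x$k, format(round(x$mean_silhouette, 3))))
  if (!is.null(x$ranking)) {
    print(x$ranking[, c("cluster", "rank", "verdict", "rmse_test", "r2_test")])
  }
  cat(" ", x$feedback$message, "\n")
  invisible(x)
}

#' Persist a pipeline run as plain-text artifacts
#'
#' Writes the quality table, preprocessing transform, clustering
#' diagnostics, cluster assignments, per-cluster evaluations and summaries,
#' plus a machine-readable `report.json` and human-readable `report.md`.
#' Artifacts contain no timestamps, so re-running a configuration
#' reproduces them byte-for-byte. With `config$plots = TRUE` the cluster
#' scatter, elbow curve and observed-vs-predicted figures are saved too.
#'
#' @param report A `quality_run_report`.
#' @param out_dir Output directory.
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(out_dir, ...)

  write_quality_csv(report$table, p("quality_table.csv"))
  write_preprocess_json(report$transform, p("preprocess.json"))
  readr::write_csv(tibble(compound_id = report$table$compound_id,
                          cluster = report$labels),
                   p("cluster_assignments.csv"), progress = FALSE)
  jsonlite::write_json(
    list(seed = report$config$seed,
         k = report$k,
         mean_silhouette = report$mean_silhouette,
         wcss_curve = setNames(as.list(report$wcss$wcss),
                               paste0("k", report$wcss$k)),
         variance_ratios = report$pca$variance_ratios,
         n_components = report$pca$n_components),
    p("clustering_diagnostics.json"), digits = NA, auto_unbox = TRUE)

  for (nm in names(report$evaluation$summaries)) {
    readr::write_csv(report$evaluation$summaries[[nm]],
                     p(paste0("summary_", nm, ".csv")), progress = FALSE)
  }
  ev <- report$evaluation$evaluations
  if (nrow(ev)) {
    ev_json <- purrr::map(seq_len(nrow(ev)), function(i) {
      list(cluster = ev$cluster[i], n_train = ev$n_train[i],
           n_test = ev$n_test[i], best_params = ev$best_params[[i]],
           rmse_train = ev$rmse_train[i], r2_train = ev$r2_train[i],
           rmse_test = ev$rmse_test[i], r2_test = ev$r2_test[i],
           verdict = if (!is.null(report$ranking))
             report$ranking$verdict[match(ev$cluster[i],
                                          report$ranking$cluster)]
           else NA_character_)
    })
  } else {
    ev_json <- list()
  }
  jsonlite::write_json(
    list(seed = report$config$seed, mode = report$config$mode,
         model = report$config$model, k = report$k,
         mean_silhouette = report$mean_silhouette,
         clusters = ev_json,
         skipped = report$evaluation$skipped,
         feedback = report$feedback[c("comparable", "message")]),
    p("report.json"), digits = NA, auto_unbox = TRUE)

  writeLines(report_markdown(report), p("report.md"))

  if (isTRUE(report$config$plots)) {
    ggplot2::ggsave(p("clusters.png"), autoplot(report), width = 6,
                    height = 5, dpi = 150)
    ggplot2::ggsave(p("elbow.png"), plot_wcss(report$wcss, report$k),
                    width = 6, height = 4, dpi = 150)
    op <- plot_observed_predicted(report)
    if (!is.null(op)) {
      ggplot2::ggsave(p("observed_vs_predicted.png"), op, width = 7,
                      height = 5, dpi = 150)
    }
  }
  invisible(out_dir)
}

report_markdown <- function(report) {
  lines <- c(
    "# Chromatographic data-quality evaluation report", "",
    sprintf("- Input mode: %s", report$config$mode),
    sprintf("- Seed: %d", report$config$seed),
    sprintf("- Records analysed: %d", nrow(report$table)),
    sprintf("- Principal components retained: %d (%.1f%% variance)",
            report$pca$n_components,
            100 * sum(report$pca$variance_ratios[
              seq_len(report$pca$n_components)])),
    sprintf("- Clusters (k): %d, selected %s", report$k,
            if (is.null(report$config$k)) "by the elbow criterion"
            else "by configuration"),
    sprintf("- Mean silhouette: %s", format(round(report$mean_silhouette, 3))),
    "", "## Per-cluster model performance", "")
  if (!is.null(report$ranking)) {
    rk <- report$ranking
    lines <- c(lines,
      "| cluster | n train | n test | RMSE test | R2 test | verdict |",
      "|---|---|---|---|---|---|",
      sprintf("| %d | %d | %d | %.4g | %s | %s |", rk$cluster, rk$n_train,
              rk$n_test, rk$rmse_test, format(round(rk$r2_test, 3)),
              rk$verdict))
  } else {
    lines <- c(lines, "No cluster was large enough to model.")
  }
  if (nrow(report$evaluation$skipped)) {
    lines <- c(lines, "", "## Skipped clusters", "",
               sprintf("- cluster %d (n = %d): %s",
                       report$evaluation$skipped$cluster,
                       report$evaluation$skipped$n,
                       report$evaluation$skipped$reason))
  }
  lines <- c(lines, "", "## Feedback to data source controllers", "",
             report$feedback$message)
  if (isTRUE(report$feedback$comparable)) {
    sf <- report$feedback$separating_features
    lines <- c(lines, "",
      "| feature | best-cluster mean | worst-cluster mean |",
      "|---|---|---|",
      sprintf("| %s | %.4g | %.4g |", sf$variable, sf$best_mean,
              sf$worst_mean))
  }
  lines
}
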