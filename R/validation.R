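# Per-cluster supervised validation: train/test split, grid-searched
# regressors, evaluation metrics, descriptive summaries, cluster ranking.

#' Hyper-parameter grid for a regressor family
#'
#' @param model_family `"gradient_boosted_trees"` or
#'   `"support_vector_regression"`.
#' @param parameters Named list mapping parameter names to candidate value
#'   vectors. Valid names: GB `max_depth`, `learning_rate`, `n_estimators`,
#'   `max_leaf_nodes`; SVR `C`, `gamma`, `epsilon`.
#' @return A `model_grid` object.
#' @seealso [gb_grid()], [svr_grid()] for the shipped default grids.
#' @export
model_grid <- function(model_family = c("gradient_boosted_trees",
                                        "support_vector_regression"),
                       parameters) {
  model_family <- match.arg(model_family)
  valid <- switch(model_family,
    gradient_boosted_trees = c("max_depth", "learning_rate", "n_estimators",
                               "max_leaf_nodes"),
    support_vector_regression = c("C", "gamma", "epsilon"))
  if (!is.list(parameters) || length(parameters) == 0L ||
      is.null(names(parameters)) || any(names(parameters) == "") ||
      any(lengths(parameters) == 0L)) {
    stop_chromaqc("`parameters` must be a non-empty named list of value vectors.",
                  "chromaqc_parameter_error")
  }
  bad <- setdiff(names(parameters), valid)
  if (length(bad) > 0) {
    stop_chromaqc(paste("Invalid parameter(s) for", model_family, ":",
                        paste(bad, collapse = ", ")),
                  "chromaqc_parameter_error")
  }
  structure(list(model_family = model_family, parameters = parameters),
            class = "model_grid")
}

#' Default gradient-boosted-trees search grid
#'
#' @param n_estimators Boosting-round candidates; the full default is
#'   `c(100, 500, 1000)`, and a reduced run may pass `100` only.
#' @return A `model_grid`.
#' @export
gb_grid <- function(n_estimators = c(100, 500, 1000)) {
  model_grid("gradient_boosted_trees", list(
    max_depth = c(5, 10, 15, 20, 50),
    learning_rate = c(0.001, 0.01, 0.1, 0.2),
    n_estimators = n_estimators,
    max_leaf_nodes = c(2, 5, 10)
  ))
}

#' Default support-vector-regression search grid
#'
#' The regularisation grid spans 1-1000 on a roughly logarithmic ladder
#' (config data, not code): 1, 21.38, 62.16 then four log-interpolated
#' steps up to 1000. Kernel is radial basis.
#'
#' @return A `model_grid`.
#' @export
svr_grid <- function() {
  model_grid("support_vector_regression", list(
    C = c(1, 21.38, 62.16, 108.54, 189.52, 330.93, 577.81, 1000),
    gamma = c(0.1, 0.01, 0.001),
    epsilon = c(0.0001, 0.00011111, 0.00012222, 0.0002)
  ))
}

#' Seeded train/test split
#'
#' Random, disjoint, exhaustive split of the rows; reproducible under a
#' fixed seed.
#'
#' @param data Tibble of cluster rows.
#' @param test_fraction Fraction of rows held out (default 0.2).
#' @param seed Integer seed.
#' @param min_size Minimum cluster size to allow modelling (default 10);
#'   smaller inputs raise a skip error the caller records.
#' @return List with `train` and `test` tibbles.
#' @export
split_train_test <- function(data, test_fraction = 0.2, seed = 1L,
                             min_size = 10L) {
  n <- nrow(data)
  if (n < min_size) {
    stop_chromaqc(sprintf("Cluster of size %d below minimum %d; skipped.",
                          n, min_size),
                  "chromaqc_small_cluster_error")
  }
  if (test_fraction <= 0 || test_fraction >= 1) {
    stop_chromaqc("`test_fraction` must be in (0, 1).",
                  "chromaqc_parameter_error")
  }
  n_test <- max(1L, floor(n * test_fraction))
  idx <- with_seed(derive_seed(seed, 7L), sample.int(n, n_test))
  list(train = data[-idx, , drop = FALSE], test = data[idx, , drop = FALSE])
}

fit_gb <- function(x, y, params, n_estimators) {
  dtrain <- xgboost::xgb.DMatrix(data = x, label = y, nthread = 1)
  xgboost::xgb.train(
    params = list(max_depth = params$max_depth, eta = params$learning_rate,
                  max_leaves = params$max_leaf_nodes, tree_method = "hist",
                  grow_policy = "lossguide",
                  objective = "reg:squarederror", nthread = 1),
    data = dtrain, nrounds = n_estimators, verbose = 0
  )
}

predict_family <- function(family, model, x, scaler = NULL) {
  if (family == "gradient_boosted_trees") {
    predict(model, xgboost::xgb.DMatrix(data = x, nthread = 1))
  } else {
    xs <- sweep(sweep(x, 2, scaler$means), 2, scaler$sds, "/")
    as.numeric(predict(model, xs))
  }
}

fit_config <- function(family, x, y, cfg) {
  if (family == "gradient_boosted_trees") {
    list(model = fit_gb(x, y, cfg, cfg$n_estimators), scaler = NULL)
  } else {
    # kernel methods are scale sensitive: z-score features on the training
    # rows only (trees are scale-equivariant and skip this)
    means <- colMeans(x)
    sds <- apply(x, 2, stats::sd)
    sds[sds == 0 | !is.finite(sds)] <- 1
    xs <- sweep(sweep(x, 2, means), 2, sds, "/")
    model <- e1071::svm(x = xs, y = y, type = "eps-regression",
                        kernel = "radial", cost = cfg$C, gamma = cfg$gamma,
                        epsilon = cfg$epsilon, scale = FALSE)
    list(model = model, scaler = list(means = means, sds = sds))
  }
}

#' Exhaustive grid search with cross-validated RMSE
#'
#' Evaluates every configuration in the grid's Cartesian product by k-fold
#' cross-validation on the training rows (seeded fold assignment), selects
#' the configuration with the lowest mean fold RMSE (ties: first in grid
#' order) and refits it on the full training set.
#'
#' @param train Training tibble containing `features` and the target column.
#' @param grid A [model_grid()].
#' @param cv_folds Number of folds (floored at 2; reduced with a warning
#'   when the training set is too small).
#' @param seed Integer seed for fold assignment.
#' @param features Feature column names (default the six quality features).
#' @param target Target column name (default `"tr"`).
#' @return A `cluster_regressor`: fitted model, `best_params`,
#'   `cv_results` tibble, feature/target names.
#' @export
grid_search_fit <- function(train, grid, cv_folds = 5L, seed = 1L,
                            features = quality_feature_names(),
                            target = "tr") {
  if (!inherits(grid, "model_grid")) {
    stop_chromaqc("`grid` must be a model_grid.", "chromaqc_parameter_error")
  }
  x <- as.matrix(train[, features, drop = FALSE])
  y <- train[[target]]
  n <- nrow(x)
  if (n < 4L || stats::sd(y) == 0) {
    stop_chromaqc("Training data degenerate (too few rows or constant target).",
                  "chromaqc_parameter_error")
  }
  if (cv_folds > n %/% 2L) {
    cv_folds <- max(2L, n %/% 2L)
    warn(sprintf("Reduced cv_folds to %d for %d training rows.", cv_folds, n))
  }
  cv_folds <- max(2L, as.integer(cv_folds))
  fold_id <- with_seed(derive_seed(seed, 11L),
                       sample(rep_len(seq_len(cv_folds), n)))
  configs <- expand.grid(grid$parameters, KEEP.OUT.ATTRS = FALSE,
                         stringsAsFactors = FALSE)
  cv_rmse <- numeric(nrow(configs))
  for (ci in seq_len(nrow(configs))) {
    cfg <- as.list(configs[ci, , drop = FALSE])
    errs <- numeric(cv_folds)
    for (f in seq_len(cv_folds)) {
      hold <- fold_id == f
      fit <- fit_config(grid$model_family, x[!hold, , drop = FALSE], y[!hold],
                        cfg)
      pred <- predict_family(grid$model_family, fit$model,
                             x[hold, , drop = FALSE], fit$scaler)
      errs[f] <- sqrt(mean((y[hold] - pred)^2))
    }
    cv_rmse[ci] <- mean(errs)
  }
  best_i <- which.min(cv_rmse)
  best_params <- as.list(configs[best_i, , drop = FALSE])
  final <- fit_config(grid$model_family, x, y, best_params)
  structure(
    list(model_family = grid$model_family, model = final$model,
         scaler = final$scaler, best_params = best_params,
         cv_results = dplyr::bind_cols(as_tibble(configs),
                                       tibble(cv_rmse = cv_rmse)),
         features = features, target = target),
    class = "cluster_regressor"
  )
}

#' @export
predict.cluster_regressor <- function(object, newdata, ...) {
  x <- as.matrix(newdata[, object$features, drop = FALSE])
  predict_family(object$model_family, object$model, x, object$scaler)
}

#' @export
print.cluster_regressor <- function(x, ...) {
  cat(sprintf("Grid-searched %s regressor (target `%s`)\n", x$model_family,
              x$target))
  cat("Best parameters:",
      paste(names(x$best_params), unlist(x$best_params), sep = "=",
            collapse = ", "), "\n")
  invisible(x)
}

#' Evaluate a fitted regressor
#'
#' Root-mean-square error and coefficient of determination on held-out
#' rows. `R^2 = 1 - SSres/SStot` about the test-set mean; with a constant
#' test target it is undefined and reported missing.
#'
#' @param predictor A `cluster_regressor` (or anything with a `predict`
#'   method over the same columns).
#' @param test Test tibble.
#' @param target Target column name.
#' @return One-row tibble: `rmse`, `r2`, `n`.
#' @export
evaluate_predictor <- function(predictor, test, target = "tr") {
  if (nrow(test) == 0L) {
    stop_chromaqc("Test set is empty.", "chromaqc_parameter_error")
  }
  obs <- test[[target]]
  pred <- predict(predictor, test)
  rmse <- sqrt(mean((obs - pred)^2))
  sstot <- sum((obs - mean(obs))^2)
  r2 <- if (sstot == 0) NA_real_ else 1 - sum((obs - pred)^2) / sstot
  if (sstot == 0) {
    inform("Constant test target: R^2 undefined, reported as missing.")
  }
  tibble(rmse = rmse, r2 = r2, n = length(obs))
}

#' Descriptive statistics of a cluster
#'
#' Mean, sample standard deviation, minimum, quartiles (linear
#' interpolation), median and maximum for every feature and the target, one
#' row per variable. A single-row cluster reports `std` as missing.
#'
#' @param rows Cluster tibble.
#' @param variables Columns to summarise (default: the six quality features
#'   plus the target `tr`).
#' @return Tibble with columns `variable, mean, std, min, q25, median,
#'   q75, max`.
#' @export
summarize_cluster <- function(rows,
                              variables = c(quality_feature_names(), "tr")) {
  variables <- intersect(variables, names(rows))
  if (nrow(rows) == 0L) {
    stop_chromaqc("Cannot summarise an empty cluster.",
                  "chromaqc_parameter_error")
  }
  purrr::map_dfr(variables, function(v) {
    vals <- rows[[v]]
    vals <- vals[!is.na(vals)]
    qs <- quantile(vals, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
    tibble(variable = v, mean = mean(vals),
           std = if (length(vals) > 1L) stats::sd(vals) else NA_real_,
           min = min(vals), q25 = qs[1], median = qs[2], q75 = qs[3],
           max = max(vals))
  })
}

#' Grid-search, fit and evaluate a regressor in every cluster
#'
#' For each cluster: within-cluster train/test split, exhaustive grid
#' search with cross-validation, refit, train and test metrics, and a
#' descriptive summary table. Clusters below `min_size` are skipped and
#' recorded.
#'
#' @param table Quality table (complete rows).
#' @param labels Integer cluster labels aligned with `table` rows.
#' @param grid A [model_grid()].
#' @param test_fraction,cv_folds,seed Split and search settings.
#' @param min_size Minimum rows for a cluster to be modelled.
#' @param features,target Modelling columns.
#' @return A `cluster_evaluation_set`: `evaluations` tibble (one row per
#'   modelled cluster: cluster, n_train, n_test, best_params list-column,
#'   rmse_train, r2_train, rmse_test, r2_test), `summaries` (named list of
#'   summary tibbles for every cluster), `skipped` tibble, `models` list.
#' @export
evaluate_clusters <- function(table, labels, grid = gb_grid(),
                              test_fraction = 0.2, cv_folds = 5L, seed = 1L,
                              min_size = 10L,
                              features = quality_feature_names(),
                              target = "tr") {
  stopifnot(nrow(table) == length(labels))
  ks <- sort(unique(labels))
  evaluations <- list()
  summaries <- list()
  models <- list()
  skipped <- list()
  for (cl in ks) {
    rows <- table[labels == cl, , drop = FALSE]
    summaries[[paste0("cluster_", cl)]] <- summarize_cluster(rows)
    res <- tryCatch({
      sp <- split_train_test(rows, test_fraction,
                             seed = derive_seed(seed, 30L + cl),
                             min_size = min_size)
      reg <- grid_search_fit(sp$train, grid, cv_folds,
                             seed = derive_seed(seed, 60L + cl),
                             features = features, target = target)
      ev_tr <- evaluate_predictor(reg, sp$train, target)
      ev_te <- evaluate_predictor(reg, sp$test, target)
      models[[paste0("cluster_", cl)]] <- reg
      tibble(cluster = cl, n_train = nrow(sp$train), n_test = nrow(sp$test),
             best_params = list(reg$best_params),
             rmse_train = ev_tr$rmse, r2_train = ev_tr$r2,
             rmse_test = ev_te$rmse, r2_test = ev_te$r2)
    }, chromaqc_small_cluster_error = function(e) {
      skipped[[length(skipped) + 1L]] <<- tibble(cluster = cl, n = nrow(rows),
                                                 reason = conditionMessage(e))
      NULL
    })
    if (!is.null(res)) evaluations[[length(evaluations) + 1L]] <- res
  }
  structure(
    list(evaluations = dplyr::bind_rows(evaluations),
         summaries = summaries,
         skipped = if (length(skipped)) dplyr::bind_rows(skipped)
                   else tibble(cluster = integer(), n = integer(),
                               reason = character()),
         models = models),
    class = "cluster_evaluation_set"
  )
}

#' @export
print.cluster_evaluation_set <- function(x, ...) {
  cat(sprintf("Per-cluster evaluation: %d modelled, %d skipped\n",
              nrow(x$evaluations), nrow(x$skipped)))
  if (nrow(x$evaluations)) {
    print(x$evaluations[, c("cluster", "n_train", "n_test", "rmse_test",
                            "r2_test")])
  }
  invisible(x)
}

#' Rank clusters by predictive performance
#'
#' Orders modelled clusters by ascending test RMSE (ties: descending test
#' R^2, then cluster index) and attaches a quality verdict: the best-ranked
#' cluster is `"high"`, the worst `"low"`, anything between `"medium"`.
#' Differences in per-cluster model performance are the evidence that the
#' clusters capture genuinely different data-quality levels.
#'
#' @param evaluations Evaluation tibble from [evaluate_clusters()] (the
#'   `evaluations` element), or a `cluster_evaluation_set`.
#' @return The tibble sorted with an added `rank` and `verdict` column.
#' @export
rank_clusters <- function(evaluations) {
  if (inherits(evaluations, "cluster_evaluation_set")) {
    evaluations <- evaluations$evaluations
  }
  if (!is.data.frame(evaluations) || nrow(evaluations) == 0L) {
    stop_chromaqc("No evaluated clusters to rank.", "chromaqc_ranking_error")
  }
  ord <- order(evaluations$rmse_test, -rank_na_last(evaluations$r2_test),
               evaluations$cluster)
  out <- evaluations[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  out$verdict <- "medium"
  out$verdict[1] <- "high"
  if (nrow(out) > 1L) out$verdict[nrow(out)] <- "low"
  out
}

rank_na_last <- function(x) {
  x[is.na(x)] <- -Inf
  x
}
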