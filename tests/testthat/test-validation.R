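test_that("train/test splits are exact, disjoint and reproducible", {
  tab <- toy_quality_table(n = 10)
  sp <- split_train_test(tab, 0.2, seed = 1)
  expect_equal(nrow(sp$train), 8)
  expect_equal(nrow(sp$test), 2)
  expect_identical(split_train_test(tab, 0.2, seed = 1), sp)

  set.seed(55)
  for (rep in 1:5) {
    n <- sample(10:40, 1)
    tab_n <- toy_quality_table(n = n, seed = rep)
    sp_n <- split_train_test(tab_n, 0.25, seed = rep)
    ids <- c(sp_n$train$compound_id, sp_n$test$compound_id)
    expect_setequal(ids, tab_n$compound_id)
    expect_equal(length(ids), n)
  }
  expect_error(split_train_test(tab[1:5, ], 0.2),
               class = "chromaqc_small_cluster_error")
})

test_that("model grids validate family-specific parameter names", {
  expect_error(model_grid("gradient_boosted_trees", list(C = 1)),
               class = "chromaqc_parameter_error")
  expect_error(model_grid("support_vector_regression", list()),
               class = "chromaqc_parameter_error")
  g <- gb_grid()
  expect_equal(sort(names(g$parameters)),
               c("learning_rate", "max_depth", "max_leaf_nodes",
                 "n_estimators"))
  expect_equal(g$parameters$max_depth, c(5, 10, 15, 20, 50))
  expect_equal(g$parameters$learning_rate, c(0.001, 0.01, 0.1, 0.2))
  s <- svr_grid()
  expect_equal(s$parameters$gamma, c(0.1, 0.01, 0.001))
  expect_true(all(c(1, 21.38, 62.16, 1000) %in% s$parameters$C))
})

test_that("a one-point grid is selected identically and params come from the grid", {
  tab <- toy_quality_table(n = 40)
  g1 <- model_grid("gradient_boosted_trees",
                   list(max_depth = 3, learning_rate = 0.1,
                        n_estimators = 50, max_leaf_nodes = 5))
  fit <- grid_search_fit(tab, g1, cv_folds = 3, seed = 2)
  expect_equal(fit$best_params,
               list(max_depth = 3, learning_rate = 0.1, n_estimators = 50,
                    max_leaf_nodes = 5))

  g2 <- model_grid("support_vector_regression",
                   list(C = c(1, 10), gamma = c(0.1, 0.01), epsilon = 0.001))
  fit2 <- grid_search_fit(tab, g2, cv_folds = 3, seed = 2)
  combos <- expand.grid(g2$parameters)
  expect_true(any(apply(combos, 1, function(row) {
    all(abs(unlist(fit2$best_params) - row) < 1e-12)
  })))
  expect_equal(nrow(tidy(fit2)), 4)
})

test_that("a noiseless linear target is learned almost perfectly", {
  set.seed(7)
  n <- 120
  tab <- tibble::tibble(
    compound_id = as.character(seq_len(n)),
    delta_tr = rnorm(n), snr = runif(n, 1, 100), skewness = runif(n, 1, 3),
    peak_area = runif(n, 1, 10), length = sample(5:20, n, TRUE),
    sulfur_count = sample(0:5, n, TRUE))
  tab$tr <- 2 * tab$length + 1
  sp <- split_train_test(tab, 0.2, seed = 3)
  fit <- grid_search_fit(sp$train, gb_grid(n_estimators = 100), cv_folds = 3,
                         seed = 3)
  ev <- evaluate_predictor(fit, sp$test)
  expect_gte(ev$r2, 0.99)
})

test_that("cross-validation folds are floored with a warning", {
  tab <- toy_quality_table(n = 10)
  g <- model_grid("support_vector_regression",
                  list(C = 1, gamma = 0.1, epsilon = 0.001))
  expect_warning(grid_search_fit(tab, g, cv_folds = 8, seed = 1),
                 "Reduced cv_folds")
})

test_that("evaluation metrics match their arithmetic definitions", {
  ident <- mock_predictor("obs_copy")
  test <- tibble::tibble(tr = c(1, 2, 3), obs_copy = c(1, 2, 3))
  ev <- evaluate_predictor(ident, test)
  expect_equal(ev$rmse, 0)
  expect_equal(ev$r2, 1)

  test2 <- tibble::tibble(tr = c(1, 2, 3), obs_copy = c(2, 2, 2))
  ev2 <- evaluate_predictor(ident, test2)   # predicting the mean
  expect_equal(ev2$r2, 0)

  test3 <- tibble::tibble(tr = c(1, 2, 3), obs_copy = c(1, 2, 4))
  ev3 <- evaluate_predictor(ident, test3)
  expect_equal(ev3$rmse, sqrt(1 / 3))

  const <- tibble::tibble(tr = c(2, 2, 2), obs_copy = c(1, 2, 3))
  expect_message(ev4 <- evaluate_predictor(ident, const), "undefined")
  expect_true(is.na(ev4$r2))
})

test_that("evaluate matches a hand-rolled oracle on random small cases", {
  ident <- mock_predictor("pred")
  set.seed(90)
  for (rep in 1:20) {
    n <- sample(3:12, 1)
    obs <- rnorm(n)
    pred <- rnorm(n)
    ev <- evaluate_predictor(ident, tibble::tibble(tr = obs, pred = pred))
    expect_equal(ev$rmse, sqrt(sum((obs - pred)^2) / n), tolerance = 1e-12)
    expect_equal(ev$r2, 1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2),
                 tolerance = 1e-12)
  }
})

test_that("cluster summaries report the standard descriptive statistics", {
  rows <- tibble::tibble(tr = c(1, 2, 3, 4, 5))
  s <- summarize_cluster(rows, variables = "tr")
  expect_equal(s$mean, 3)
  expect_equal(s$median, 3)
  expect_equal(s$q25, 2)
  expect_equal(s$q75, 4)
  expect_equal(s$std, sd(1:5))

  one <- summarize_cluster(tibble::tibble(tr = 4), variables = "tr")
  expect_true(is.na(one$std))

  set.seed(61)
  rnd <- summarize_cluster(toy_quality_table(n = 25))
  expect_true(all(rnd$min <= rnd$q25 & rnd$q25 <= rnd$median &
                    rnd$median <= rnd$q75 & rnd$q75 <= rnd$max))
})

test_that("cluster ranking orders by test RMSE with stable tie-breaks", {
  ev <- tibble::tibble(cluster = c(1, 2, 3), n_train = 8, n_test = 2,
                       best_params = list(list(), list(), list()),
                       rmse_train = 0.05, r2_train = 0.9,
                       rmse_test = c(0.08, 0.57, 0.71),
                       r2_test = c(0.95, 0.78, 0.03))
  rk <- rank_clusters(ev)
  expect_equal(rk$cluster, c(1, 2, 3))
  expect_equal(rk$verdict, c("high", "medium", "low"))

  tie <- ev
  tie$rmse_test <- 0.1
  tie$r2_test <- 0.5
  expect_equal(rank_clusters(tie)$cluster, c(1, 2, 3))
  expect_error(rank_clusters(ev[0, ]), class = "chromaqc_ranking_error")
})

test_that("per-cluster evaluation skips small clusters and records them", {
  tab <- toy_quality_table(n = 26)
  labels <- c(rep(1, 12), rep(2, 11), rep(3, 3))
  g <- model_grid("support_vector_regression",
                  list(C = c(1, 10), gamma = 0.1, epsilon = 0.001))
  ev <- evaluate_clusters(tab, labels, g, cv_folds = 3, seed = 5)
  expect_equal(ev$evaluations$cluster, c(1, 2))
  expect_equal(ev$skipped$cluster, 3)
  expect_length(ev$summaries, 3)
  expect_equal(glance(ev)$n_modelled, 2)
  expect_equal(nrow(tidy(ev)), 2)
})
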