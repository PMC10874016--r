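test_that("model configuration validates hyperparameter names", {
  m <- build_model("knn", list(n_neighbors = 2, p = 2, algorithm = "brute"))
  expect_equal(m$hyper$n_neighbors, 2)
  expect_error(build_model("knn", list(k = 2)), "invalid hyperparameter")
  expect_error(build_model("catboost"), "arg")
  # legacy token shim is applied and recorded
  dt <- build_model("decision_tree", list(max_features = "auto"))
  expect_equal(dt$hyper$max_features, "sqrt")
  expect_match(dt$shim_notes, "auto")
})

test_that("metric set satisfies its identities", {
  y <- c(3, 4)
  m <- metric_set(c(0, 0), y)
  expect_equal(m$rmse, sqrt(12.5))
  expect_equal(m$mae, 3.5)
  perfect <- metric_set(y, y)
  expect_equal(unlist(perfect[c("rmse", "mse", "mae")]), c(rmse = 0, mse = 0, mae = 0))
  expect_equal(unlist(perfect[c("pearson", "spearman", "r2")]),
               c(pearson = 1, spearman = 1, r2 = 1))
  set.seed(30)
  p <- rnorm(50); t <- rnorm(50)
  r <- metric_set(p, t)
  expect_equal(r$rmse^2, r$mse, tolerance = 1e-9)
  expect_lte(abs(r$pearson), 1)
  # spearman invariant under strictly monotone transforms of predictions
  expect_equal(metric_set(exp(p), t)$spearman, r$spearman)
  expect_error(metric_set(1, 1), ">= 2")
  expect_equal(metric_set(c(Inf, 1), c(0, 1))$status, "failed")
})

test_that("the zoo fits a noiseless planted linear signal", {
  fm <- linear_fixture(n = 240, noise_sd = 0)
  sp <- split_and_normalize(fm, seed = 9)
  fits <- list(
    gradient_boosted_trees = build_model("gradient_boosted_trees",
                                         list(n_estimators = 200, max_depth = 4)),
    random_forest = build_model("random_forest", list(n_estimators = 100)),
    extra_trees = build_model("extra_trees", list(n_estimators = 100)),
    svm = build_model("svm", list(kernel = "rbf", C = 1.5, gamma = "scale")),
    decision_tree = build_model("decision_tree", list(max_depth = 10)),
    knn = build_model("knn", list(n_neighbors = 3, p = 2)))
  for (kind in names(fits)) {
    f <- train_model(fits[[kind]], sp$train, seed = 1)
    m <- evaluate_model(f, sp$train, "train")
    expect_equal(m$subset, "train")
    expect_gt(m$r2, if (kind == "gradient_boosted_trees") 0.99 else 0.5)
  }
  # sgd linear model recovers a linear signal well
  f <- train_model(build_model("sgd", list(penalty = "l2", alpha = 1e-5,
                                           learning_rate = "adaptive")),
                   sp$train, seed = 1)
  expect_gt(evaluate_model(f, sp$test)$r2, 0.9)
})

test_that("Minkowski kNN honors k and p", {
  fm <- linear_fixture(n = 60, noise_sd = 0)
  sp <- split_and_normalize(fm, seed = 10)
  f1 <- train_model(build_model("knn", list(n_neighbors = 1, p = 2)), sp$train)
  # k = 1: every training point predicts itself
  expect_equal(predict(f1, sp$train), sp$train$target)
  f2 <- train_model(build_model("knn", list(n_neighbors = 3, p = 1)), sp$train)
  q <- sp$test$values[1, , drop = FALSE]
  d <- rowSums(abs(sweep(sp$train$values, 2, q)))
  expect_equal(predict(f2, q)[1], mean(sp$train$target[order(d)[1:3]]))
})

test_that("tree-model refits with the same seed reproduce predictions", {
  fm <- linear_fixture(n = 120, noise_sd = 0.2)
  sp <- split_and_normalize(fm, seed = 11)
  for (kind in c("gradient_boosted_trees", "random_forest", "extra_trees")) {
    a <- predict(train_model(build_model(kind, list(n_estimators = 50)), sp$train,
                             seed = 3), sp$test)
    b <- predict(train_model(build_model(kind, list(n_estimators = 50)), sp$train,
                             seed = 3), sp$test)
    expect_identical(a, b, info = kind)
  }
})

test_that("predictions are independent of batch order", {
  fm <- linear_fixture(n = 80, noise_sd = 0)
  sp <- split_and_normalize(fm, seed = 12)
  f <- train_model(build_model("gradient_boosted_trees", list(n_estimators = 30)),
                   sp$train)
  p <- predict(f, sp$test)
  perm <- rev(seq_len(nrow(sp$test$values)))
  fm_perm <- feature_matrix(sp$test$values[perm, ], fm$schema,
                            sp$test$row_ids[perm],
                            colnames_override = colnames(sp$test$values))
  expect_equal(predict(f, fm_perm), p[perm])
})

test_that("grid search picks the dominant configuration deterministically", {
  fm <- linear_fixture(n = 150, noise_sd = 0.1)
  sp <- split_and_normalize(fm, seed = 13)
  s <- hyperparameter_search("knn", list(n_neighbors = c(2, 50), p = 2),
                             sp$train, protocol = list(folds = 3), seed = 2)
  expect_equal(s$best$hyper$n_neighbors, 2)
  expect_equal(nrow(s$log), 2)
  s2 <- hyperparameter_search("knn", list(n_neighbors = c(2, 50), p = 2),
                              sp$train, protocol = list(folds = 3), seed = 2)
  expect_identical(s$log, s2$log)
  expect_error(hyperparameter_search("knn", list(), sp$train), "empty")
})

test_that("net search samples within the stated ranges", {
  fm <- linear_fixture(n = 80, noise_sd = 0.1)
  sp <- split_and_normalize(fm, seed = 14)
  grid <- list(ranges = list(depth = c(1, 1, 1), layer_size = c(8, 16, 8),
                             epochs = c(10, 20, 10),
                             learning_rate = c(0.00001, 0.001, 0.00001)),
               choices = list(use_dropout = FALSE))
  s <- hyperparameter_search("deep_net", grid, sp$train,
                             protocol = list(folds = 2, n_candidates = 3), seed = 3)
  expect_gte(s$best$hyper$learning_rate, 0.00001)
  expect_lte(s$best$hyper$learning_rate, 0.001)
  expect_true(s$best$hyper$layer_size %in% c(8, 16))
  expect_equal(nrow(s$log), 3)
})

test_that("prediction failures are structured and do not block the batch", {
  bench <- benchmark_split(1)
  arts <- list(fitted = train_model(build_model("gradient_boosted_trees",
                                                list(n_estimators = 20)),
                                    bench$split$train),
               schema = feature_schema(), stats = bench$split$stats,
               kept_columns = colnames(bench$pruned$values),
               genomics = bench$gen$genomics,
               anomaly_map = load_anomaly_map(), cargo_vocab = load_cargo_vocab())
  batch <- bind_records(make_record("ok1"),
                        make_record("bad", sequence = "GR??K"),
                        make_record("ok2", sequence = "KLALKLALKALKAALKLA"))
  out <- predict_records(arts, batch)
  expect_equal(out$status, c("ok", "failed", "ok"))
  expect_true(all(is.finite(out$predicted_log10_uptake[out$status == "ok"])))
  expect_match(out$reason[2], "substitution")
  # a curated training record re-predicts to its stored train prediction
  rec1 <- bench$curated[match(bench$split$train$row_ids[1], bench$curated$record_id), ]
  single <- predict_records(arts, rec1)
  expect_equal(single$predicted_log10_uptake,
               unname(predict(arts$fitted, bench$split$train)[1]),
               tolerance = 1e-9)
})

test_that("published optima pass validation for every kind", {
  for (kind in c("svm", "sgd", "knn", "decision_tree", "random_forest",
                 "extra_trees", "gradient_boosted_trees", "deep_net", "forked_net"))
    expect_s3_class(build_model(kind, default_optima(kind)), "cpp_model")
})
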