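# The nine-regressor zoo: configuration and validation, backends, training,
# six-metric evaluation, cross-validated hyperparameter search, and the
# end-to-end prediction path. Classical backends: e1071 (SVM), rpart (DT),
# ranger (RF / extremely randomized trees), xgboost (XGB); the Minkowski kNN
# and SGD linear regressor are implemented here, and both nets run on the
# in-package feed-forward engine.

MODEL_KINDS <- c("svm", "sgd", "knn", "decision_tree", "random_forest",
                 "extra_trees", "gradient_boosted_trees", "deep_net", "forked_net")

hyper_schema <- function(kind) {
  switch(kind,
    svm = c("kernel", "C", "gamma"),
    sgd = c("loss", "penalty", "alpha", "learning_rate", "eta0", "max_iter"),
    knn = c("n_neighbors", "p", "algorithm"),
    decision_tree = c("splitter", "criterion", "max_depth", "min_samples_split",
                      "min_samples_leaf", "min_weight_fraction_leaf", "max_features"),
    random_forest = c("n_estimators", "criterion", "max_depth", "min_samples_split",
                      "min_samples_leaf", "min_weight_fraction_leaf"),
    extra_trees = c("n_estimators", "criterion", "max_depth", "min_samples_split",
                    "min_samples_leaf", "min_weight_fraction_leaf"),
    gradient_boosted_trees = c("n_estimators", "max_depth", "max_leaves",
                               "learning_rate", "booster", "alpha", "lambda", "gamma"),
    deep_net = c("depth", "layer_size", "use_dropout", "dropout_rate",
                 "epochs", "learning_rate", "weight_decay", "average_epochs"),
    forked_net = c("depth", "dropout", "use_dropout", "learning_rate", "epochs",
                   "weight_decay", paste0(forked_branch_names(), "_layer_size")),
    abort(sprintf("unknown model kind '%s'", kind), "config_error"))
}

# grid tokens from legacy scikit-learn-style vocabularies mapped to modern
# equivalents; recorded on the config so the shim is auditable
compat_shim <- function(kind, hyper) {
  notes <- character(0)
  if (!is.null(hyper$max_features) && identical(hyper$max_features, "auto")) {
    hyper$max_features <- "sqrt"
    notes <- c(notes, "max_features 'auto' -> 'sqrt'")
  }
  list(hyper = hyper, notes = notes)
}

#' Build a model configuration
#'
#' Validates hyperparameter names against the per-kind grid schema and
#' returns an untrained model handle.
#'
#' @param kind one of `r paste(MODEL_KINDS, collapse = ", ")`.
#' @param hyper named list of hyperparameters (Table-2-style names in
#'   snake_case, e.g. `n_neighbors`, `max_depth`, `learning_rate`).
#' @param seed integer seed attached to the handle.
#' @return object of class `cpp_model` (untrained handle).
#' @export
build_model <- function(kind, hyper = list(), seed = 1L) {
  kind <- match.arg(kind, MODEL_KINDS)
  bad <- setdiff(names(hyper), hyper_schema(kind))
  if (length(bad))
    abort(sprintf("invalid hyperparameter '%s' for kind '%s'", bad[1], kind),
          "config_error")
  sh <- compat_shim(kind, hyper)
  structure(list(kind = kind, hyper = sh$hyper, shim_notes = sh$notes,
                 seed = as.integer(seed)),
            class = "cpp_model")
}

#' @export
print.cpp_model <- function(x, ...) {
  cat("<cpp_model>", x$kind, "\n")
  if (length(x$hyper))
    cat("  ", paste(names(x$hyper), vapply(x$hyper, function(v) paste(v, collapse = ","),
                                           character(1)), sep = "=", collapse = "; "), "\n")
  invisible(x)
}

hv <- function(model, name, default) model$hyper[[name]] %||% default

svm_gamma <- function(gamma, x) {
  if (is.numeric(gamma)) return(gamma)
  p <- ncol(x)
  switch(gamma,
         scale = 1 / (p * mean(apply(x, 2, var)) + 1e-12),
         auto = 1 / p,
         abort(sprintf("unknown gamma '%s'", gamma), "config_error"))
}

#' Train a model on a normalized feature matrix
#'
#' @param model a `cpp_model` handle from [build_model()].
#' @param fm normalized training `cpp_feature_matrix` with a target.
#' @param seed RNG seed (defaults to the handle's).
#' @return object of class `cpp_fitted_model` with a [predict()] method.
#'   Nets additionally carry their training loss curve.
#' @export
train_model <- function(model, fm, seed = model$seed) {
  if (is.null(fm$target)) abort("training requires a target", "validation_error")
  x <- fm$values
  y <- fm$target
  if (any(!is.finite(x)) || any(!is.finite(y)))
    abort("training inputs must be finite", "validation_error")
  set.seed(seed)
  h <- model$hyper
  remap <- NULL
  if (model$kind %in% c("deep_net", "forked_net")) {
    remap <- fit_binary_remap(x)
    x <- apply_binary_remap(remap, x)
  }
  fit <- switch(model$kind,
    svm = {
      kern <- switch(hv(model, "kernel", "rbf"), linear = "linear",
                     poly = "polynomial", rbf = "radial", sigmoid = "sigmoid")
      e1071::svm(x, y, kernel = kern, cost = hv(model, "C", 1),
                 gamma = svm_gamma(hv(model, "gamma", "scale"), x), scale = FALSE)
    },
    sgd = sgd_fit(x, y,
                  penalty = hv(model, "penalty", "l2"),
                  alpha = hv(model, "alpha", 1e-4),
                  schedule = hv(model, "learning_rate", "invscaling"),
                  eta0 = hv(model, "eta0", 0.01),
                  max_iter = hv(model, "max_iter", 100L)),
    knn = list(x = x, y = y, k = hv(model, "n_neighbors", 5L), p = hv(model, "p", 2)),
    decision_tree = {
      df <- as.data.frame(x); df$.y <- y
      depth <- hv(model, "max_depth", 30L)
      rpart::rpart(.y ~ ., df, method = "anova",
                   control = rpart::rpart.control(
                     maxdepth = min(if (is.null(depth)) 30L else depth, 30L),
                     minsplit = hv(model, "min_samples_split", 2L),
                     minbucket = hv(model, "min_samples_leaf", 1L),
                     cp = 0, xval = 0))
    },
    random_forest = ranger_fit(x, y, h, extratrees = FALSE, seed = seed),
    extra_trees = ranger_fit(x, y, h, extratrees = TRUE, seed = seed),
    gradient_boosted_trees = {
      params <- list(max_depth = hv(model, "max_depth", 6L),
                     eta = hv(model, "learning_rate", 0.3),
                     booster = hv(model, "booster", "gbtree"),
                     alpha = hv(model, "alpha", 0),
                     lambda = hv(model, "lambda", 1),
                     gamma = hv(model, "gamma", 0),
                     nthread = 1)
      ml <- hv(model, "max_leaves", NULL)
      if (!is.null(ml)) params$max_leaves <- ml
      params <- params[!vapply(params, is.null, logical(1))]
      xgboost::xgb.train(params = params,
                         data = xgboost::xgb.DMatrix(x, label = y, nthread = 1),
                         nrounds = hv(model, "n_estimators", 100L))
    },
    deep_net = train_plain_net(x, y,
                               depth = hv(model, "depth", 1L),
                               layer_size = hv(model, "layer_size", 500L),
                               learning_rate = hv(model, "learning_rate", 5e-4),
                               epochs = hv(model, "epochs", 230L),
                               use_dropout = isTRUE(hv(model, "use_dropout", FALSE)),
                               dropout_rate = hv(model, "dropout_rate", 0.3),
                               weight_decay = hv(model, "weight_decay", 0),
                               average_epochs = hv(model, "average_epochs", 0),
                               seed = seed),
    forked_net = {
      groups <- forked_group_cols(colnames(x), fm$schema)
      widths <- lapply(names(groups), function(g)
        hv(model, paste0(g, "_layer_size"), 32L))
      names(widths) <- names(groups)
      spec <- forked_net_spec(unlist(widths),
                              depth = hv(model, "depth", 7L),
                              dropout = hv(model, "dropout", 0.9),
                              use_dropout = isTRUE(hv(model, "use_dropout", FALSE)),
                              learning_rate = hv(model, "learning_rate", 1e-4),
                              epochs = hv(model, "epochs", 170L),
                              weight_decay = hv(model, "weight_decay", 0))
      c(train_forked_net(x, y, groups, spec, seed = seed), list(spec = spec))
    })
  structure(list(kind = model$kind, model = model, fit = fit,
                 columns = colnames(x), seed = seed, remap = remap,
                 loss_curve = fit$loss_curve),
            class = "cpp_fitted_model")
}

ranger_fit <- function(x, y, h, extratrees, seed) {
  df <- as.data.frame(x); df$.y <- y
  ranger::ranger(.y ~ ., df,
                 num.trees = h$n_estimators %||% 100L,
                 max.depth = h$max_depth %||% 0L,
                 min.node.size = h$min_samples_leaf %||% 5L,
                 splitrule = if (extratrees) "extratrees" else "variance",
                 replace = !extratrees,
                 sample.fraction = if (extratrees) 1 else 0.632,
                 num.threads = 1, seed = seed)
}

# linear model fit by stochastic gradient descent on squared error with
# l2/l1/elasticnet penalties and scikit-learn-style step-size schedules
sgd_fit <- function(x, y, penalty = "l2", alpha = 1e-4, schedule = "invscaling",
                    eta0 = 0.01, max_iter = 100L, l1_ratio = 0.15) {
  n <- nrow(x); p <- ncol(x)
  w <- numeric(p); b <- 0
  t <- 1
  best <- Inf; stall <- 0; eta_ad <- eta0
  for (epoch in seq_len(max_iter)) {
    ord <- sample.int(n)
    for (i in ord) {
      eta <- switch(schedule,
                    constant = eta0,
                    invscaling = eta0 / t^0.25,
                    optimal = 1 / (alpha * (t + 1 / (alpha * eta0))),
                    adaptive = eta_ad,
                    abort(sprintf("unknown learning-rate schedule '%s'", schedule),
                          "config_error"))
      xi <- x[i, ]
      err <- sum(xi * w) + b - y[i]
      grad <- err * xi
      grad <- grad + switch(penalty,
                            l2 = alpha * w,
                            l1 = alpha * sign(w),
                            elasticnet = alpha * (l1_ratio * sign(w) +
                                                    (1 - l1_ratio) * w),
                            abort(sprintf("unknown penalty '%s'", penalty),
                                  "config_error"))
      w <- w - eta * grad
      b <- b - eta * err
      t <- t + 1
    }
    loss <- mean((x %*% w + b - y)^2)
    if (!is.finite(loss)) break
    if (schedule == "adaptive") {
      if (loss > best - 1e-6) { stall <- stall + 1 } else stall <- 0
      if (stall >= 5) { eta_ad <- eta_ad / 5; stall <- 0 }
    }
    best <- min(best, loss)
  }
  list(w = w, b = b, diverged = !all(is.finite(c(w, b))))
}

minkowski_knn <- function(fit, xnew) {
  apply(xnew, 1, function(q) {
    d <- if (fit$p == 2) sqrt(colSums((t(fit$x) - q)^2))
         else rowSums(abs(sweep(fit$x, 2, q))^fit$p)^(1 / fit$p)
    mean(fit$y[order(d)[seq_len(fit$k)]])
  })
}

#' Predict from a fitted model
#'
#' @param object a `cpp_fitted_model`.
#' @param newdata numeric matrix or `cpp_feature_matrix` with the training
#'   columns.
#' @param ... unused.
#' @return numeric predictions.
#' @export
predict.cpp_fitted_model <- function(object, newdata, ...) {
  x <- if (inherits(newdata, "cpp_feature_matrix")) newdata$values else newdata
  if (!identical(colnames(x), object$columns))
    abort("prediction columns do not match the fitted model", "schema_error")
  if (!is.null(object$remap)) x <- apply_binary_remap(object$remap, x)
  switch(object$kind,
    svm = as.numeric(predict(object$fit, x)),
    sgd = as.numeric(x %*% object$fit$w + object$fit$b),
    knn = as.numeric(minkowski_knn(object$fit, x)),
    decision_tree = as.numeric(predict(object$fit, as.data.frame(x))),
    random_forest = ,
    extra_trees = as.numeric(predict(object$fit, as.data.frame(x),
                                     num.threads = 1)$predictions),
    gradient_boosted_trees = as.numeric(predict(object$fit,
                                                xgboost::xgb.DMatrix(x, nthread = 1))),
    deep_net = as.numeric(stack_forward(object$fit$net, x)$acts[[length(object$fit$net) + 1L]]),
    forked_net = as.numeric(forked_forward_net(object$fit$net, x)$pred))
}

#' Six-metric regression evaluation
#'
#' @param predictions,targets numeric vectors of equal length `>= 2`.
#' @return list of class `cpp_metric_set`: `rmse`, `mse`, `mae`, `pearson`,
#'   `spearman`, `r2`. Non-finite predictions (a diverged model) yield
#'   `status = "failed"` with `NA` metrics instead of an error.
#' @export
metric_set <- function(predictions, targets) {
  if (length(predictions) != length(targets) || length(targets) < 2)
    abort("need >= 2 paired values for evaluation", "domain_error")
  if (any(!is.finite(predictions))) {
    return(structure(list(rmse = NA_real_, mse = NA_real_, mae = NA_real_,
                          pearson = NA_real_, spearman = NA_real_, r2 = NA_real_,
                          status = "failed"),
                     class = "cpp_metric_set"))
  }
  err <- predictions - targets
  mse <- mean(err^2)
  structure(list(rmse = sqrt(mse), mse = mse, mae = mean(abs(err)),
                 pearson = suppressWarnings(cor(predictions, targets)),
                 spearman = suppressWarnings(cor(predictions, targets,
                                                 method = "spearman")),
                 r2 = 1 - sum(err^2) / sum((targets - mean(targets))^2),
                 status = "ok"),
            class = "cpp_metric_set")
}

#' @export
print.cpp_metric_set <- function(x, ...) {
  if (identical(x$status, "failed")) { cat("<cpp_metric_set> failed\n"); return(invisible(x)) }
  cat(sprintf("<cpp_metric_set> rmse %.3f mse %.3f mae %.3f pearson %.3f spearman %.3f r2 %.3f\n",
              x$rmse, x$mse, x$mae, x$pearson, x$spearman, x$r2))
  invisible(x)
}

#' Evaluate a fitted model on a matrix
#'
#' @param fitted a `cpp_fitted_model`.
#' @param fm normalized `cpp_feature_matrix` with target.
#' @param subset label attached to the result (`"train"` or `"test"`).
#' @return a `cpp_metric_set` with a `subset` field.
#' @export
evaluate_model <- function(fitted, fm, subset = "test") {
  m <- metric_set(predict(fitted, fm), fm$target)
  m$subset <- subset
  m
}

#' Default hyperparameter grids for the model zoo
#'
#' Exhaustive candidate lists for the seven classical models and sampling
#' ranges for the two nets, mirroring the published search space.
#'
#' @param kind model kind.
#' @return for classical kinds, a named list of candidate value vectors; for
#'   nets, a list with `ranges` (each `c(lo, hi, q)`) and `choices`.
#' @export
default_grid <- function(kind) {
  kind <- match.arg(kind, MODEL_KINDS)
  switch(kind,
    svm = list(kernel = c("linear", "poly", "rbf", "sigmoid"), C = c(0.5, 1.0, 1.5),
               gamma = c("scale", "auto")),
    sgd = list(loss = "squared_error", penalty = c("l2", "l1", "elasticnet"),
               alpha = c(0.00001, 0.0001, 0.001),
               learning_rate = c("invscaling", "optimal", "constant", "adaptive")),
    knn = list(n_neighbors = c(2, 3, 5, 7), p = c(1, 2),
               algorithm = c("auto", "ball_tree", "kd_tree", "brute")),
    decision_tree = list(splitter = c("best", "random"),
                         criterion = c("squared_error", "friedman_mse", "absolute_error"),
                         max_depth = c(3, 5, 10, 50, 100),
                         min_samples_split = c(2, 3, 5, 7, 10),
                         min_samples_leaf = c(2, 3, 5, 7, 10),
                         min_weight_fraction_leaf = c(0, 0.25, 0.5),
                         max_features = c("auto", "sqrt", "log2")),
    random_forest = list(n_estimators = c(10, 50, 100, 250),
                         criterion = c("squared_error", "friedman_mse", "absolute_error"),
                         max_depth = c(3, 5, 10, 50, 100),
                         min_samples_split = c(2, 3, 5, 7, 10),
                         min_samples_leaf = c(2, 3, 5, 7, 10),
                         min_weight_fraction_leaf = c(0, 0.25, 0.5)),
    extra_trees = list(n_estimators = c(10, 50, 100, 250),
                       criterion = c("squared_error", "friedman_mse", "absolute_error"),
                       max_depth = c(3, 5, 10, 50, 100),
                       min_samples_split = c(2, 3, 5, 7, 10),
                       min_samples_leaf = c(2, 3, 5, 7, 10),
                       min_weight_fraction_leaf = c(0, 0.25, 0.5)),
    gradient_boosted_trees = list(n_estimators = c(10, 50, 100, 250),
                                  max_depth = c(3, 5, 10, 50, 100),
                                  max_leaves = c(1, 3, 5, 10, 25),
                                  learning_rate = c(0.15, 0.3, 0.46, 0.6, 0.76, 0.9),
                                  booster = c("gbtree", "gblinear", "dart"),
                                  alpha = c(0, 1, 3, 5), lambda = c(1, 3, 5),
                                  gamma = c(0, 1, 3, 5)),
    deep_net = list(ranges = list(depth = c(1, 10, 1), layer_size = c(100, 1500, 100),
                                  dropout_rate = c(0.1, 0.9, 0.1),
                                  epochs = c(100, 1000, 10),
                                  learning_rate = c(0.00001, 0.001, 0.00001),
                                  weight_decay = c(0, 5, 0.5)),
                    choices = list(use_dropout = c(TRUE, FALSE))),
    forked_net = list(ranges = c(list(depth = c(1, 10, 1), dropout = c(0.1, 0.9, 0.1),
                                      learning_rate = c(0.00001, 0.001, 0.00001),
                                      epochs = c(100, 1000, 10),
                                      weight_decay = c(0, 5, 0.5),
                                      experimental_layer_size = c(5, 50, 1),
                                      cargo_layer_size = c(25, 250, 1),
                                      sequence_anomalies_layer_size = c(5, 200, 1),
                                      whole_peptide_layer_size = c(10, 300, 1),
                                      sequence_encoding_layer_size = c(100, 1000, 1),
                                      genomics_layer_size = c(100, 750, 1),
                                      anomalous_position_layer_size = c(5, 50, 1))),
                     choices = list(use_dropout = c(TRUE, FALSE))))
}

#' Published optimal hyperparameters for each model kind
#'
#' The tuned optima reported for the original benchmark, usable as defaults.
#'
#' @param kind model kind.
#' @return named list of hyperparameters.
#' @export
default_optima <- function(kind) {
  kind <- match.arg(kind, MODEL_KINDS)
  switch(kind,
    svm = list(kernel = "rbf", C = 1.5, gamma = "scale"),
    sgd = list(loss = "squared_error", penalty = "l2", alpha = 0.00001,
               learning_rate = "adaptive"),
    knn = list(n_neighbors = 2, p = 2, algorithm = "brute"),
    decision_tree = list(splitter = "best", criterion = "friedman_mse",
                         max_depth = 10, min_samples_split = 3,
                         min_samples_leaf = 7, min_weight_fraction_leaf = 0,
                         max_features = "auto"),
    random_forest = list(n_estimators = 50, criterion = "squared_error",
                         max_depth = 50, min_samples_split = 3,
                         min_samples_leaf = 3, min_weight_fraction_leaf = 0),
    extra_trees = list(n_estimators = 10, criterion = "friedman_mse",
                       max_depth = 100, min_samples_split = 10,
                       min_samples_leaf = 7, min_weight_fraction_leaf = 0),
    gradient_boosted_trees = list(n_estimators = 50, max_depth = 10,
                                  max_leaves = 10, booster = "dart",
                                  alpha = 1, lambda = 3, gamma = 0),
    deep_net = list(depth = 1, layer_size = 500, use_dropout = TRUE,
                    dropout_rate = 0.3, epochs = 230, learning_rate = 0.0005),
    forked_net = list(depth = 7, dropout = 0.9, use_dropout = FALSE,
                      learning_rate = 0.0001, epochs = 170,
                      experimental_layer_size = 39, cargo_layer_size = 239,
                      sequence_anomalies_layer_size = 79,
                      whole_peptide_layer_size = 155,
                      sequence_encoding_layer_size = 850,
                      genomics_layer_size = 687,
                      anomalous_position_layer_size = 45))
}

sample_net_config <- function(grid, n) {
  qsample <- function(r) {
    v <- runif(n, r[1], r[2])
    q <- if (length(r) >= 3) r[3] else 1
    pmin(r[2], pmax(r[1], round(v / q) * q))
  }
  cand <- lapply(grid$ranges, qsample)
  for (nm in names(grid$choices))
    cand[[nm]] <- sample(grid$choices[[nm]], n, replace = TRUE)
  lapply(seq_len(n), function(i) lapply(cand, `[[`, i))
}

#' Cross-validated hyperparameter search
#'
#' Exhaustive over the candidate grid for the classical models; random
#' sampling within the stated ranges (quantized) for the nets. Selection
#' criterion: mean k-fold cross-validated MSE on the training set.
#'
#' @param kind model kind.
#' @param grid for classical kinds a named list of candidate vectors (crossed
#'   exhaustively); for nets a `ranges`/`choices` spec (see
#'   [default_grid()]).
#' @param fm normalized training `cpp_feature_matrix` with target.
#' @param protocol list: `folds` (default 5), `n_candidates` for net sampling
#'   (default 10).
#' @param seed RNG seed controlling folds, sampling, and model fits.
#' @return list with `best` (a `cpp_model`), `best_mse`, and `log`
#'   (data.frame of every trial with its CV MSE).
#' @export
hyperparameter_search <- function(kind, grid = default_grid(kind), fm,
                                  protocol = list(folds = 5), seed = 1L) {
  kind <- match.arg(kind, MODEL_KINDS)
  if (!length(grid)) abort("empty hyperparameter grid", "config_error")
  folds <- protocol$folds %||% 5
  set.seed(seed)
  n <- nrow(fm$values)
  fold_id <- sample(rep_len(seq_len(folds), n))
  candidates <- if (kind %in% c("deep_net", "forked_net")) {
    sample_net_config(grid, protocol$n_candidates %||% 10L)
  } else {
    g <- expand.grid(grid, stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
    lapply(seq_len(nrow(g)), function(i) as.list(g[i, , drop = FALSE]))
  }
  cols <- colnames(fm$values)
  mses <- vapply(seq_along(candidates), function(ci) {
    cfg <- build_model(kind, candidates[[ci]], seed = derive_seed(seed, ci))
    fold_mse <- vapply(seq_len(folds), function(f) {
      tr <- fold_id != f
      sub <- function(idx) feature_matrix(fm$values[idx, , drop = FALSE], fm$schema,
                                          fm$row_ids[idx], fm$target[idx],
                                          colnames_override = cols)
      fit <- train_model(cfg, sub(which(tr)), seed = derive_seed(seed, ci))
      pred <- predict(fit, sub(which(!tr)))
      if (any(!is.finite(pred))) return(Inf)
      mean((pred - fm$target[!tr])^2)
    }, numeric(1))
    mean(fold_mse)
  }, numeric(1))
  log <- data.frame(trial = seq_along(candidates),
                    config = vapply(candidates, function(cc)
                      paste(names(cc), unlist(lapply(cc, paste, collapse = "|")),
                            sep = "=", collapse = ";"), character(1)),
                    cv_mse = mses, stringsAsFactors = FALSE)
  best_i <- which.min(mses)
  list(best = build_model(kind, candidates[[best_i]], seed = seed),
       best_mse = mses[best_i], log = log)
}

#' End-to-end prediction for new records
#'
#' Runs featurization, column pruning, normalization, and model prediction
#' using the artifacts of a completed training run. Records that fail
#' featurization are reported as structured failures; the rest proceed.
#'
#' @param artifacts list from [cmd_pipeline()]: `fitted`, `schema`, `stats`,
#'   `kept_columns`, `genomics`, `anomaly_map`, `cargo_vocab`.
#' @param records a `cpp_records` table.
#' @return data.frame with `record_id`, `predicted_log10_uptake`, `status`,
#'   `genomics_match`, `n_substitutions`, `reason`.
#' @export
predict_records <- function(artifacts, records) {
  out <- data.frame(record_id = records$record_id,
                    predicted_log10_uptake = NA_real_,
                    status = "failed", genomics_match = NA_real_,
                    n_substitutions = NA_integer_, reason = NA_character_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(records))) {
    res <- tryCatch({
      rec <- records[i, , drop = FALSE]
      v <- featurize_record(rec, artifacts$schema, artifacts$genomics,
                            artifacts$anomaly_map, artifacts$cargo_vocab)
      names(v) <- schema_colnames(artifacts$schema)
      match_flag <- unname(v["genomics.match"])
      v <- v[artifacts$kept_columns]
      x <- matrix(v, nrow = 1, dimnames = list(rec$record_id, names(v)))
      x <- sweep(x, 2, ifelse(artifacts$stats$scaled, artifacts$stats$mean, 0), "-")
      x <- sweep(x, 2, ifelse(artifacts$stats$scaled, artifacts$stats$sd, 1), "/")
      sub <- substitute_anomalies(rec$sequence, artifacts$anomaly_map)
      list(pred = predict(artifacts$fitted, x),
           match = match_flag,
           nsub = nrow(sub$annotation))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      out$reason[i] <- conditionMessage(res)
    } else {
      out$predicted_log10_uptake[i] <- res$pred
      out$status[i] <- "ok"
      out$genomics_match[i] <- res$match
      out$n_substitutions[i] <- res$nsub
    }
  }
  out
}
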