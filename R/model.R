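# Random-forest classifier: published hyperparameter search ranges, stratified
# k-fold cross-validation, grid search, final fit and prediction. The forest
# engine is ranger with Gini splits; scores are fractions of trees voting
# for the promoter class.

#' Stratified cross-validation plan
#'
#' Assigns every sample to one of `k` folds, stratified per class so fold
#' sizes within a class differ by at most one. Deterministic given `seed`.
#'
#' @param features Labeled feature tibble (or any tibble with `sample_id`
#'   and `label`).
#' @param k Number of folds (default 5).
#' @param seed Integer seed.
#' @return A `cv_plan` tibble with columns `sample_id`, `label`, `fold`.
#' @export
make_cv_plan <- function(features, k = 5, seed = 1) {
  if (!is.data.frame(features) || !all(c("sample_id", "label") %in% names(features))) {
    abort("`features` must have `sample_id` and `label` columns.")
  }
  if (k < 2L) abort("`k` must be at least 2.")
  y <- features$label
  if (!all(y %in% c(0L, 1L))) abort("Labels must be 0 or 1.")
  if (min(table(y)) < k) abort("Each class needs at least `k` samples.")

  fold <- integer(length(y))
  withr::with_seed(seed, {
    for (cls in unique(y)) {
      i <- which(y == cls)
      fold[sample(i)] <- rep_len(seq_len(k), length(i))
    }
  })
  out <- tibble(sample_id = features$sample_id, label = as.integer(y), fold = fold)
  attr(out, "k") <- as.integer(k)
  attr(out, "seed") <- seed
  class(out) <- c("cv_plan", class(out))
  out
}

#' Random-forest hyperparameter grid
#'
#' Full factorial grid over the five tuned hyperparameters. The defaults are
#' the published search ranges — trees 80 to 150 in steps of 5, depth 15 to
#' 20, minimum leaf size 1 to 8, minimum split size 2 to 5, and the fraction
#' of features tried per split 0.1 to 1 in steps of 0.1 — giving
#' 15 x 6 x 8 x 4 x 10 = 28,800 combinations.
#'
#' @param n_estimators Numbers of trees.
#' @param max_depth Maximum tree depths.
#' @param min_samples_leaf Minimum samples in a terminal node.
#' @param min_samples_split Minimum samples required to split a node.
#' @param max_features Fractions of the feature count tried at each split
#'   (`mtry = ceiling(fraction * d)`).
#' @return Tibble with one row per hyperparameter combination.
#' @examples
#' nrow(rf_param_grid()) # 28800
#' @export
rf_param_grid <- function(n_estimators = seq(80L, 150L, by = 5L),
                          max_depth = 15:20,
                          min_samples_leaf = 1:8,
                          min_samples_split = 2:5,
                          max_features = seq(0.1, 1, by = 0.1)) {
  stopifnot(all(max_features > 0), all(max_features <= 1))
  tidyr::expand_grid(
    n_estimators = as.integer(n_estimators),
    max_depth = as.integer(max_depth),
    min_samples_leaf = as.integer(min_samples_leaf),
    min_samples_split = as.integer(min_samples_split),
    max_features = max_features
  )
}

check_params <- function(params) {
  need <- c("n_estimators", "max_depth", "min_samples_leaf",
            "min_samples_split", "max_features")
  if (!is.data.frame(params)) params <- as_tibble(as.list(params))
  if (!all(need %in% names(params)) || nrow(params) != 1L) {
    abort(paste0("`params` must be one row with columns: ", paste(need, collapse = ", ")))
  }
  full <- rf_param_grid()
  for (nm in need) {
    domain <- unique(full[[nm]])
    ok <- if (nm == "max_features") {
      any(abs(params[[nm]] - domain) < 1e-9) # grid steps of 0.1 accumulate fp error
    } else {
      params[[nm]] %in% domain
    }
    if (!ok) {
      abort(paste0("`", nm, "` = ", params[[nm]], " is outside the search domain."))
    }
  }
  params[, need]
}

# Fit one Gini forest on a plain feature matrix
fit_forest <- function(x, y, params, seed) {
  ranger::ranger(
    x = as.data.frame(x), y = factor(y, levels = c(0L, 1L)),
    num.trees = params$n_estimators,
    max.depth = params$max_depth,
    min.bucket = params$min_samples_leaf,
    min.node.size = params$min_samples_split,
    mtry = min(ncol(x), ceiling(params$max_features * ncol(x))),
    splitrule = "gini",
    importance = "impurity",
    seed = seed,
    num.threads = 1L
  )
}

# Fraction of trees voting class 1, per sample
forest_score <- function(fit, x) {
  pred <- predict(fit, as.data.frame(x), predict.all = TRUE, num.threads = 1L)
  idx1 <- which(fit$forest$levels == "1")
  rowMeans(pred$predictions == idx1)
}

objective_value <- function(objective, truth, score) {
  pred <- as.integer(score >= 0.5)
  switch(objective,
    accuracy = mean(pred == truth),
    mcc = suppressMessages(classification_metrics(confusion_counts(truth, pred))$mcc),
    auc = auc(roc_curve(truth, score))
  )
}

#' Grid search over forest hyperparameters by cross-validation
#'
#' Evaluates every grid row by k-fold cross-validation under `plan` (train
#' on k - 1 folds, score the held-out fold) and returns the combination with
#' the best mean objective. Exact ties are broken deterministically in
#' favour of fewer trees, then shallower depth, then lexicographically on
#' the remaining hyperparameters.
#'
#' @param features Labeled feature tibble.
#' @param grid Hyperparameter grid (default [rf_param_grid()]; pass a subset
#'   for desk-scale runs).
#' @param plan A `cv_plan` over the same samples ([make_cv_plan()]).
#' @param objective `"accuracy"` (default), `"mcc"` or `"auc"`.
#' @param seed Seed for the per-fold forest fits.
#' @return An `rf_grid_search`: list with `best` (one-row params tibble),
#'   `results` (grid plus `mean_objective` and per-fold values), `objective`.
#' @export
grid_search <- function(features, grid = rf_param_grid(), plan,
                        objective = c("accuracy", "mcc", "auc"), seed = 1) {
  objective <- match.arg(objective)
  check_feature_tbl(features, require_label = TRUE)
  stopifnot(inherits(plan, "cv_plan"))
  if (!identical(plan$sample_id, features$sample_id)) {
    abort("`plan` was built for different samples than `features`.")
  }
  if (!is.data.frame(grid) || nrow(grid) == 0L) abort("`grid` must be a non-empty grid.")

  x <- feature_values(features)
  y <- features$label
  k <- attr(plan, "k")
  folds <- lapply(seq_len(k), function(f) which(plan$fold == f))

  fold_objective <- function(params, holdout) {
    truth <- y[holdout]
    if (length(unique(truth)) < 2L && objective != "accuracy") {
      warn("Skipping a single-class fold in grid search.")
      return(NA_real_)
    }
    fit <- fit_forest(x[-holdout, , drop = FALSE], y[-holdout], params, seed)
    objective_value(objective, truth, forest_score(fit, x[holdout, , drop = FALSE]))
  }

  per_combo <- purrr::map_dbl(seq_len(nrow(grid)), function(i) {
    params <- check_params(grid[i, ])
    mean(purrr::map_dbl(folds, fold_objective, params = params), na.rm = TRUE)
  })

  results <- dplyr::mutate(as_tibble(grid), mean_objective = per_combo)
  ranked <- dplyr::arrange(
    results, dplyr::desc(.data$mean_objective), .data$n_estimators,
    .data$max_depth, .data$min_samples_leaf, .data$min_samples_split,
    .data$max_features
  )
  out <- list(
    best = ranked[1L, setdiff(names(ranked), "mean_objective")],
    best_objective = ranked$mean_objective[1L],
    results = results,
    objective = objective,
    seed = seed
  )
  class(out) <- "rf_grid_search"
  out
}

#' @export
print.rf_grid_search <- function(x, ...) {
  cat("<rf_grid_search> ", nrow(x$results), " combination(s); best mean ",
      x$objective, " = ", sprintf("%.4f", x$best_objective), "\n", sep = "")
  print(x$best)
  invisible(x)
}

#' Train the final random forest
#'
#' Fits a Gini-split forest with the chosen hyperparameters on the full
#' training matrix.
#'
#' @param features Labeled feature tibble.
#' @param params One-row tibble (or named list) of hyperparameters within
#'   the search domain, e.g. `grid_search(...)$best`.
#' @param seed Forest seed.
#' @return A `promforest_model`: the fitted forest plus hyperparameters,
#'   training feature ids and seeds.
#' @export
train_rf <- function(features, params, seed = 1) {
  check_feature_tbl(features, require_label = TRUE)
  params <- check_params(params)
  x <- feature_values(features)
  fit <- fit_forest(x, features$label, params, seed)
  out <- list(
    fit = fit,
    params = params,
    feature_ids = colnames(x),
    n_train = nrow(x),
    class_counts = table(factor(features$label, levels = c(0L, 1L))),
    seed = seed
  )
  class(out) <- "promforest_model"
  out
}

#' @export
print.promforest_model <- function(x, ...) {
  cat("<promforest_model> Gini random forest: ", x$params$n_estimators,
      " trees, depth <= ", x$params$max_depth, ", ", length(x$feature_ids),
      " features, ", x$n_train, " training samples\n", sep = "")
  invisible(x)
}

#' Predict promoter scores and labels
#'
#' The score of a sample is the fraction of trees voting for the promoter
#' class; the predicted label is 1 when the score is at least 0.5. Feature
#' columns are realigned to the training order by name; missing or unknown
#' feature columns are an error.
#'
#' @param object A `promforest_model`.
#' @param newdata Feature tibble with the training feature columns (any
#'   order).
#' @param ... Unused.
#' @return Tibble with `sample_id`, `score`, `pred` (and `label` if present
#'   in `newdata`).
#' @export
predict.promforest_model <- function(object, newdata, ...) {
  check_feature_tbl(newdata, require_label = FALSE)
  ids <- feature_ids(newdata)
  missing <- setdiff(object$feature_ids, ids)
  extra <- setdiff(ids, object$feature_ids)
  if (length(missing) > 0L || length(extra) > 0L) {
    abort(paste0(
      "Feature mismatch with the trained model (",
      length(missing), " missing, ", length(extra), " unknown columns)."
    ))
  }
  x <- feature_values(newdata)[, object$feature_ids, drop = FALSE]
  score <- forest_score(object$fit, x)
  out <- tibble(
    sample_id = newdata$sample_id,
    score = score,
    pred = as.integer(score >= 0.5)
  )
  if ("label" %in% names(newdata)) out$label <- as.integer(newdata$label)
  out
}

#' Save / load a trained model with a JSON sidecar
#'
#' The model is serialized with `saveRDS`; a JSON sidecar next to it records
#' the hyperparameters, seeds and a hash of the training feature ids.
#' Loading verifies the sidecar hash so a model cannot be silently applied
#' with the wrong feature layout.
#'
#' @param model A `promforest_model`.
#' @param path Model path (`.rds`); the sidecar is written to
#'   `<path>.json`.
#' @return `path` invisibly (`save_model`); a `promforest_model`
#'   (`load_model`).
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "promforest_model"))
  saveRDS(model, path)
  jsonlite::write_json(
    list(
      package = "promforest",
      params = model$params,
      seed = model$seed,
      n_features = length(model$feature_ids),
      feature_hash = feature_hash(model$feature_ids)
    ),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "promforest_model"))
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (!identical(meta$feature_hash, feature_hash(model$feature_ids))) {
      abort("Model sidecar hash does not match the serialized model.")
    }
  }
  model
}

# order-sensitive polynomial rolling hash of the feature id vector
feature_hash <- function(ids) {
  h <- 0
  for (b in utf8ToInt(paste(ids, collapse = "\x1f"))) {
    h <- (h * 31 + b) %% 2147483647
  }
  sprintf("%08x", h)
}
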