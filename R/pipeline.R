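# End-to-end convenience wrapper: split -> encode -> select -> grid search
# -> final fit -> cross-validated and independent-set evaluation.

#' Run the full promoter-prediction pipeline
#'
#' Splits a labeled sequence set into training and independent parts,
#' encodes both with the positional dinucleotide statistics of `props`,
#' selects features on the training matrix (ANOVA F + first-level
#' clustering), grid-searches the forest hyperparameters under stratified
#' k-fold cross-validation, fits the final forest, and evaluates it on the
#' folds and on the held-out independent set.
#'
#' @param seqs Labeled sequence tibble (`id`, `seq`, `label`), one length.
#' @param props A `property_tbl` of dinucleotide physicochemical properties.
#' @param split_ratio Training fraction (default 0.8).
#' @param k Cross-validation folds (default 5).
#' @param grid Hyperparameter grid (default [rf_param_grid()]; pass a
#'   subset for desk-scale runs).
#' @param objective Grid-search objective (`"accuracy"`, `"mcc"`, `"auc"`).
#' @param linkage,metric,scale_features Clustering options, see
#'   [first_level_pairs()].
#' @param standardize,variance Encoder options, see [dinuc_stats()].
#' @param seed Master seed; the split, folds, tie-breaks and forests derive
#'   deterministic sub-seeds from it.
#' @return A `promforest_run`: list with `split`, `stats_map`, `selection`,
#'   `search`, `model`, `cv`, `test_metrics`, `test_roc`, `config`.
#' @examples
#' \donttest{
#' seqs <- simulate_promoter_dataset(n_pos = 60, n_neg = 60, seed = 1)
#' props <- simulate_property_table(K = 30, seed = 2)
#' run <- run_promoter_pipeline(seqs, props,
#'   grid = rf_param_grid(100, 16, 2, 2, 0.3), seed = 7)
#' glance(run)
#' }
#' @export
run_promoter_pipeline <- function(seqs, props, split_ratio = 0.8, k = 5,
                                  grid = rf_param_grid(),
                                  objective = "accuracy",
                                  linkage = "ward", metric = "euclidean",
                                  scale_features = TRUE,
                                  standardize = FALSE,
                                  variance = "population", seed = 1) {
  seeds <- derive_seeds(seed)
  split <- split_dataset(seqs, ratio = split_ratio, seed = seeds["split"])
  stats_map <- dinuc_stats(props, standardize = standardize, variance = variance)

  train_full <- encode_dataset(split$train, stats_map)
  test_full <- encode_dataset(split$test, stats_map)

  selection <- select_feature_subset(train_full,
    linkage = linkage, metric = metric,
    scale_features = scale_features, seed = seeds["tie"]
  )
  train <- apply_selection(train_full, selection)
  test <- apply_selection(test_full, selection)

  plan <- make_cv_plan(train, k = k, seed = seeds["cv"])
  search <- grid_search(train, grid = grid, plan = plan,
                        objective = objective, seed = seeds["forest"])
  model <- train_rf(train, search$best, seed = seeds["forest"])
  cv <- cross_validated_report(train, search$best, plan, seed = seeds["forest"])

  preds <- predict(model, test)
  test_metrics <- classification_metrics(confusion_counts(preds$label, preds$pred))
  test_roc <- roc_curve(preds$label, preds$score)
  test_metrics$auc <- auc(test_roc)

  out <- list(
    split = split,
    stats_map = stats_map,
    selection = selection,
    search = search,
    model = model,
    cv = cv,
    test_metrics = test_metrics,
    test_roc = test_roc,
    config = list(
      split_ratio = split_ratio, k = k, objective = objective,
      linkage = linkage, metric = metric, scale_features = scale_features,
      standardize = standardize, variance = variance, seed = seed,
      derived_seeds = as.list(seeds)
    )
  )
  class(out) <- "promforest_run"
  out
}

# fixed offsets keep every random stage independently reproducible
derive_seeds <- function(seed) {
  base <- as.integer(seed) %% 1000000L
  c(split = base + 11L, tie = base + 23L, cv = base + 37L, forest = base + 53L)
}

#' @export
print.promforest_run <- function(x, ...) {
  cat("<promforest_run> seed ", x$config$seed, "\n", sep = "")
  cat("  features: ", length(x$selection$feature_ids), " -> ",
      length(x$selection$retained), " retained\n", sep = "")
  cat("  best params: ", paste(names(x$search$best), unlist(x$search$best),
                               sep = "=", collapse = ", "), "\n", sep = "")
  cat("  CV mean (percent):\n")
  print(metrics_percent(x$cv$summary))
  cat("  independent set (percent):\n")
  print(metrics_percent(x$test_metrics))
  invisible(x)
}
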