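# broom-style tidy()/glance() methods for the fitted objects.

#' Tidy a feature selection
#'
#' One row per feature with its F value, pair membership and fate.
#'
#' @param x A `feature_selection` from [select_features()].
#' @param ... Unused.
#' @return Tibble with columns `feature`, `f_value`, `pair`, `status`.
#' @exportS3Method generics::tidy
tidy.feature_selection <- function(x, ...) {
  d <- length(x$feature_ids)
  pair <- rep(NA_integer_, d)
  if (nrow(x$decisions) > 0L) {
    pair[x$decisions$j] <- seq_len(nrow(x$decisions))
    pair[x$decisions$k] <- seq_len(nrow(x$decisions))
  }
  tibble(
    feature = x$feature_ids,
    f_value = x$f_values,
    pair = pair,
    status = ifelse(seq_len(d) %in% x$retained, "retained", "removed")
  )
}

#' @rdname tidy.feature_selection
#' @exportS3Method generics::glance
glance.feature_selection <- function(x, ...) {
  tibble(
    n_features = length(x$feature_ids),
    n_pairs = nrow(x$decisions),
    n_singletons = length(x$feature_ids) - 2L * nrow(x$decisions),
    n_retained = length(x$retained),
    n_ties = sum(x$decisions$tie_broken),
    linkage = x$config$linkage,
    metric = x$config$metric,
    scaled = x$config$scale_features,
    seed = x$seed
  )
}

#' Tidy a trained forest
#'
#' One row per feature with its Gini impurity importance.
#'
#' @param x A `promforest_model` from [train_rf()].
#' @param ... Unused.
#' @return Tibble with columns `feature`, `importance`, sorted decreasing.
#' @exportS3Method generics::tidy
tidy.promforest_model <- function(x, ...) {
  imp <- ranger::importance(x$fit)
  dplyr::arrange(
    tibble(feature = names(imp), importance = unname(imp)),
    dplyr::desc(.data$importance)
  )
}

#' @rdname tidy.promforest_model
#' @exportS3Method generics::glance
glance.promforest_model <- function(x, ...) {
  dplyr::bind_cols(
    x$params,
    tibble(
      n_features = length(x$feature_ids),
      n_train = x$n_train,
      oob_error = x$fit$prediction.error,
      seed = x$seed
    )
  )
}

#' Tidy a cross-validation report
#'
#' Fold rows plus the mean row, metrics as fractions.
#'
#' @param x A `cv_report` from [cross_validated_report()].
#' @param ... Unused.
#' @return Tibble with columns `fold`, `sn`, `sp`, `acc`, `mcc`, `auc`.
#' @exportS3Method generics::tidy
tidy.cv_report <- function(x, ...) {
  dplyr::bind_rows(
    x$folds[, c("fold", "sn", "sp", "acc", "mcc", "auc")],
    x$summary
  )
}

#' @rdname tidy.cv_report
#' @exportS3Method generics::glance
glance.cv_report <- function(x, ...) {
  dplyr::bind_cols(
    x$summary[, c("sn", "sp", "acc", "mcc", "auc")],
    tibble(pooled_auc = x$pooled_auc, k = x$k, seed = x$seed)
  )
}

#' Tidy a grid search
#'
#' @param x An `rf_grid_search` from [grid_search()].
#' @param ... Unused.
#' @return The per-combination results tibble, best first.
#' @exportS3Method generics::tidy
tidy.rf_grid_search <- function(x, ...) {
  dplyr::arrange(x$results, dplyr::desc(.data$mean_objective))
}

#' @rdname tidy.rf_grid_search
#' @exportS3Method generics::glance
glance.rf_grid_search <- function(x, ...) {
  dplyr::bind_cols(
    x$best,
    tibble(
      mean_objective = x$best_objective,
      objective = x$objective,
      n_combinations = nrow(x$results)
    )
  )
}

#' Glance at a full pipeline run
#'
#' Headline numbers of a [run_promoter_pipeline()] result: mean CV metrics
#' and independent-set metrics, as fractions.
#'
#' @param x A `promforest_run`.
#' @param ... Unused.
#' @return One-row tibble: `cv_*` and `test_*` metric columns plus feature
#'   bookkeeping.
#' @exportS3Method generics::glance
glance.promforest_run <- function(x, ...) {
  cv <- x$cv$summary[, c("sn", "sp", "acc", "mcc", "auc")]
  names(cv) <- paste0("cv_", names(cv))
  test <- x$test_metrics[, c("sn", "sp", "acc", "mcc", "auc")]
  names(test) <- paste0("test_", names(test))
  dplyr::bind_cols(
    cv, test,
    tibble(
      n_features = length(x$selection$feature_ids),
      n_retained = length(x$selection$retained),
      seed = x$config$seed
    )
  )
}
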