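# Binary-classifier evaluation: confusion counts, Sn/Sp/Acc/MCC, ROC/AUC
# and the five-fold cross-validation report.

#' Confusion counts of binary predictions
#'
#' TP and FN count the true promoters (label 1) predicted 1 and 0; TN and FP
#' count the true non-promoters predicted 0 and 1.
#'
#' @param truth Vector of true labels (0/1).
#' @param predicted Vector of predicted labels (0/1), same length.
#' @return One-row tibble with columns `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_counts <- function(truth, predicted) {
  if (length(truth) != length(predicted)) abort("`truth` and `predicted` differ in length.")
  if (!all(truth %in% c(0L, 1L)) || !all(predicted %in% c(0L, 1L))) {
    abort("Labels and predictions must be 0 or 1.")
  }
  tibble(
    tp = sum(truth == 1L & predicted == 1L),
    fp = sum(truth == 0L & predicted == 1L),
    tn = sum(truth == 0L & predicted == 0L),
    fn = sum(truth == 1L & predicted == 0L)
  )
}

#' Sensitivity, specificity, accuracy and MCC from confusion counts
#'
#' Sn = TP/(TP+FN), Sp = TN/(TN+FP), Acc = (TP+TN)/n and
#' MCC = (TP*TN - FP*FN) / sqrt((TP+FN)(TN+FP)(TP+FP)(TN+FN)). MCC is
#' defined as 0 (with a message) when any denominator factor is zero. All
#' values are returned as fractions; see [metrics_percent()] for the
#' two-decimal percentage style used in reports.
#'
#' @param counts One-row tibble or named vector/list with `tp`, `fp`, `tn`,
#'   `fn` (nonnegative).
#' @return A `metric_set` tibble: `tp`, `fp`, `tn`, `fn`, `sn`, `sp`, `acc`,
#'   `mcc`.
#' @examples
#' classification_metrics(c(tp = 181, fp = 26, tn = 174, fn = 19))
#' @export
classification_metrics <- function(counts) {
  counts <- as.list(counts)
  need <- c("tp", "fp", "tn", "fn")
  if (!all(need %in% names(counts))) {
    abort("`counts` must provide tp, fp, tn and fn.")
  }
  tp <- as.numeric(counts$tp); fp <- as.numeric(counts$fp)
  tn <- as.numeric(counts$tn); fn <- as.numeric(counts$fn)
  if (any(c(tp, fp, tn, fn) < 0)) abort("Confusion counts must be nonnegative.")
  n <- tp + fp + tn + fn
  if (n == 0) abort("All confusion counts are zero.")
  if (tp + fn == 0 || tn + fp == 0) {
    abort("Sn/Sp need at least one positive and one negative sample.")
  }
  denom_factors <- c(tp + fn, tn + fp, tp + fp, tn + fn)
  mcc <- if (any(denom_factors == 0)) {
    inform("MCC set to 0: a confusion-matrix margin is zero.")
    0
  } else {
    (tp * tn - fp * fn) / sqrt(prod(denom_factors))
  }
  out <- tibble(
    tp = tp, fp = fp, tn = tn, fn = fn,
    sn = tp / (tp + fn),
    sp = tn / (tn + fp),
    acc = (tp + tn) / n,
    mcc = mcc
  )
  class(out) <- c("metric_set", class(out))
  out
}

#' Metrics as two-decimal percentages
#'
#' Formats a metric set in the percentage style of promoter-prediction
#' reports (e.g. Sn 90.50, Sp 87.00, Acc 88.75, MCC 77.55); MCC is scaled to
#' a percentage like the other metrics.
#'
#' @param metrics A `metric_set` from [classification_metrics()] (extra
#'   columns such as `auc` are formatted too when present).
#' @return Tibble of character columns, each value formatted `%.2f`.
#' @export
metrics_percent <- function(metrics) {
  cols <- intersect(c("sn", "sp", "acc", "mcc", "auc"), names(metrics))
  dplyr::mutate(
    metrics[, cols, drop = FALSE],
    dplyr::across(dplyr::everything(), ~ sprintf("%.2f", 100 * .x))
  )
}

#' ROC curve and AUC from scores
#'
#' Sweeps a decision threshold across the unique scores (classifying
#' `score >= threshold` as promoter) and records one (FPR, TPR) point per
#' threshold plus the (0,0) endpoint. Tied scores move the curve diagonally,
#' so the trapezoidal AUC equals the probabilistic
#' P(score_pos > score_neg) + 0.5 P(equal).
#'
#' @param truth True labels (0/1), both classes present.
#' @param scores Numeric scores, higher meaning more promoter-like.
#' @return A `roc_curve` tibble with columns `threshold`, `fpr`, `tpr`
#'   (monotone nondecreasing, from (0,0) to (1,1)) and attribute `auc`.
#' @export
roc_curve <- function(truth, scores) {
  if (length(truth) != length(scores)) abort("`truth` and `scores` differ in length.")
  if (!all(truth %in% c(0L, 1L))) abort("Labels must be 0 or 1.")
  if (length(unique(truth)) < 2L) abort("ROC needs both classes present.")
  if (any(!is.finite(scores))) abort("Scores must be finite.")

  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- truth[ord]
  n_pos <- sum(truth == 1L)
  n_neg <- sum(truth == 0L)
  last <- !duplicated(s, fromLast = TRUE) # last index of each tied block
  out <- tibble(
    threshold = c(Inf, s[last]),
    fpr = c(0, cumsum(y == 0L)[last] / n_neg),
    tpr = c(0, cumsum(y == 1L)[last] / n_pos)
  )
  attr(out, "auc") <- sum(diff(out$fpr) * (head(out$tpr, -1) + out$tpr[-1]) / 2)
  class(out) <- c("roc_curve", class(out))
  out
}

#' Area under a ROC curve
#'
#' @param roc A `roc_curve` from [roc_curve()].
#' @return AUC in `[0, 1]` (trapezoidal rule).
#' @export
auc <- function(roc) {
  stopifnot(inherits(roc, "roc_curve"))
  attr(roc, "auc")
}

#' Cross-validated performance report
#'
#' Refits the forest on each train split of `plan`, scores the held-out
#' fold, and reports one metric row per fold (Sn, Sp, Acc, MCC, AUC), an
#' arithmetic mean-of-folds row, and the ROC over the pooled held-out
#' scores.
#'
#' @param features Labeled feature tibble.
#' @param params One-row hyperparameter tibble (within the search domain).
#' @param plan A `cv_plan` over the same samples.
#' @param seed Forest seed shared across fold refits.
#' @return A `cv_report`: list with `folds` (tibble, one row per fold),
#'   `summary` (the mean row), `pooled_roc`, `pooled_auc`, `params`, `seed`.
#' @export
cross_validated_report <- function(features, params, plan, seed = 1) {
  check_feature_tbl(features, require_label = TRUE)
  stopifnot(inherits(plan, "cv_plan"))
  if (!identical(plan$sample_id, features$sample_id)) {
    abort("`plan` was built for different samples than `features`.")
  }
  params <- check_params(params)
  x <- feature_values(features)
  y <- features$label
  k <- attr(plan, "k")

  fold_rows <- vector("list", k)
  pooled <- list(truth = integer(0), score = numeric(0))
  for (f in seq_len(k)) {
    holdout <- which(plan$fold == f)
    truth <- y[holdout]
    if (length(unique(truth)) < 2L) abort(paste0("Fold ", f, " contains a single class."))
    fit <- fit_forest(x[-holdout, , drop = FALSE], y[-holdout], params, seed)
    score <- forest_score(fit, x[holdout, , drop = FALSE])
    m <- classification_metrics(confusion_counts(truth, as.integer(score >= 0.5)))
    m$auc <- auc(roc_curve(truth, score))
    fold_rows[[f]] <- dplyr::bind_cols(tibble(fold = as.character(f)), m)
    pooled$truth <- c(pooled$truth, truth)
    pooled$score <- c(pooled$score, score)
  }
  folds <- dplyr::bind_rows(fold_rows)
  metric_cols <- c("sn", "sp", "acc", "mcc", "auc")
  summary <- dplyr::bind_cols(
    tibble(fold = "mean"),
    dplyr::summarise(folds, dplyr::across(dplyr::all_of(metric_cols), mean))
  )
  pooled_roc <- roc_curve(pooled$truth, pooled$score)
  out <- list(
    folds = folds,
    summary = summary,
    pooled_roc = pooled_roc,
    pooled_auc = auc(pooled_roc),
    params = params,
    k = k,
    seed = seed
  )
  class(out) <- "cv_report"
  out
}

#' @export
print.cv_report <- function(x, ...) {
  cat("<cv_report> ", x$k, "-fold cross-validation (percent):\n", sep = "")
  shown <- dplyr::bind_rows(
    x$folds[, c("fold", "sn", "sp", "acc", "mcc", "auc")],
    x$summary
  )
  print(dplyr::bind_cols(shown["fold"], metrics_percent(shown)), n = Inf)
  cat("pooled AUC: ", sprintf("%.4f", x$pooled_auc), "\n", sep = "")
  invisible(x)
}

#' Write a cross-validation report as TSV
#'
#' One row per fold plus the mean row, with Sn/Sp/Acc/MCC as two-decimal
#' percentages and AUC as a fraction; ROC points go to a companion CSV for
#' external plotting.
#'
#' @param report A `cv_report`.
#' @param path Output TSV path; ROC points are written to `<path>.roc.csv`.
#' @return `path`, invisibly.
#' @export
write_cv_report <- function(report, path) {
  stopifnot(inherits(report, "cv_report"))
  rows <- dplyr::bind_rows(
    report$folds[, c("fold", "sn", "sp", "acc", "mcc", "auc")],
    report$summary
  )
  out <- dplyr::bind_cols(
    rows["fold"],
    metrics_percent(rows[, c("sn", "sp", "acc", "mcc")]),
    tibble(auc = sprintf("%.4f", rows$auc))
  )
  readr::write_tsv(out, path, progress = FALSE)
  readr::write_csv(as_tibble(report$pooled_roc), paste0(path, ".roc.csv"),
                   progress = FALSE)
  invisible(path)
}
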