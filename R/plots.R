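# ggplot2 autoplot methods for the main result types.

#' Plot a ROC curve
#'
#' @param object A `roc_curve` from [roc_curve()].
#' @param ... Unused.
#' @return A ggplot object: the ROC with the chance diagonal and the AUC in
#'   the subtitle.
#' @exportS3Method ggplot2::autoplot
autoplot.roc_curve <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object), ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(linewidth = 0.8, colour = "#2166ac") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "False positive rate (1 - Sp)", y = "True positive rate (Sn)",
      title = "ROC curve",
      subtitle = sprintf("AUC = %.4f", attr(object, "auc"))
    ) +
    ggplot2::theme_minimal()
}

#' Plot a feature selection
#'
#' F value per feature, coloured by fate; members of a first-level pair
#' share a connecting line, singletons are diamonds.
#'
#' @param object A `feature_selection` from [select_features()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.feature_selection <- function(object, ...) {
  td <- tidy(object)
  td$index <- seq_len(nrow(td))
  paired <- td[!is.na(td$pair), , drop = FALSE]
  p <- ggplot2::ggplot(td, ggplot2::aes(x = .data$index, y = .data$f_value))
  if (nrow(paired) > 0L) {
    p <- p + ggplot2::geom_line(
      data = paired,
      ggplot2::aes(group = .data$pair),
      colour = "grey70", linetype = "dotted"
    )
  }
  p +
    ggplot2::geom_point(
      ggplot2::aes(colour = .data$status, shape = is.na(.data$pair)),
      size = 2
    ) +
    ggplot2::scale_colour_manual(
      values = c(retained = "#2166ac", removed = "#b2182b"), name = NULL
    ) +
    ggplot2::scale_shape_manual(
      values = c(`TRUE` = 18, `FALSE` = 16), guide = "none"
    ) +
    ggplot2::labs(
      x = "Feature index", y = "ANOVA F value",
      title = "ANOVA + first-level clustering feature selection",
      subtitle = sprintf(
        "%d features: %d pairs, %d singletons, %d retained",
        nrow(td), nrow(object$decisions),
        nrow(td) - 2L * nrow(object$decisions), length(object$retained)
      )
    ) +
    ggplot2::theme_minimal()
}

#' Plot a cross-validation report
#'
#' Per-fold Sn/Sp/Acc/MCC/AUC with the mean as a horizontal reference.
#'
#' @param object A `cv_report` from [cross_validated_report()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.cv_report <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object$folds[, c("fold", "sn", "sp", "acc", "mcc", "auc")],
    -"fold", names_to = "metric", values_to = "value"
  )
  mean_long <- tidyr::pivot_longer(
    object$summary, -"fold", names_to = "metric", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$fold, y = .data$value)) +
    ggplot2::geom_col(fill = "#2166ac", width = 0.7) +
    ggplot2::geom_hline(
      data = mean_long, ggplot2::aes(yintercept = .data$value),
      linetype = "dashed", colour = "#b2182b"
    ) +
    ggplot2::facet_wrap(~metric, nrow = 1) +
    ggplot2::labs(x = "Fold", y = "Value (fraction)",
                  title = "Cross-validated performance by fold") +
    ggplot2::theme_minimal()
}
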