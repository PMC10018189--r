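# Redundancy-aware feature selection: score each feature with a two-group
# one-way ANOVA F value, pair features by first-level agglomerative
# clustering, and keep the higher-F member of each pair plus all singletons.

#' One-way ANOVA F value of every feature
#'
#' For each feature column, computes the classical two-group one-way ANOVA
#' F statistic F = MS_between / MS_within with degrees of freedom (1, n - 2).
#' Degenerate features are handled explicitly: if both mean squares are zero
#' (feature constant everywhere) F is 0 with a warning; if only the
#' within-group mean square is zero (classes perfectly separated with no
#' scatter) F is `Inf`, which outranks every finite value in selection.
#'
#' @param features Labeled feature tibble (`sample_id`, `label`, features).
#' @return An `anova_f` tibble with columns `feature`, `f_value`,
#'   `ms_between`, `ms_within`.
#' @export
anova_f <- function(features) {
  check_feature_tbl(features, require_label = TRUE)
  y <- features$label
  if (length(unique(y)) < 2L) abort("Both classes must be present to compute F values.")
  n <- length(y)
  if (n < 4L) abort("Need at least 4 samples (>= 2 per class).")
  if (min(table(y)) < 2L) abort("Each class needs at least 2 samples.")

  x <- feature_values(features)
  n0 <- sum(y == 0L)
  n1 <- sum(y == 1L)
  m0 <- colMeans(x[y == 0L, , drop = FALSE])
  m1 <- colMeans(x[y == 1L, , drop = FALSE])
  m <- colMeans(x)
  ss_between <- n0 * (m0 - m)^2 + n1 * (m1 - m)^2
  ss_within <- colSums(sweep(x[y == 0L, , drop = FALSE], 2L, m0)^2) +
    colSums(sweep(x[y == 1L, , drop = FALSE], 2L, m1)^2)
  ms_between <- ss_between # df = 1
  ms_within <- ss_within / (n - 2L)

  # relative zero threshold: constant columns hit exact-arithmetic noise
  scale <- pmax(colMeans(x^2), .Machine$double.xmin)
  zero_w <- ms_within <= 1e-12 * scale
  zero_b <- ms_between <= 1e-12 * scale
  f <- ms_between / ms_within
  f[zero_w & zero_b] <- 0
  f[zero_w & !zero_b] <- Inf
  if (any(zero_w & zero_b)) {
    warn(paste0(
      "F set to 0 for ", sum(zero_w & zero_b),
      " feature(s) constant across all samples."
    ))
  }
  out <- tibble(
    feature = colnames(x),
    f_value = unname(f),
    ms_between = unname(ms_between),
    ms_within = unname(ms_within)
  )
  class(out) <- c("anova_f", class(out))
  out
}

LINKAGE_METHODS <- c(ward = "ward.D2", complete = "complete",
                     average = "average", single = "single")

#' First-level pairs from agglomerative clustering of features
#'
#' Clusters the feature columns (the transposed sample matrix) with
#' agglomerative hierarchical clustering and extracts the FIRST-LEVEL PAIRS:
#' merges whose two children are both original features. Every feature not in
#' such a merge is a singleton, so pairs and singletons always partition the
#' feature set.
#'
#' @param features Feature tibble (labels optional; only the feature columns
#'   are clustered).
#' @param linkage One of `"ward"` (default), `"complete"`, `"average"`,
#'   `"single"`.
#' @param metric `"euclidean"` (default) or `"correlation"` (distance
#'   1 - Pearson r between feature columns).
#' @param scale_features Z-score each feature across samples before
#'   computing distances (default `TRUE`): the five statistics live on very
#'   different scales (sums are ~K times means), so unscaled Euclidean
#'   distance would be dominated by the sum features. Constant features are
#'   centred only.
#' @return A `feature_pairing`: list with `pairs` (tibble `j`, `k`, `height`,
#'   j < k as column indices), `singletons` (integer vector), `feature_ids`,
#'   and `config`.
#' @export
first_level_pairs <- function(features, linkage = "ward",
                              metric = c("euclidean", "correlation"),
                              scale_features = TRUE) {
  metric <- match.arg(metric)
  if (!linkage %in% names(LINKAGE_METHODS)) {
    abort(paste0("`linkage` must be one of: ", paste(names(LINKAGE_METHODS), collapse = ", ")))
  }
  check_feature_tbl(features, require_label = FALSE)
  x <- feature_values(features)
  d <- ncol(x)
  if (d < 2L) abort("Need at least 2 features to cluster.")

  if (scale_features) {
    x <- apply(x, 2L, function(col) {
      s <- sd(col)
      if (s == 0 || !is.finite(s)) col - mean(col) else (col - mean(col)) / s
    })
  }
  dd <- switch(metric,
    euclidean = dist(t(x)),
    correlation = stats::as.dist(1 - stats::cor(x))
  )
  if (any(!is.finite(dd))) abort("Non-finite feature distances; check input features.")
  tree <- hclust(dd, method = LINKAGE_METHODS[[linkage]])

  leaf_merges <- which(tree$merge[, 1L] < 0L & tree$merge[, 2L] < 0L)
  pairs <- tibble(
    j = pmin(-tree$merge[leaf_merges, 1L], -tree$merge[leaf_merges, 2L]),
    k = pmax(-tree$merge[leaf_merges, 1L], -tree$merge[leaf_merges, 2L]),
    height = tree$height[leaf_merges]
  )
  pairs <- dplyr::arrange(pairs, .data$j)
  out <- list(
    pairs = pairs,
    singletons = setdiff(seq_len(d), c(pairs$j, pairs$k)),
    feature_ids = colnames(x),
    config = list(linkage = linkage, metric = metric, scale_features = scale_features)
  )
  class(out) <- "feature_pairing"
  out
}

#' @export
print.feature_pairing <- function(x, ...) {
  cat("<feature_pairing> ", length(x$feature_ids), " features: ",
      nrow(x$pairs), " first-level pairs, ", length(x$singletons),
      " singletons\n", sep = "")
  cat("  linkage=", x$config$linkage, ", metric=", x$config$metric,
      ", scaled=", x$config$scale_features, "\n", sep = "")
  invisible(x)
}

#' Retain the higher-F member of each pair
#'
#' For every first-level pair the feature with the larger ANOVA F value is
#' retained and the other removed; an exact F tie is broken by a seeded
#' uniform choice. All singleton features are retained directly, so
#' `|retained| = d - |pairs|`.
#'
#' @param f_values An `anova_f` tibble from [anova_f()].
#' @param pairing A `feature_pairing` from [first_level_pairs()].
#' @param seed Integer seed for tie-breaking (recorded in the result).
#' @return A `feature_selection`: list with sorted integer vectors `retained`
#'   and `removed`, a `decisions` tibble (one row per pair: members, F
#'   values, winner, tie flag), `feature_ids`, `seed`, `config`.
#' @export
select_features <- function(f_values, pairing, seed = 1) {
  stopifnot(inherits(pairing, "feature_pairing"))
  if (!is.data.frame(f_values) || !all(c("feature", "f_value") %in% names(f_values))) {
    abort("`f_values` must be an `anova_f` table with columns `feature`, `f_value`.")
  }
  if (!identical(f_values$feature, pairing$feature_ids)) {
    abort("F values and pairing were computed on different features (id mismatch).")
  }
  f <- f_values$f_value
  d <- length(f)

  decisions <- withr::with_seed(seed, {
    purrr::pmap_dfr(pairing$pairs, function(j, k, height) {
      tie <- isTRUE(f[j] == f[k]) # Inf == Inf counts as a tie
      winner <- if (tie) sample(c(j, k), 1L) else if (f[j] >= f[k]) j else k
      tibble(
        j = j, k = k, f_j = f[j], f_k = f[k],
        winner = winner, tie_broken = tie
      )
    })
  })
  winners <- if (nrow(decisions) > 0L) decisions$winner else integer(0)
  retained <- sort(c(winners, pairing$singletons))
  out <- list(
    retained = retained,
    removed = sort(setdiff(seq_len(d), retained)),
    decisions = decisions,
    feature_ids = pairing$feature_ids,
    f_values = f,
    seed = seed,
    config = pairing$config
  )
  class(out) <- "feature_selection"
  out
}

#' @export
print.feature_selection <- function(x, ...) {
  cat("<feature_selection> ", length(x$feature_ids), " -> ",
      length(x$retained), " features (", nrow(x$decisions), " pairs, ",
      length(x$feature_ids) - 2L * nrow(x$decisions), " singletons; seed ",
      x$seed, ")\n", sep = "")
  invisible(x)
}

#' Subset a feature matrix to the retained features
#'
#' @param features Feature tibble with exactly the feature columns (same ids,
#'   same order) the selection was computed on; anything else errors rather
#'   than silently misaligning.
#' @param selection A `feature_selection` from [select_features()].
#' @return Feature tibble with `sample_id`, `label` (if present) and the
#'   retained feature columns in retained-index order.
#' @export
apply_selection <- function(features, selection) {
  stopifnot(inherits(selection, "feature_selection"))
  check_feature_tbl(features, require_label = FALSE)
  ids <- feature_ids(features)
  if (!identical(ids, selection$feature_ids)) {
    abort(paste0(
      "Feature columns do not match the selection (expected ",
      length(selection$feature_ids), " features in the original order)."
    ))
  }
  keep <- c(intersect(c("sample_id", "label"), names(features)),
            ids[selection$retained])
  features[, keep, drop = FALSE]
}

#' Run the full ANOVA + clustering selection
#'
#' Convenience wrapper chaining [anova_f()], [first_level_pairs()] and
#' [select_features()] on one labeled feature matrix.
#'
#' @inheritParams anova_f
#' @inheritParams first_level_pairs
#' @inheritParams select_features
#' @return A `feature_selection` (see [select_features()]).
#' @export
select_feature_subset <- function(features, linkage = "ward",
                                  metric = "euclidean",
                                  scale_features = TRUE, seed = 1) {
  f <- anova_f(features)
  pairing <- first_level_pairs(features,
    linkage = linkage, metric = metric,
    scale_features = scale_features
  )
  select_features(f, pairing, seed = seed)
}

#' Export a selection report as JSON
#'
#' Records the clustering configuration, seed, per-pair decisions with F
#' values, singletons and retained feature ids — enough to regenerate a
#' pairing visualization or audit the selection externally.
#'
#' @param selection A `feature_selection`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_selection_report <- function(selection, path) {
  stopifnot(inherits(selection, "feature_selection"))
  jsonlite::write_json(
    list(
      config = selection$config,
      seed = selection$seed,
      n_features = length(selection$feature_ids),
      pairs = selection$decisions,
      singletons = selection$feature_ids[setdiff(selection$retained,
                                                 selection$decisions$winner)],
      retained = selection$feature_ids[selection$retained]
    ),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
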