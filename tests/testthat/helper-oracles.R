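# Independent oracles and fixture builders shared across the suite.
# Each oracle is coded from the textbook definition, separately from the
# package implementation it cross-checks.

# Column-wise one-way ANOVA F via stats::aov (textbook route).
oracle_anova_f <- function(features) {
  y <- factor(features$label)
  vapply(feature_ids(features), function(id) {
    fit <- stats::anova(stats::aov(features[[id]] ~ y))
    fit[["F value"]][1L]
  }, numeric(1))
}

# Probabilistic AUC by exhaustive positive/negative pair comparison.
oracle_auc_pairwise <- function(truth, scores) {
  pos <- scores[truth == 1]
  neg <- scores[truth == 0]
  grid <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
  mean(grid)
}

# Naive agglomerative clustering with the ward.D2 Lance-Williams update,
# returning the first-level pairs (merges of two original leaves) as a
# sorted two-column matrix. O(d^3); for small matrices only.
oracle_first_level_pairs_ward <- function(x) {
  d <- ncol(x)
  dm <- as.matrix(stats::dist(t(x)))
  diag(dm) <- Inf
  sizes <- rep(1L, d)
  is_leaf <- rep(TRUE, d)
  alive <- rep(TRUE, d)
  pairs <- NULL
  for (step in seq_len(d - 1L)) {
    idx <- which(dm == min(dm[alive, alive]), arr.ind = TRUE)
    idx <- idx[alive[idx[, 1L]] & alive[idx[, 2L]], , drop = FALSE]
    i <- min(idx[1L, ]); j <- max(idx[1L, ])
    if (is_leaf[i] && is_leaf[j]) pairs <- rbind(pairs, c(i, j))
    ni <- sizes[i]; nj <- sizes[j]
    for (k in which(alive)) {
      if (k == i || k == j) next
      nk <- sizes[k]
      dm[i, k] <- dm[k, i] <- sqrt(
        ((ni + nk) * dm[i, k]^2 + (nj + nk) * dm[j, k]^2 - nk * dm[i, j]^2) /
          (ni + nj + nk)
      )
    }
    sizes[i] <- ni + nj
    is_leaf[i] <- FALSE
    alive[j] <- FALSE
    dm[j, ] <- dm[, j] <- Inf
  }
  pairs[order(pairs[, 1L]), , drop = FALSE]
}

# Brute-force selection: oracle pairing + max-F retention (no tie handling;
# callers use continuous data where exact ties have probability zero).
oracle_select <- function(features) {
  x <- scale(feature_values(features))
  x[is.na(x)] <- 0
  pairs <- oracle_first_level_pairs_ward(x)
  f <- oracle_anova_f(features)
  winners <- apply(pairs, 1L, function(p) p[which.max(f[p])])
  sort(c(winners, setdiff(seq_along(f), as.vector(pairs))))
}

# Small labeled feature tibble with random values.
random_feature_tbl <- function(n = 20, d = 10, seed = 1) {
  withr::with_seed(seed, {
    x <- matrix(rnorm(n * d), n, d)
    colnames(x) <- sprintf("f_%03d", seq_len(d))
    dplyr::bind_cols(
      tibble::tibble(
        sample_id = sprintf("s%03d", seq_len(n)),
        label = rep(c(0L, 1L), length.out = n)
      ),
      tibble::as_tibble(x)
    )
  })
}

# Three-feature toy in the first-level-clustering setting: features 2 and 3
# are near-duplicates (they pair first) with F2 > F3; feature 1 is
# unrelated and ends up a singleton.
toy_three_feature_matrix <- function(seed = 42) {
  withr::with_seed(seed, {
    n <- 20L
    label <- rep(c(0L, 1L), each = n / 2L)
    f2 <- 2 * label + rnorm(n, sd = 0.3)
    f3 <- f2 + rnorm(n, sd = 0.15) # extra within-group scatter lowers F
    f1 <- rnorm(n)
    tibble::tibble(
      sample_id = sprintf("s%02d", seq_len(n)), label = label,
      feat_1 = f1, feat_2 = f2, feat_3 = f3
    )
  })
}

# Tiny fixed-length labeled sequence tibble.
tiny_seqs <- function(n = 6, L = 12, seed = 1) {
  simulate_promoter_dataset(
    n_pos = n / 2, n_neg = n / 2, length = L,
    motif = "TATA", motif_start = 3, match_prob = 1, seed = seed
  )
}
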