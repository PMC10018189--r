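test_that("two-group ANOVA F matches hand arithmetic and the aov oracle", {
  # group0 = [1, 2], group1 = [3, 4]: SSB = 4 (df 1), SSW = 1 (df 2) -> F = 8
  feats <- tibble::tibble(
    sample_id = paste0("s", 1:4), label = c(0L, 0L, 1L, 1L),
    f_001 = c(1, 2, 3, 4)
  )
  expect_equal(anova_f(feats)$f_value, 8)

  # random 20 x 10 matrix vs independently computed textbook ANOVA
  rf <- random_feature_tbl(n = 20, d = 10, seed = 31)
  got <- anova_f(rf)
  expect_equal(got$f_value, unname(oracle_anova_f(rf)), tolerance = 1e-10)
  expect_true(all(got$f_value >= 0))

  # invariant to sample order and to class relabeling
  perm <- sample(seq_len(20))
  expect_equal(anova_f(rf[perm, ])$f_value, got$f_value, tolerance = 1e-10)
  flipped <- dplyr::mutate(rf, label = 1L - label)
  expect_equal(anova_f(flipped)$f_value, got$f_value, tolerance = 1e-10)
})

test_that("degenerate features follow the explicit F rules", {
  feats <- tibble::tibble(
    sample_id = paste0("s", 1:6), label = rep(c(0L, 1L), each = 3),
    const = rep(0.1, 6),               # constant everywhere -> F = 0
    separ = c(1, 1, 1, 2, 2, 2),       # separated, no within scatter -> Inf
    normal = c(1, 2, 3, 4, 5, 7)
  )
  expect_warning(got <- anova_f(feats), "constant")
  expect_equal(got$f_value[got$feature == "const"], 0)
  expect_identical(got$f_value[got$feature == "separ"], Inf)
  expect_true(is.finite(got$f_value[got$feature == "normal"]))

  single <- dplyr::mutate(feats, label = 0L)
  expect_error(anova_f(single), "Both classes")
  expect_error(anova_f(feats[c(1, 2, 4), ]), "at least 4|at least 2")
})

test_that("first-level pairs come from leaf-leaf merges and partition features", {
  toy <- toy_three_feature_matrix()
  pairing <- first_level_pairs(toy)
  expect_equal(nrow(pairing$pairs), 1)
  expect_equal(c(pairing$pairs$j, pairing$pairs$k), c(2, 3))
  expect_equal(pairing$singletons, 1)

  # d = 2 forces exactly one pair
  two <- random_feature_tbl(n = 10, d = 2, seed = 8)
  p2 <- first_level_pairs(two)
  expect_equal(nrow(p2$pairs), 1)
  expect_length(p2$singletons, 0)

  # an exactly duplicated feature pairs with its copy at height zero
  dup <- random_feature_tbl(n = 15, d = 6, seed = 12)
  dup$f_006 <- dup$f_003
  pd <- first_level_pairs(dup)
  zero_pair <- pd$pairs[pd$pairs$height < 1e-10, ]
  expect_equal(c(zero_pair$j, zero_pair$k), c(3, 6))

  # partition invariant across random instances and linkages
  for (seed in 1:4) {
    d <- sample(3:12, 1)
    m <- random_feature_tbl(n = 12, d = d, seed = seed)
    for (linkage in c("ward", "complete", "average", "single")) {
      pr <- first_level_pairs(m, linkage = linkage)
      members <- c(pr$pairs$j, pr$pairs$k, pr$singletons)
      expect_setequal(members, seq_len(d))
      expect_equal(2 * nrow(pr$pairs) + length(pr$singletons), d)
    }
  }
})

test_that("pairing agrees with a naive Lance-Williams agglomerative oracle", {
  for (seed in 1:6) {
    m <- random_feature_tbl(n = sample(10:30, 1), d = sample(4:12, 1),
                            seed = 100 + seed)
    pr <- first_level_pairs(m, linkage = "ward")
    x <- scale(as.matrix(m[, feature_ids(m)]))
    oracle <- oracle_first_level_pairs_ward(x)
    expect_equal(as.matrix(pr$pairs[, c("j", "k")]), oracle,
                 ignore_attr = TRUE)
  }
})

test_that("selection keeps the larger-F member per pair plus singletons", {
  toy <- toy_three_feature_matrix()
  f <- anova_f(toy)
  expect_gt(f$f_value[2], f$f_value[3]) # construction check: F2 > F3
  sel <- select_features(f, first_level_pairs(toy), seed = 1)
  expect_equal(sel$retained, c(1, 2))
  expect_equal(sel$removed, 3)
  expect_equal(length(sel$retained),
               length(sel$feature_ids) - nrow(sel$decisions))

  # full-pipeline equivalence with the brute-force oracle
  for (seed in 1:4) {
    m <- random_feature_tbl(n = 24, d = sample(5:12, 1), seed = 200 + seed)
    sel_m <- select_feature_subset(m, seed = 1)
    expect_equal(sel_m$retained, oracle_select(m))
  }
})

test_that("exact F ties are broken by a seeded coin with ~0.5 frequency", {
  # two identical columns: same F, distance zero, guaranteed pair
  base <- random_feature_tbl(n = 16, d = 3, seed = 77)
  base$f_002 <- base$f_001
  f <- anova_f(base)
  pairing <- first_level_pairs(base)
  expect_true(any(pairing$pairs$j == 1 & pairing$pairs$k == 2))
  picks <- vapply(1:1000, function(s) {
    sel <- select_features(f, pairing, seed = s)
    sel$decisions$winner[sel$decisions$j == 1]
  }, numeric(1))
  expect_true(all(picks %in% c(1, 2)))
  freq <- mean(picks == 1)
  expect_gt(freq, 0.45)
  expect_lt(freq, 0.55)
  # deterministic given one seed
  s1 <- select_features(f, pairing, seed = 99)
  s2 <- select_features(f, pairing, seed = 99)
  expect_identical(s1$retained, s2$retained)
  expect_true(any(s1$decisions$tie_broken))
})

test_that("applying a selection subsets columns safely", {
  m <- random_feature_tbl(n = 12, d = 8, seed = 5)
  sel <- select_feature_subset(m, seed = 2)
  sub <- apply_selection(m, sel)
  expect_identical(feature_ids(sub), sel$feature_ids[sel$retained])
  expect_identical(sub$label, m$label)

  # identity selection keeps everything
  all_single <- sel
  all_single$retained <- seq_along(sel$feature_ids)
  all_single$removed <- integer(0)
  expect_identical(as.data.frame(apply_selection(m, all_single)),
                   as.data.frame(m))

  # shuffled or renamed columns are an error, not silent misalignment
  shuffled <- m[, c("sample_id", "label", rev(feature_ids(m)))]
  expect_error(apply_selection(shuffled, sel), "do not match")
  expect_error(apply_selection(m[, 1:5], sel), "do not match")
})

test_that("retained features never lose the global closest-pair distance floor", {
  # the closest pair loses one member, so the minimum pairwise distance
  # among retained features is >= the pre-selection global minimum
  for (seed in 1:4) {
    m <- random_feature_tbl(n = 20, d = 10, seed = 300 + seed)
    sel <- select_feature_subset(m, seed = 1)
    x <- scale(as.matrix(m[, feature_ids(m)]))
    dm <- as.matrix(dist(t(x)))
    diag(dm) <- Inf
    kept <- dm[sel$retained, sel$retained]
    expect_gte(min(kept), min(dm))
  }
})

test_that("selection reports serialize with config, decisions and ids", {
  m <- random_feature_tbl(n = 12, d = 6, seed = 15)
  sel <- select_feature_subset(m, seed = 3)
  path <- withr::local_tempfile(fileext = ".json")
  write_selection_report(sel, path)
  rep <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(rep$config$linkage, "ward")
  expect_equal(rep$seed, 3)
  expect_setequal(rep$retained, sel$feature_ids[sel$retained])
  expect_equal(nrow(rep$pairs), nrow(sel$decisions))

  td <- tidy(sel)
  expect_equal(sum(td$status == "retained"), length(sel$retained))
  gl <- glance(sel)
  expect_equal(gl$n_retained, gl$n_features - gl$n_pairs)
})
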