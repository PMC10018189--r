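test_that("dinucleotide statistics match hand arithmetic and a brute-force oracle", {
  # constant row: (c, c, c, 0, K*c)
  props <- simulate_property_table(K = 5, seed = 1, constant_dinucs = "CG")
  sm <- dinuc_stats(props)
  cg <- sm[sm$dinuc == "CG", ]
  expect_equal(cg$p_min, cg$p_max)
  expect_equal(cg$p_mean, cg$p_min)
  expect_equal(cg$p_var, 0)
  expect_equal(cg$p_sum, 5 * cg$p_mean)

  # K = 2, row [1, 3] -> (1, 3, 2, 1, 4) with population variance
  row13 <- new_property_tbl(matrix(c(1, 3), nrow = 16, ncol = 2, byrow = TRUE))
  sm13 <- dinuc_stats(row13)
  expect_equal(unlist(sm13[1, -1]), c(p_min = 1, p_max = 3, p_mean = 2,
                                      p_var = 1, p_sum = 4))
  # sample-variance flag uses denominator K - 1
  expect_equal(dinuc_stats(row13, variance = "sample")$p_var[1], 2)

  # random 16 x 90 table vs a per-row recomputation with base summaries
  props90 <- simulate_property_table(K = 90, seed = 23)
  sm90 <- dinuc_stats(props90)
  vals <- as.matrix(props90[-1])
  for (i in seq_len(16)) {
    x <- vals[i, ]
    expect_equal(sm90$p_min[i], min(x))
    expect_equal(sm90$p_max[i], max(x))
    expect_equal(sm90$p_mean[i], mean(x))
    expect_equal(sm90$p_var[i], mean((x - mean(x))^2), tolerance = 1e-12)
    expect_equal(sm90$p_sum[i], sum(x))
  }
})

test_that("statistic invariants hold on random tables", {
  for (seed in 1:5) {
    props <- simulate_property_table(K = sample(2:120, 1), seed = seed)
    sm <- dinuc_stats(props)
    k <- attr(sm, "K")
    expect_true(all(sm$p_min <= sm$p_mean + 1e-12))
    expect_true(all(sm$p_mean <= sm$p_max + 1e-12))
    expect_true(all(sm$p_var >= 0))
    expect_equal(sm$p_sum, k * sm$p_mean, tolerance = 1e-9)
  }
})

test_that("dinucleotide decomposition follows the L - 1 overlapping windows", {
  expect_identical(dinucleotides_of("ACGT"), c("AC", "CG", "GT"))
  expect_identical(dinucleotides_of("AA"), "AA")
  seq81 <- strrep("ACGT", 21) |> substr(1, 81)
  expect_length(dinucleotides_of(seq81), 80)
  expect_error(dinucleotides_of("A"), "length >= 2")
  expect_error(dinucleotides_of("ACGN"), "outside")
})

test_that("sequence encoding is a positional five-statistic lookup", {
  props <- simulate_property_table(K = 90, seed = 2)
  sm <- dinuc_stats(props)

  seq81 <- simulate_promoter_dataset(n_pos = 1, n_neg = 1, seed = 3)$seq[1]
  v <- encode_sequence(seq81, sm)
  expect_length(v, 400)
  expect_identical(names(v)[1:5],
                   c("pos001_min", "pos001_max", "pos001_mean",
                     "pos001_var", "pos001_sum"))

  # a 2 bp sequence encodes exactly to its dinucleotide's 5-vector
  ta <- encode_sequence("TA", sm)
  expect_equal(unname(ta),
               unlist(sm[sm$dinuc == "TA", c("p_min", "p_max", "p_mean",
                                             "p_var", "p_sum")], use.names = FALSE))

  # general 5 * (L - 1) law
  for (L in c(2, 10, 81)) {
    s <- substr(strrep("ACGT", ceiling(L / 4)), 1, L)
    expect_length(encode_sequence(s, sm), 5 * (L - 1))
  }

  # changing one base only perturbs the two overlapping dinucleotide slots
  s1 <- strrep("A", 20)
  j <- 10
  s2 <- paste0(substr(s1, 1, j - 1), "G", substr(s1, j + 1, 20))
  d <- which(encode_sequence(s1, sm) != encode_sequence(s2, sm))
  touched <- c(5 * (j - 2) + 1:5, 5 * (j - 1) + 1:5)
  expect_true(all(d %in% touched))
  expect_true(length(d) > 0)
})

test_that("dataset encoding preserves order, labels and the lookup structure", {
  props <- simulate_property_table(K = 30, seed = 4)
  sm <- dinuc_stats(props)
  seqs <- tiny_seqs(n = 10, L = 81)
  feats <- encode_dataset(seqs, sm)
  expect_equal(nrow(feats), 10)
  expect_length(feature_ids(feats), 400)
  expect_identical(feats$sample_id, seqs$id)
  expect_identical(feats$label, seqs$label)

  # row i equals the single-sequence encoder on sequence i
  for (i in c(1, 7)) {
    expect_equal(unlist(feats[i, feature_ids(feats)]),
                 encode_sequence(seqs$seq[i], sm))
  }

  # at most 16 distinct 5-vectors occur across all positions and samples
  m <- as.matrix(feats[, feature_ids(feats)])
  blocks <- unique(apply(
    matrix(as.vector(t(m)), ncol = 5, byrow = TRUE), 1, paste, collapse = "|"
  ))
  expect_lte(length(blocks), 16)

  # shuffled input rows come back in the shuffled order
  perm <- c(3, 1, 2, 10, 9, 4, 5, 8, 6, 7)
  expect_equal(as.data.frame(encode_dataset(seqs[perm, ], sm)),
               as.data.frame(feats[perm, ]), ignore_attr = TRUE)

  # degenerate and invalid inputs error
  expect_error(encode_dataset(seqs[0, ], sm), "empty")
  mixed <- seqs
  mixed$seq[2] <- substr(mixed$seq[2], 1, 50)
  expect_error(encode_dataset(mixed, sm), "one length")

  # identical property rows give identical 5-vectors (lookup consistency)
  dup <- simulate_property_table(K = 10, seed = 5, duplicate_of = c(TA = "AT"))
  smd <- dinuc_stats(dup)
  expect_equal(encode_sequence("TA", smd), encode_sequence("AT", smd),
               ignore_attr = TRUE)
})

test_that("property standardization z-scores columns before the statistics", {
  props <- simulate_property_table(K = 8, seed = 6)
  smz <- dinuc_stats(props, standardize = TRUE)
  vals <- scale(as.matrix(props[-1]))
  expect_equal(smz$p_mean, unname(rowMeans(vals)), tolerance = 1e-12)
  # every standardized column has mean 0 across dinucleotides
  expect_equal(sum(smz$p_sum), 0, tolerance = 1e-9)
})
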