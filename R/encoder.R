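# Positional dinucleotide physicochemical encoder: each position's
# dinucleotide is replaced by five statistical parameters (min, max, mean,
# variance, sum) of its K property values, giving a 5*(L-1) feature vector.

#' Per-dinucleotide statistical parameters of a property table
#'
#' Collapses the K physicochemical properties of each dinucleotide into the
#' five statistical parameters used by the encoder: minimum, maximum,
#' arithmetic mean, variance and sum.
#'
#' @param props A `property_tbl` (see [read_property_table()]).
#' @param standardize If `TRUE`, z-score each property column across the 16
#'   dinucleotides before computing the statistics. Default `FALSE`: the
#'   statistics describe the properties as distributed in the table.
#' @param variance `"population"` (default; denominator K, so a constant row
#'   has variance exactly 0) or `"sample"` (denominator K - 1).
#' @return A `dinuc_stats` tibble with columns `dinuc`, `p_min`, `p_max`,
#'   `p_mean`, `p_var`, `p_sum`; attribute `K` records the number of
#'   properties.
#' @examples
#' props <- simulate_property_table(K = 90, seed = 1)
#' dinuc_stats(props)
#' @export
dinuc_stats <- function(props, standardize = FALSE,
                        variance = c("population", "sample")) {
  variance <- match.arg(variance)
  check_property_tbl(props)
  vals <- property_values(props)
  k <- ncol(vals)
  if (standardize) {
    vals <- apply(vals, 2L, function(x) {
      s <- sd(x)
      if (s == 0) x - mean(x) else (x - mean(x)) / s
    })
  }
  means <- rowMeans(vals)
  sq_dev <- rowSums((vals - means)^2)
  vars <- if (variance == "population") sq_dev / k else {
    if (k < 2L) abort("Sample variance needs K >= 2 properties.")
    sq_dev / (k - 1L)
  }
  out <- tibble(
    dinuc = DINUCLEOTIDES,
    p_min = unname(apply(vals, 1L, min)),
    p_max = unname(apply(vals, 1L, max)),
    p_mean = unname(means),
    p_var = unname(vars),
    p_sum = unname(rowSums(vals))
  )
  attr(out, "K") <- k
  attr(out, "standardize") <- standardize
  attr(out, "variance") <- variance
  class(out) <- c("dinuc_stats", class(out))
  out
}

check_dinuc_stats <- function(stats_map) {
  cols <- c("dinuc", "p_min", "p_max", "p_mean", "p_var", "p_sum")
  if (!is.data.frame(stats_map) || !all(cols %in% names(stats_map)) ||
      !identical(sort(stats_map$dinuc), sort(DINUCLEOTIDES))) {
    abort("`stats_map` must be a complete `dinuc_stats` table (see `dinuc_stats()`).")
  }
  invisible(stats_map)
}

STAT_NAMES <- c("min", "max", "mean", "var", "sum")

# 16 x 5 lookup matrix in canonical dinucleotide order
stats_matrix <- function(stats_map) {
  m <- as.matrix(stats_map[match(DINUCLEOTIDES, stats_map$dinuc),
                           c("p_min", "p_max", "p_mean", "p_var", "p_sum")])
  rownames(m) <- DINUCLEOTIDES
  colnames(m) <- STAT_NAMES
  m
}

#' Overlapping dinucleotides of a sequence
#'
#' A sequence of length L contains L - 1 overlapping dinucleotides; element i
#' covers bases i and i + 1.
#'
#' @param seq A single DNA string over A, C, G, T (length >= 2).
#' @return Character vector of length `nchar(seq) - 1`.
#' @examples
#' dinucleotides_of("ACGT") # "AC" "CG" "GT"
#' @export
dinucleotides_of <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  seq <- toupper(seq)
  l <- nchar(seq)
  if (l < 2L) abort("Sequence must have length >= 2.")
  if (stringr::str_detect(seq, "[^ACGT]")) abort("Sequence contains characters outside {A,C,G,T}.")
  substring(seq, seq_len(l - 1L), seq_len(l - 1L) + 1L)
}

#' Encode one sequence as positional dinucleotide statistics
#'
#' Concatenates, over positions i = 1..L-1, the five statistical parameters
#' of the dinucleotide starting at position i, in the fixed order
#' (min, max, mean, var, sum). The result has length 5 * (L - 1) — 400 for
#' the 81 bp windows the predictor was designed around.
#'
#' @param seq A DNA string (length >= 2).
#' @param stats_map A `dinuc_stats` table from [dinuc_stats()].
#' @return Named numeric vector; names are feature ids of the form
#'   `pos017_var` (1-based position, statistic).
#' @export
encode_sequence <- function(seq, stats_map) {
  check_dinuc_stats(stats_map)
  dn <- dinucleotides_of(seq)
  m <- stats_matrix(stats_map)[match(dn, DINUCLEOTIDES), , drop = FALSE]
  out <- as.vector(t(m))
  names(out) <- encoder_feature_ids(nchar(seq))
  out
}

encoder_feature_ids <- function(L) {
  as.vector(t(outer(
    seq_len(L - 1L), STAT_NAMES,
    function(i, s) sprintf("pos%03d_%s", i, s)
  )))
}

#' Encode a labeled sequence set into a feature matrix
#'
#' Applies [encode_sequence()] to every record of a fixed-length sequence
#' set, preserving row order and carrying labels through.
#'
#' @param seqs Sequence tibble (`id`, `seq`, optionally `label`); all
#'   sequences must share one length.
#' @param stats_map A `dinuc_stats` table from [dinuc_stats()].
#' @return Feature tibble: `sample_id`, `label` (if present), then
#'   5 * (L - 1) feature columns.
#' @examples
#' props <- simulate_property_table(K = 10, seed = 1)
#' seqs <- simulate_promoter_dataset(n_pos = 5, n_neg = 5, seed = 1)
#' dim(encode_dataset(seqs, dinuc_stats(props)))
#' @export
encode_dataset <- function(seqs, stats_map) {
  check_sequence_tbl(seqs, require_label = FALSE, require_equal_length = TRUE)
  check_dinuc_stats(stats_map)
  L <- nchar(seqs$seq[1L])
  if (L < 2L) abort("Sequences must have length >= 2.")
  sm <- stats_matrix(stats_map)

  # dinucleotide index per (sample, position), then block lookup per position
  chars <- matrix(unlist(strsplit(seqs$seq, "", fixed = TRUE), use.names = FALSE),
                  nrow = nrow(seqs), byrow = TRUE)
  blocks <- lapply(seq_len(L - 1L), function(j) {
    dn <- paste0(chars[, j], chars[, j + 1L])
    sm[match(dn, DINUCLEOTIDES), , drop = FALSE]
  })
  vals <- do.call(cbind, blocks)
  colnames(vals) <- encoder_feature_ids(L)

  out <- tibble(sample_id = seqs$id)
  if ("label" %in% names(seqs)) {
    if (!all(seqs$label %in% c(0L, 1L))) abort("Labels must be 0 or 1.")
    out$label <- as.integer(seqs$label)
  }
  dplyr::bind_cols(out, as_tibble(vals))
}
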