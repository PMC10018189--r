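# Seeded simulators for the two external inputs: a dinucleotide
# physicochemical property table, and a labeled fixed-length sequence set
# where positives carry a planted consensus box against a background model.

#' Simulate a dinucleotide property table
#'
#' Draws a 16 x K property matrix with controlled per-dinucleotide spread:
#' each dinucleotide gets a location drawn from N(0, `dinuc_spread`) and its
#' K property values are N(location, `noise_sd`). Pathological variants for
#' encoder testing: rows can be made exactly constant, or exact copies of
#' another dinucleotide's row.
#'
#' @param K Number of properties (default 90, the size of published
#'   dinucleotide physicochemical collections).
#' @param seed Integer seed; the same seed reproduces the table exactly.
#' @param dinuc_spread Standard deviation of the per-dinucleotide locations.
#' @param noise_sd Within-dinucleotide standard deviation across properties.
#' @param constant_dinucs Character vector of dinucleotides whose rows are
#'   set to a single repeated value (their location).
#' @param duplicate_of Named character vector, e.g. `c(TA = "AT")`, copying
#'   the row of the value onto the name.
#' @return A `property_tbl` (see [read_property_table()]).
#' @export
simulate_property_table <- function(K = 90, seed = 1, dinuc_spread = 1,
                                    noise_sd = 1, constant_dinucs = NULL,
                                    duplicate_of = NULL) {
  if (K < 1L) abort("`K` must be at least 1.")
  vals <- withr::with_seed(seed, {
    loc <- stats::rnorm(16L, 0, dinuc_spread)
    m <- t(vapply(seq_len(16L), function(i) stats::rnorm(K, loc[i], noise_sd),
                  numeric(K)))
    if (!is.null(constant_dinucs)) {
      stopifnot(all(constant_dinucs %in% DINUCLEOTIDES))
      for (dn in constant_dinucs) {
        m[match(dn, DINUCLEOTIDES), ] <- loc[match(dn, DINUCLEOTIDES)]
      }
    }
    m
  })
  if (!is.null(duplicate_of)) {
    stopifnot(all(names(duplicate_of) %in% DINUCLEOTIDES),
              all(duplicate_of %in% DINUCLEOTIDES))
    for (dn in names(duplicate_of)) {
      vals[match(dn, DINUCLEOTIDES), ] <- vals[match(duplicate_of[[dn]], DINUCLEOTIDES), ]
    }
  }
  new_property_tbl(vals)
}

#' C. glutamicum style background base frequencies
#'
#' Base composition matching a 53.8% G+C genome (G and C at 26.9% each),
#' for more realistic negative sequences than the uniform default.
#'
#' @return Named numeric vector over A, C, G, T summing to 1.
#' @export
cg_background <- function() {
  c(A = 0.231, C = 0.269, G = 0.269, T = 0.231)
}

#' Simulate a labeled promoter / non-promoter sequence set
#'
#' Negatives are i.i.d. draws from the background base distribution
#' (emulating random fixed-length genome fragments). Positives start as
#' background and then carry a planted consensus box: at each motif position
#' the consensus base is emitted with probability `match_prob`, otherwise
#' one of the other three bases uniformly. With `match_prob = 0.25` under a
#' uniform background the planted positions are exactly background, giving
#' a null (signal-free) dataset.
#'
#' @param n_pos,n_neg Class sizes (defaults 1000 + 1000, the benchmark
#'   scale).
#' @param length Sequence length L (default 81).
#' @param motif Consensus string planted in positives (default `"TATAAT"`,
#'   a canonical bacterial -10 box).
#' @param motif_start 1-based start of the motif (default 66, a -10-box-like
#'   offset in an 81 bp window whose transcription start lies near the 3'
#'   end).
#' @param match_prob Per-base probability that a motif position carries the
#'   consensus base (default 0.95).
#' @param background Named base frequencies (A, C, G, T), summing to 1;
#'   default uniform. See [cg_background()].
#' @param seed Integer seed; the same seed reproduces the set exactly.
#' @return Labeled sequence tibble (`id`, `seq`, `label`), positives first.
#' @examples
#' simulate_promoter_dataset(n_pos = 3, n_neg = 3, length = 20,
#'                           motif = "TATAAT", motif_start = 10, seed = 1)
#' @export
simulate_promoter_dataset <- function(n_pos = 1000, n_neg = 1000, length = 81,
                                      motif = "TATAAT", motif_start = 66,
                                      match_prob = 0.95,
                                      background = c(A = 0.25, C = 0.25,
                                                     G = 0.25, T = 0.25),
                                      seed = 1) {
  bases <- c("A", "C", "G", "T")
  stopifnot(n_pos >= 1L, n_neg >= 1L, length >= 2L)
  if (!all(bases %in% names(background)) ||
      abs(sum(background) - 1) > 1e-8 || any(background < 0)) {
    abort("`background` must be nonnegative A/C/G/T frequencies summing to 1.")
  }
  background <- background[bases]
  motif <- toupper(motif)
  motif_chars <- strsplit(motif, "", fixed = TRUE)[[1L]]
  if (any(!motif_chars %in% bases)) abort("`motif` must be over {A,C,G,T}.")
  if (motif_start < 1L || motif_start + nchar(motif) - 1L > length) {
    abort("Motif does not fit: motif_start + nchar(motif) - 1 must be <= length.")
  }
  if (match_prob < 0 || match_prob > 1) abort("`match_prob` must be in [0, 1].")

  withr::with_seed(seed, {
    draw_background <- function(n) {
      matrix(sample(bases, n * length, replace = TRUE, prob = background),
             nrow = n)
    }
    pos <- draw_background(n_pos)
    for (p in seq_along(motif_chars)) {
      col <- motif_start + p - 1L
      hit <- stats::runif(n_pos) < match_prob
      pos[hit, col] <- motif_chars[p]
      if (any(!hit)) {
        others <- setdiff(bases, motif_chars[p])
        pos[!hit, col] <- sample(others, sum(!hit), replace = TRUE)
      }
    }
    neg <- draw_background(n_neg)
    tibble(
      id = c(sprintf("pos_%05d", seq_len(n_pos)), sprintf("neg_%05d", seq_len(n_neg))),
      seq = c(apply(pos, 1L, paste, collapse = ""), apply(neg, 1L, paste, collapse = "")),
      label = c(rep(1L, n_pos), rep(0L, n_neg))
    )
  })
}
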