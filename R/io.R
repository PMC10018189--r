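# Sequence, property-table and feature-matrix I/O plus dataset assembly.

#' Read a FASTA file into a sequence tibble
#'
#' Parses a (possibly multi-line) FASTA file, uppercases the sequences and
#' validates that they contain only A, C, G, T. Record ids are the first
#' whitespace-delimited token of each header.
#'
#' @param path Path to a FASTA file.
#' @param label Optional class label attached to every record: `1` for
#'   promoters, `0` for non-promoters, or `NULL` (prediction mode).
#' @param on_invalid What to do with a record containing a non-ACGT character
#'   (e.g. `N`): `"abort"` (default) stops with the offending record id,
#'   `"drop"` removes the record with a warning.
#' @return A tibble with columns `id`, `seq` and (if `label` was given)
#'   `label`.
#' @examples
#' tmp <- tempfile(fileext = ".fasta")
#' writeLines(c(">p1", "ACGTACGT", ">p2", "TTGACAAT"), tmp)
#' read_fasta(tmp, label = 1)
#' @export
read_fasta <- function(path, label = NULL, on_invalid = c("abort", "drop")) {
  on_invalid <- match.arg(on_invalid)
  if (!file.exists(path)) {
    abort(paste0("FASTA file not found: ", path))
  }
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) == 0L) {
    abort(paste0("FASTA file is empty: ", path))
  }
  ids <- stringr::str_extract(names(set), "^\\S+")
  seqs <- toupper(as.character(set))
  bad <- stringr::str_detect(seqs, "[^ACGT]")
  if (any(bad)) {
    if (on_invalid == "abort") {
      abort(paste0(
        "Non-ACGT character in record(s): ",
        paste(ids[bad], collapse = ", ")
      ))
    }
    warn(paste0(
      "Dropping ", sum(bad), " record(s) with non-ACGT characters: ",
      paste(ids[bad], collapse = ", ")
    ))
    ids <- ids[!bad]
    seqs <- seqs[!bad]
    if (length(seqs) == 0L) abort("All records were dropped; nothing to read.")
  }
  out <- tibble(id = unname(ids), seq = unname(seqs))
  if (!is.null(label)) {
    stopifnot(label %in% c(0, 1))
    out$label <- as.integer(label)
  }
  out
}

#' Write a sequence tibble to FASTA
#'
#' @param seqs Tibble with columns `id` and `seq`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  check_sequence_tbl(seqs, require_label = FALSE)
  set <- Biostrings::DNAStringSet(setNames(seqs$seq, seqs$id))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

check_sequence_tbl <- function(seqs, require_label = TRUE, require_equal_length = FALSE) {
  if (!is.data.frame(seqs) || !all(c("id", "seq") %in% names(seqs))) {
    abort("`seqs` must be a data frame with columns `id` and `seq`.")
  }
  if (nrow(seqs) == 0L) abort("Sequence set is empty.")
  if (any(stringr::str_detect(seqs$seq, "[^ACGT]"))) {
    abort("Sequences contain characters outside {A,C,G,T}.")
  }
  if (require_label) {
    if (!"label" %in% names(seqs)) abort("`seqs` must have a `label` column.")
    if (!all(seqs$label %in% c(0L, 1L))) abort("Labels must be 0 or 1.")
  }
  if (require_equal_length && length(unique(nchar(seqs$seq))) != 1L) {
    abort("All sequences in a dataset must share one length.")
  }
  invisible(seqs)
}

#' Read a dinucleotide physicochemical property table
#'
#' Reads a TSV/CSV table of numeric physicochemical properties for the 16
#' dinucleotides and returns it in canonical orientation: one row per
#' dinucleotide in the order of [DINUCLEOTIDES], one column per property.
#' The file may be laid out either as 16 rows x K properties (dinucleotide
#' names in the first column) or transposed as K rows x 16 columns
#' (dinucleotide names in the header); orientation is auto-detected by
#' locating the line or column holding at least 12 of the 16 dinucleotide
#' tokens.
#'
#' @param path Path to a TSV or CSV file.
#' @return A `property_tbl`: tibble with column `dinuc` followed by K numeric
#'   property columns.
#' @export
read_property_table <- function(path) {
  if (!file.exists(path)) abort(paste0("Property table not found: ", path))
  delim <- guess_delim(path)
  raw <- suppressWarnings(readr::read_delim(
    path, delim = delim, col_names = FALSE,
    col_types = readr::cols(.default = readr::col_character()),
    show_col_types = FALSE, progress = FALSE
  ))
  raw <- as.matrix(raw)
  if (nrow(raw) < 2L || ncol(raw) < 2L) abort("Property table too small to parse.")

  n_dinuc_hits <- function(x) sum(toupper(trimws(x)) %in% DINUCLEOTIDES)
  header_hits <- n_dinuc_hits(raw[1L, ])
  column_hits <- n_dinuc_hits(raw[, 1L])

  if (header_hits >= 12L) {
    # K rows x 16 cols: dinucleotides run along the header
    dn_idx <- which(toupper(trimws(raw[1L, ])) %in% DINUCLEOTIDES)
    dn <- toupper(trimws(raw[1L, dn_idx]))
    prop_names <- if (dn_idx[1L] > 1L) trimws(raw[-1L, 1L]) else NULL
    vals <- t(apply(raw[-1L, dn_idx, drop = FALSE], 1:2, parse_num_cell))
    colnames(vals) <- NULL
  } else if (column_hits >= 12L) {
    # 16 rows x K cols: dinucleotides run down the first column
    dn_idx <- which(toupper(trimws(raw[, 1L])) %in% DINUCLEOTIDES)
    dn <- toupper(trimws(raw[dn_idx, 1L]))
    has_header <- !(toupper(trimws(raw[1L, 1L])) %in% DINUCLEOTIDES)
    prop_names <- if (has_header) trimws(raw[1L, -1L]) else NULL
    vals <- apply(raw[dn_idx, -1L, drop = FALSE], 1:2, parse_num_cell)
  } else {
    abort(paste0(
      "Could not locate the dinucleotide axis in ", path,
      " (need >= 12 of the 16 dinucleotide names in one line or column)."
    ))
  }

  missing <- setdiff(DINUCLEOTIDES, dn)
  if (length(missing) > 0L) {
    abort(paste0("missing dinucleotide ", paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(dn)) {
    abort(paste0(
      "duplicate dinucleotide ",
      paste(unique(dn[duplicated(dn)]), collapse = ", ")
    ))
  }
  if (ncol(vals) == 0L) abort("Property table has zero property columns.")
  if (any(!is.finite(vals))) abort("Property table contains non-numeric or non-finite cells.")

  vals <- vals[match(DINUCLEOTIDES, dn), , drop = FALSE]
  new_property_tbl(vals, prop_names)
}

parse_num_cell <- function(x) {
  out <- suppressWarnings(as.numeric(x))
  out
}

guess_delim <- function(path) {
  first <- readLines(path, n = 1L)
  if (stringr::str_count(first, "\t") >= stringr::str_count(first, ",")) "\t" else ","
}

new_property_tbl <- function(values, prop_names = NULL) {
  k <- ncol(values)
  if (is.null(prop_names) || length(prop_names) != k || anyDuplicated(prop_names)) {
    prop_names <- sprintf("prop_%03d", seq_len(k))
  }
  colnames(values) <- prop_names
  out <- dplyr::bind_cols(tibble(dinuc = DINUCLEOTIDES), as_tibble(values))
  class(out) <- c("property_tbl", class(out))
  out
}

#' Write a property table to TSV
#'
#' @param props A `property_tbl` (see [read_property_table()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_property_table <- function(props, path) {
  check_property_tbl(props)
  readr::write_tsv(as_tibble(props), path, progress = FALSE)
  invisible(path)
}

check_property_tbl <- function(props) {
  if (!is.data.frame(props) || names(props)[1L] != "dinuc") {
    abort("`props` must be a property table with a leading `dinuc` column.")
  }
  if (!identical(sort(props$dinuc), sort(DINUCLEOTIDES)) || nrow(props) != 16L) {
    abort("Property table must have exactly the 16 dinucleotide rows.")
  }
  vals <- property_values(props)
  if (ncol(vals) < 1L) abort("Property table must have at least one property (K >= 1).")
  if (!all(is.finite(vals))) abort("Property table values must be finite numbers.")
  invisible(props)
}

# 16 x K numeric matrix in canonical dinucleotide order
property_values <- function(props) {
  m <- as.matrix(props[match(DINUCLEOTIDES, props$dinuc), -1L, drop = FALSE])
  rownames(m) <- DINUCLEOTIDES
  storage.mode(m) <- "double"
  m
}

#' Stratified train/independent split of a labeled sequence set
#'
#' Splits each class independently at `ratio` (so a 1,000 + 1,000 set at 0.8
#' becomes 800 + 800 training and 200 + 200 independent records). When
#' `ratio * n` is fractional for a class the extra record goes to the
#' training part. Deterministic given `seed`.
#'
#' @param seqs Labeled sequence tibble (`id`, `seq`, `label`).
#' @param ratio Training fraction, strictly between 0 and 1. Default 0.8.
#' @param seed Integer seed controlling the shuffle.
#' @return List with tibbles `train` and `test`, each carrying a
#'   `split` attribute tag.
#' @export
split_dataset <- function(seqs, ratio = 0.8, seed = 1) {
  check_sequence_tbl(seqs)
  if (!(ratio > 0 && ratio < 1)) abort("`ratio` must lie strictly between 0 and 1.")
  counts <- table(seqs$label)
  if (any(counts < 2L)) abort("Each class needs at least 2 records to split.")

  idx <- withr::with_seed(seed, {
    unlist(lapply(split(seq_len(nrow(seqs)), seqs$label), function(i) {
      i <- sample(i)
      # round() guards against 1 - ratio not being exactly representable
      n_test <- floor(round((1 - ratio) * length(i), 9))
      # test records flagged negative; extra fractional record stays in train
      c(i[seq_len(length(i) - n_test)], -i[seq_len(n_test) + (length(i) - n_test)])
    }), use.names = FALSE)
  })
  train <- seqs[sort(idx[idx > 0]), , drop = FALSE]
  test <- seqs[sort(-idx[idx < 0]), , drop = FALSE]
  attr(train, "split") <- "train"
  attr(test, "split") <- "independent"
  list(train = train, test = test)
}

#' Write / apply a split manifest
#'
#' A split manifest is a small JSON file listing the record ids of each part,
#' so a train/independent partition can be reproduced exactly across runs.
#'
#' @param split A list with `train` and `test` tibbles, as returned by
#'   [split_dataset()].
#' @param path Manifest path (JSON).
#' @return `path` invisibly (`write_split_manifest`); a split list
#'   (`apply_split_manifest`).
#' @export
write_split_manifest <- function(split, path) {
  stopifnot(is.list(split), all(c("train", "test") %in% names(split)))
  jsonlite::write_json(
    list(train = split$train$id, test = split$test$id),
    path, auto_unbox = FALSE
  )
  invisible(path)
}

#' @rdname write_split_manifest
#' @param seqs Labeled sequence tibble to partition.
#' @export
apply_split_manifest <- function(seqs, path) {
  check_sequence_tbl(seqs, require_label = FALSE)
  manifest <- jsonlite::read_json(path, simplifyVector = TRUE)
  missing <- setdiff(c(manifest$train, manifest$test), seqs$id)
  if (length(missing) > 0L) {
    abort(paste0("Manifest ids absent from dataset: ", paste(head(missing, 5L), collapse = ", ")))
  }
  list(
    train = seqs[seqs$id %in% manifest$train, , drop = FALSE],
    test = seqs[seqs$id %in% manifest$test, , drop = FALSE]
  )
}

#' Read / write a feature matrix as TSV
#'
#' Feature matrices are tibbles with a `sample_id` column, an optional
#' `label` column (0/1), and one numeric column per feature, so selection
#' and modeling can also be run on externally produced matrices.
#'
#' @param features Feature tibble.
#' @param path TSV path.
#' @return `path` invisibly (`write_feature_matrix`); a feature tibble
#'   (`read_feature_matrix`).
#' @export
write_feature_matrix <- function(features, path) {
  check_feature_tbl(features, require_label = FALSE)
  readr::write_tsv(features, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  check_feature_tbl(out, require_label = FALSE)
  out
}

check_feature_tbl <- function(features, require_label = TRUE) {
  if (!is.data.frame(features) || !"sample_id" %in% names(features)) {
    abort("`features` must be a data frame with a `sample_id` column.")
  }
  ids <- feature_ids(features)
  if (length(ids) == 0L) abort("Feature matrix has no feature columns.")
  vals <- feature_values(features)
  if (!all(is.finite(vals))) abort("Feature values must all be finite.")
  if (require_label || "label" %in% names(features)) {
    if (!"label" %in% names(features)) abort("`features` must have a `label` column.")
    if (!all(features$label %in% c(0L, 1L))) abort("Labels must be 0 or 1.")
  }
  invisible(features)
}

#' Feature-column ids of a feature matrix
#'
#' @param features Feature tibble.
#' @return Character vector of feature column names (everything except
#'   `sample_id` and `label`).
#' @export
feature_ids <- function(features) {
  setdiff(names(features), c("sample_id", "label"))
}

# n x d numeric matrix of the feature columns
feature_values <- function(features) {
  m <- as.matrix(features[, feature_ids(features), drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- features$sample_id
  m
}
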