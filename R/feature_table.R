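#' Feature tables
#'
#' A feature table holds non-negative integer read counts of features
#' (typically amplicon sequence variants, ASVs) per sample. It is represented
#' as a tibble whose first column, `feature_id`, carries unique feature
#' identifiers and whose remaining columns are one integer count vector per
#' sample. The canonical on-disk layout is features-as-rows TSV with a
#' `#FeatureID` header (QIIME style); the transposed layout is accepted via
#' `orientation = "samples"`.
#'
#' @param path Path to a tab-separated file with a header row.
#' @param orientation `"features"` (rows are features, the default) or
#'   `"samples"` (rows are samples; the table is transposed on read).
#'
#' @return A validated feature-table tibble.
#' @export
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' ft <- feature_table(
#'   feature_id = c("ASV_1", "ASV_2"),
#'   S1 = c(5L, 1L), S2 = c(0L, 3L)
#' )
#' write_feature_table(ft, tf)
#' read_feature_table(tf)
read_feature_table <- function(path, orientation = c("features", "samples")) {
  orientation <- match.arg(orientation)
  header <- strsplit(readLines(path, n = 1), "\t", fixed = TRUE)[[1]]
  if (anyDuplicated(header[-1])) {
    abort(paste0("Duplicated ",
                 if (orientation == "features") "sample" else "feature",
                 " identifier(s) in '", basename(path), "': ",
                 paste(unique(header[-1][duplicated(header[-1])]), collapse = ", ")))
  }
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (ncol(raw) < 2) {
    abort("A feature table needs an identifier column plus at least one count column.")
  }
  ids <- raw[[1]]
  mat <- as.matrix(raw[-1])
  num <- suppressWarnings(array(as.numeric(mat), dim = dim(mat), dimnames = dimnames(mat)))
  if (anyNA(num)) {
    bad <- which(is.na(num) & !is.na(mat), arr.ind = TRUE)
    abort(paste0("Non-numeric count in '", basename(path), "' at row ",
                 bad[1, 1], ", column '", colnames(mat)[bad[1, 2]], "'."))
  }
  if (orientation == "samples") {
    num <- t(num)
    new_ids <- colnames(raw)[-1]
    colnames(num) <- ids
    ids <- new_ids
  }
  out <- tibble::tibble(feature_id = ids)
  out <- dplyr::bind_cols(out, tibble::as_tibble(num))
  validate_feature_table(out)
}

#' Construct a feature table from vectors
#'
#' @param feature_id Character vector of unique feature identifiers.
#' @param ... One named integer vector of counts per sample.
#' @return A validated feature-table tibble.
#' @export
feature_table <- function(feature_id, ...) {
  validate_feature_table(tibble::tibble(feature_id = as.character(feature_id), ...))
}

#' Validate a feature table
#'
#' Checks identifier uniqueness and that all counts are non-negative
#' integers. Called by all readers and constructors; exported so synthetic or
#' hand-built tables can be checked too.
#'
#' @param table A feature-table tibble (`feature_id` + count columns).
#' @return The table, invisibly unchanged, as a tibble.
#' @export
validate_feature_table <- function(table) {
  table <- tibble::as_tibble(table)
  if (names(table)[1] != "feature_id") {
    names(table)[1] <- "feature_id"
  }
  ids <- table$feature_id
  if (anyDuplicated(ids)) {
    abort(paste0("Duplicated feature identifier(s): ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  samples <- names(table)[-1]
  if (anyDuplicated(samples)) {
    abort(paste0("Duplicated sample identifier(s): ",
                 paste(unique(samples[duplicated(samples)]), collapse = ", ")))
  }
  counts <- counts_matrix(table)
  if (any(!is.finite(counts))) abort("Counts must be finite.")
  if (any(counts < 0)) abort("Counts must be non-negative.")
  if (any(counts != round(counts))) abort("Counts must be integers.")
  table
}

#' Write a feature table to TSV
#'
#' @param table A feature-table tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  table <- validate_feature_table(table)
  out <- table
  names(out)[1] <- "#FeatureID"
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Extract the count matrix of a feature table
#'
#' @param table A feature-table tibble.
#' @return A numeric matrix, features as rows, with dimnames.
#' @export
counts_matrix <- function(table) {
  m <- as.matrix(table[-1])
  mode(m) <- "numeric"
  rownames(m) <- table$feature_id
  m
}

#' Per-sample read depths
#'
#' @param table A feature-table tibble.
#' @return A tibble with `sample_id` and `depth` (column sums).
#' @export
sample_depths <- function(table) {
  m <- counts_matrix(table)
  tibble::tibble(sample_id = colnames(m), depth = unname(colSums(m)))
}

#' Subset a feature table to a set of samples
#'
#' @param table A feature-table tibble.
#' @param sample_ids Character vector of sample identifiers to keep.
#' @param drop_empty_features Drop features with zero total count afterwards?
#' @return A feature-table tibble.
#' @export
select_samples <- function(table, sample_ids, drop_empty_features = FALSE) {
  missing <- setdiff(sample_ids, names(table)[-1])
  if (length(missing)) {
    abort(paste0("Sample(s) not in table: ", paste(missing, collapse = ", ")))
  }
  out <- table[, c("feature_id", sample_ids)]
  if (drop_empty_features && length(sample_ids)) {
    keep <- rowSums(counts_matrix(out)) > 0
    out <- out[keep, ]
  }
  out
}
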