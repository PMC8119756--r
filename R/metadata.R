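#' Sample metadata
#'
#' Sample metadata links each sample to its class (`specimen` or
#' `field_control`), its sample type (e.g. `meconium`, `amnion`) and, for
#' specimens from paired designs, a pair identifier (e.g. the cow-calf
#' couple). Field controls are empty sampling instruments processed
#' alongside specimens; they anchor the contaminant filter.
#'
#' @param path Path to a TSV with columns `sample_id`, `sample_class`,
#'   `sample_type` and optionally `pair_id` (empty cells = unpaired).
#' @return A tibble with one row per sample; `pair_id` is `NA` when absent.
#' @export
read_sample_metadata <- function(path) {
  md <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  validate_sample_metadata(md)
}

#' @rdname read_sample_metadata
#' @param metadata A data frame to validate.
#' @export
validate_sample_metadata <- function(metadata) {
  metadata <- tibble::as_tibble(metadata)
  required <- c("sample_id", "sample_class", "sample_type")
  missing <- setdiff(required, names(metadata))
  if (length(missing)) {
    abort(paste0("Metadata is missing required column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (!"pair_id" %in% names(metadata)) metadata$pair_id <- NA_character_
  metadata$pair_id[metadata$pair_id %in% ""] <- NA_character_
  if (anyDuplicated(metadata$sample_id)) {
    abort("Duplicated sample_id in metadata.")
  }
  bad <- setdiff(unique(metadata$sample_class), c("specimen", "field_control"))
  if (length(bad)) {
    abort(paste0("Unknown sample_class value(s): ", paste(bad, collapse = ", "),
                 " (expected 'specimen' or 'field_control')."))
  }
  # a pair links at most one specimen per sample type
  paired <- metadata[!is.na(metadata$pair_id) & metadata$sample_class == "specimen", ]
  if (nrow(paired)) {
    dup <- paired |>
      dplyr::count(.data$pair_id, .data$sample_type) |>
      dplyr::filter(.data$n > 1)
    if (nrow(dup)) {
      abort(paste0("pair_id '", dup$pair_id[1], "' links more than one '",
                   dup$sample_type[1], "' specimen."))
    }
  }
  metadata[c("sample_id", "sample_class", "sample_type", "pair_id")]
}

#' @rdname read_sample_metadata
#' @param metadata A validated metadata tibble.
#' @export
write_sample_metadata <- function(metadata, path) {
  metadata <- validate_sample_metadata(metadata)
  readr::write_tsv(metadata, path, progress = FALSE)
  invisible(path)
}

#' Check that a table and its metadata agree
#'
#' Every sample column of the table must have exactly one metadata row.
#'
#' @param table A feature-table tibble.
#' @param metadata A metadata tibble.
#' @return The metadata rows for the table's samples, in table order.
#' @export
align_metadata <- function(table, metadata) {
  metadata <- validate_sample_metadata(metadata)
  samples <- names(table)[-1]
  missing <- setdiff(samples, metadata$sample_id)
  if (length(missing)) {
    abort(paste0("Sample(s) without metadata: ", paste(missing, collapse = ", ")))
  }
  metadata[match(samples, metadata$sample_id), ]
}
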