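#' Relative abundance profiles
#'
#' Divides each sample's counts by its read depth so every column sums to 1.
#'
#' @param table A feature-table tibble.
#' @return A tibble of the same shape with proportions instead of counts.
#' @export
relative_abundance <- function(table) {
  m <- as.matrix(table[-1]); mode(m) <- "numeric"
  depth <- colSums(m)
  if (any(depth == 0)) {
    abort(paste0("Zero-depth sample(s): ",
                 paste(names(table)[-1][depth == 0], collapse = ", ")))
  }
  dplyr::bind_cols(table[1], tibble::as_tibble(sweep(m, 2, depth, "/")))
}

#' Shannon diversity of a proportion vector
#'
#' `H = -sum(p_i * log(p_i))` over the positive entries, natural log.
#'
#' @param p Non-negative proportions summing to 1 (within `tol`).
#' @param tol Tolerance on the unit-sum check.
#' @return The Shannon index (natural-log units, "nats").
#' @export
#' @examples
#' shannon(rep(0.25, 4))  # log(4)
shannon <- function(p, tol = 1e-8) {
  if (any(p < 0)) abort("Proportions must be non-negative.")
  if (abs(sum(p) - 1) > tol) abort("Proportions must sum to 1.")
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Per-sample Shannon diversity of a feature table
#'
#' Computes the Shannon index for every sample of a (count or proportion)
#' feature table; counts are converted to proportions first. Typically run
#' on a genus-aggregated table ([aggregate_by_rank()]), without rarefaction.
#'
#' @param table A feature-table tibble.
#' @return A tibble with `sample_id` and `shannon`.
#' @export
shannon_diversity <- function(table) {
  rel <- relative_abundance(table)
  m <- as.matrix(rel[-1])
  tibble::tibble(sample_id = colnames(m),
                 shannon = unname(apply(m, 2, shannon)))
}
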