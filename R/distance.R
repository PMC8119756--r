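#' Bray-Curtis dissimilarity matrix
#'
#' `d(x, y) = 1 - 2 * sum(pmin(x, y)) / (sum(x) + sum(y))` for every pair of
#' samples. By default samples are converted to proportions first, so
#' unequal read depths do not masquerade as composition differences; set
#' `as_proportions = FALSE` to use raw counts.
#'
#' @param table A feature-table tibble (samples as columns).
#' @param as_proportions Normalise each sample to proportions first
#'   (default `TRUE`).
#' @return A `distance_matrix` object: a symmetric numeric matrix with zero
#'   diagonal and sample-id dimnames.
#' @export
#' @examples
#' ft <- feature_table(c("a", "b", "c"), S1 = c(1L, 1L, 0L), S2 = c(0L, 1L, 1L))
#' bray_curtis(ft)  # d(S1, S2) = 0.5
bray_curtis <- function(table, as_proportions = TRUE) {
  if (as_proportions) table <- relative_abundance(table)
  m <- as.matrix(table[-1]); mode(m) <- "numeric"
  n <- ncol(m)
  d <- matrix(0, n, n, dimnames = list(colnames(m), colnames(m)))
  tot <- colSums(m)
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      s <- tot[i] + tot[j]
      d[i, j] <- d[j, i] <- if (s == 0) 0 else 1 - 2 * sum(pmin(m[, i], m[, j])) / s
    }
  }
  new_distance_matrix(d)
}

new_distance_matrix <- function(d) {
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  structure(d, class = c("distance_matrix", "matrix"))
}

#' Coerce to a distance matrix
#'
#' Accepts a `dist` object or a symmetric matrix with zero diagonal.
#'
#' @param d A `dist`, matrix or `distance_matrix`.
#' @param tol Symmetry tolerance.
#' @return A `distance_matrix`.
#' @export
as_distance_matrix <- function(d, tol = 1e-10) {
  if (inherits(d, "distance_matrix")) return(d)
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (!is.matrix(d) || nrow(d) != ncol(d)) abort("Need a square matrix or dist.")
  if (max(abs(d - t(d))) > tol) abort("Distance matrix is not symmetric.")
  if (any(abs(diag(d)) > tol)) abort("Distance matrix diagonal must be zero.")
  if (any(d < -tol)) abort("Distances must be non-negative.")
  if (is.null(rownames(d))) {
    rownames(d) <- colnames(d) <- paste0("S", seq_len(nrow(d)))
  }
  d <- (d + t(d)) / 2
  diag(d) <- 0
  new_distance_matrix(d)
}

#' @export
print.distance_matrix <- function(x, ...) {
  cat(sprintf("distance_matrix: %d samples\n", nrow(x)))
  print(unclass(x), ...)
  invisible(x)
}

#' @method tidy distance_matrix
#' @export
tidy.distance_matrix <- function(x, ...) {
  n <- nrow(x)
  idx <- which(upper.tri(x), arr.ind = TRUE)
  tibble::tibble(sample_1 = rownames(x)[idx[, 1]],
                 sample_2 = colnames(x)[idx[, 2]],
                 distance = x[idx])
}

#' Write a distance matrix as TSV
#'
#' @param d A `distance_matrix`.
#' @param path Output path.
#' @export
write_distance_matrix <- function(d, path) {
  out <- tibble::as_tibble(unclass(d))
  out <- dplyr::bind_cols(tibble::tibble(sample_id = rownames(d)), out)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
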