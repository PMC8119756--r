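#' Principal coordinates analysis (classical metric scaling)
#'
#' Double-centres the squared distance matrix (`B = -1/2 J D^2 J` with
#' `J = I - 11'/n`), eigendecomposes `B`, and retains the
#' positive-eigenvalue axes; coordinates are eigenvectors scaled by the
#' square root of their eigenvalue. No correction is applied for negative
#' eigenvalues; `proportion_explained` is relative to the sum of positive
#' eigenvalues.
#'
#' @param d A `distance_matrix` (or anything [as_distance_matrix()] takes).
#' @param eig_tol Eigenvalues below `eig_tol * max(eigenvalue)` are treated
#'   as zero and not retained.
#' @return A `pcoa_result`: `eigenvalues` (all, descending), `coordinates`
#'   (tibble, `sample_id` + `Axis.1`, `Axis.2`, ...),
#'   `proportion_explained`, `negative_eigenvalues` (sum of magnitudes).
#' @export
pcoa <- function(d, eig_tol = 1e-9) {
  d <- as_distance_matrix(d)
  n <- nrow(d)
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% (unclass(d)^2) %*% J
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  pos <- e$values > eig_tol * max(abs(e$values), 1e-300)
  k <- sum(pos)
  coords <- if (k) {
    e$vectors[, seq_len(k), drop = FALSE] %*% diag(sqrt(e$values[seq_len(k)]), k)
  } else {
    matrix(0, n, 0)
  }
  colnames(coords) <- if (k) paste0("Axis.", seq_len(k)) else character()
  pos_sum <- sum(e$values[pos])
  structure(list(
    eigenvalues = e$values,
    coordinates = dplyr::bind_cols(tibble::tibble(sample_id = rownames(d)),
                                   tibble::as_tibble(coords)),
    proportion_explained = if (k) e$values[seq_len(k)] / pos_sum else numeric(),
    negative_eigenvalues = sum(abs(e$values[e$values < 0]))
  ), class = "pcoa_result")
}

#' @export
print.pcoa_result <- function(x, ...) {
  k <- length(x$proportion_explained)
  cat(sprintf("PCoA: %d samples, %d positive axes\n",
              nrow(x$coordinates), k))
  if (k) {
    cat("  proportion explained:",
        paste0(sprintf("%.1f%%", 100 * head(x$proportion_explained, 3)),
               collapse = ", "),
        if (k > 3) "..." else "", "\n")
  }
  invisible(x)
}

#' @method tidy pcoa_result
#' @export
tidy.pcoa_result <- function(x, ...) x$coordinates

#' @method glance pcoa_result
#' @export
glance.pcoa_result <- function(x, ...) {
  tibble::tibble(n_samples = nrow(x$coordinates),
                 n_axes = length(x$proportion_explained),
                 prop_axis1 = x$proportion_explained[1],
                 prop_axis2 = if (length(x$proportion_explained) > 1)
                   x$proportion_explained[2] else NA_real_,
                 negative_eigenvalue_mass = x$negative_eigenvalues)
}

#' Ordination scatter plot
#'
#' @param object A `pcoa_result`.
#' @param metadata Optional sample metadata to colour points by sample type
#'   and shape by sample class.
#' @param ... Unused.
#' @method autoplot pcoa_result
#' @export
autoplot.pcoa_result <- function(object, metadata = NULL, ...) {
  df <- object$coordinates
  if (ncol(df) < 3) abort("Need at least two positive axes to plot.")
  if (!is.null(metadata)) {
    df <- dplyr::left_join(df, validate_sample_metadata(metadata), by = "sample_id")
  }
  pe <- object$proportion_explained
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$Axis.1, y = .data$Axis.2)) +
    ggplot2::labs(x = sprintf("Axis 1 (%.1f%%)", 100 * pe[1]),
                  y = sprintf("Axis 2 (%.1f%%)", 100 * pe[2])) +
    ggplot2::theme_minimal()
  if (!is.null(metadata)) {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$sample_type,
                                         shape = .data$sample_class), size = 2)
  } else {
    p + ggplot2::geom_point(size = 2)
  }
}
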