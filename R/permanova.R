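# Sum over groups of (1/n_g) * sum_{i<j in g} d_ij^2, for each column of a
# label matrix (one permutation per column), via indicator algebra.
ss_within_perms <- function(D2, label_mat) {
  groups <- unique(as.vector(label_mat[, 1]))
  out <- numeric(ncol(label_mat))
  for (g in groups) {
    I <- (label_mat == g) * 1
    ng <- colSums(I)
    out <- out + colSums((D2 %*% I) * I) / (2 * ng)
  }
  out
}

#' PERMANOVA on a distance matrix
#'
#' One-way permutational multivariate analysis of variance. With `n` samples
#' in `g` groups: `SS_total = (1/n) sum_{i<j} d_ij^2`, `SS_within = sum_g
#' (1/n_g) sum_{i<j in g} d_ij^2`, pseudo-F `= ((SS_total - SS_within) /
#' (g - 1)) / (SS_within / (n - g))` and `R^2 = 1 - SS_within / SS_total`.
#' The p-value uses unrestricted label permutations: `p = (#\{F* >= F\} + 1)
#' / (n_perm + 1)`. With `n_perm = "exact"` (two groups only) all distinct
#' label arrangements are enumerated and `p` is the exact proportion with
#' `F* >= F`, observed arrangement included.
#'
#' @param d A `distance_matrix` (or coercible).
#' @param labels Group label per sample (character or factor), in the order
#'   of the distance matrix.
#' @param n_perm Number of Monte Carlo permutations (default 9999), or
#'   `"exact"` for full enumeration.
#' @param seed Integer seed for the permutations (default 1; recorded in
#'   the result).
#' @return A `permanova_result`: `pseudo_f`, `r_squared`, `p_value`,
#'   `n_permutations`, `seed`, `ss_total`, `ss_within`, `df`.
#' @export
permanova <- function(d, labels, n_perm = 9999, seed = 1) {
  d <- as_distance_matrix(d)
  n <- nrow(d)
  labels <- as.character(labels)
  if (length(labels) != n) abort("One label per sample is required.")
  groups <- unique(labels)
  g <- length(groups)
  if (g < 2) abort("PERMANOVA needs at least two groups.")
  if (n <= g) abort("PERMANOVA needs more samples than groups.")
  D2 <- unclass(d)^2
  ss_total <- sum(D2[upper.tri(D2)]) / n
  obs <- ss_within_perms(D2, matrix(labels, ncol = 1))
  pseudo_f_of <- function(ssw) ((ss_total - ssw) / (g - 1)) / (ssw / (n - g))
  degenerate <- ss_total <= 0 || obs <= 0
  f_obs <- if (degenerate) 0 else pseudo_f_of(obs)
  if (identical(n_perm, "exact")) {
    if (g != 2) abort("Exact enumeration is implemented for two groups only.")
    n1 <- sum(labels == groups[1])
    idx <- combn(n, n1)
    lab_mat <- matrix(groups[2], n, ncol(idx))
    lab_mat[cbind(as.vector(idx), rep(seq_len(ncol(idx)), each = n1))] <- groups[1]
    ssw <- ss_within_perms(D2, lab_mat)
    f_perm <- if (degenerate) rep(0, length(ssw)) else pseudo_f_of(ssw)
    p <- if (degenerate) 1 else mean(f_perm >= f_obs - 1e-12)
    n_used <- ncol(idx)
  } else {
    lab_mat <- withr::with_seed(seed,
      replicate(n_perm, sample(labels)))
    ssw <- ss_within_perms(D2, lab_mat)
    f_perm <- if (degenerate) rep(0, n_perm) else pseudo_f_of(ssw)
    p <- if (degenerate) 1 else (sum(f_perm >= f_obs - 1e-12) + 1) / (n_perm + 1)
    n_used <- n_perm
  }
  structure(list(pseudo_f = f_obs,
                 r_squared = if (ss_total > 0) 1 - obs / ss_total else 0,
                 p_value = p, n_permutations = n_used, seed = seed,
                 ss_total = ss_total, ss_within = obs,
                 df = c(between = g - 1, within = n - g)),
            class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf("PERMANOVA: pseudo-F = %.4g (df %d, %d), R^2 = %.4f, p = %.4g (%d permutations)\n",
              x$pseudo_f, x$df[1], x$df[2], x$r_squared, x$p_value,
              x$n_permutations))
  invisible(x)
}

#' @method tidy permanova_result
#' @export
tidy.permanova_result <- function(x, ...) {
  tibble::tibble(pseudo_f = x$pseudo_f, r_squared = x$r_squared,
                 p_value = x$p_value, df_between = x$df[[1]],
                 df_within = x$df[[2]], n_permutations = x$n_permutations,
                 seed = x$seed)
}

#' @method glance permanova_result
#' @export
glance.permanova_result <- function(x, ...) tidy.permanova_result(x, ...)

#' Homogeneity of multivariate group dispersions
#'
#' Embeds the samples by [pcoa()] (positive-eigenvalue axes only), computes
#' each sample's Euclidean distance `z_i` to its group centroid in that
#' space, and tests equality of mean dispersion with the one-way ANOVA F
#' statistic on `z`, with a permutation p-value obtained by permuting the
#' dispersions across samples. Negative-eigenvalue bookkeeping (imaginary
#' axes) is deliberately not performed.
#'
#' @inheritParams permanova
#' @return A `permdisp_result`: `f_statistic`, `p_value`, `group_means`
#'   (mean distance to centroid per group), `distances` (per sample),
#'   `n_permutations`, `seed`.
#' @export
permdisp <- function(d, labels, n_perm = 9999, seed = 1) {
  d <- as_distance_matrix(d)
  n <- nrow(d)
  labels <- as.character(labels)
  if (length(labels) != n) abort("One label per sample is required.")
  groups <- unique(labels)
  if (length(groups) < 2) abort("permdisp needs at least two groups.")
  sizes <- table(labels)
  if (any(sizes < 2)) {
    abort("permdisp needs at least two samples per group (single-member groups have no dispersion).")
  }
  ord <- pcoa(d)
  coords <- as.matrix(ord$coordinates[-1])
  z <- numeric(n)
  for (g in groups) {
    i <- labels == g
    centroid <- colMeans(coords[i, , drop = FALSE])
    z[i] <- sqrt(rowSums(sweep(coords[i, , drop = FALSE], 2, centroid)^2))
  }
  f_of <- function(zz) {
    gm <- tapply(zz, labels, mean)
    ng <- as.vector(sizes[names(gm)])
    ss_b <- sum(ng * (gm - mean(zz))^2)
    ss_w <- sum((zz - gm[labels])^2)
    if (ss_w <= 1e-300) {
      if (ss_b <= 1e-300) 0 else Inf
    } else {
      (ss_b / (length(groups) - 1)) / (ss_w / (n - length(groups)))
    }
  }
  f_obs <- f_of(z)
  if (all(z == 0)) {
    f_obs <- 0
    p <- 1
  } else {
    f_perm <- withr::with_seed(seed,
      replicate(n_perm, f_of(sample(z))))
    p <- (sum(f_perm >= f_obs - 1e-12) + 1) / (n_perm + 1)
  }
  structure(list(f_statistic = f_obs, p_value = p,
                 group_means = tapply(z, labels, mean),
                 distances = tibble::tibble(sample_id = rownames(d),
                                            group = labels, distance = z),
                 n_permutations = n_perm, seed = seed),
            class = "permdisp_result")
}

#' @export
print.permdisp_result <- function(x, ...) {
  cat(sprintf("Dispersion homogeneity: F = %.4g, p = %.4g (%d permutations)\n",
              x$f_statistic, x$p_value, x$n_permutations))
  gm <- x$group_means
  cat("  mean distance to centroid:",
      paste(sprintf("%s = %.4g", names(gm), gm), collapse = ", "), "\n")
  invisible(x)
}

#' @method tidy permdisp_result
#' @export
tidy.permdisp_result <- function(x, ...) {
  tibble::tibble(group = names(x$group_means),
                 mean_distance = as.vector(x$group_means))
}

#' @method glance permdisp_result
#' @export
glance.permdisp_result <- function(x, ...) {
  tibble::tibble(f_statistic = x$f_statistic, p_value = x$p_value,
                 n_permutations = x$n_permutations, seed = x$seed)
}
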