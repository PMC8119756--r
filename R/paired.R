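#' Features abundant across two paired tables
#'
#' Selects the features whose summed count across ALL samples of both
#' tables is strictly greater than `min_total` (`mode = "total"`, default),
#' or which exceed `min_total` in every single sample (`mode =
#' "per_sample"`). Features present in only one table count as zero in the
#' other.
#'
#' @param table_a,table_b Feature-table tibbles sharing a feature space.
#' @param min_total Count threshold (strict `>`), default 100.
#' @param mode `"total"` or `"per_sample"`.
#' @return Character vector of retained feature identifiers.
#' @export
select_shared_features <- function(table_a, table_b, min_total = 100,
                                   mode = c("total", "per_sample")) {
  mode <- match.arg(mode)
  shared_space <- union(table_a$feature_id, table_b$feature_id)
  if (!length(intersect(table_a$feature_id, table_b$feature_id))) {
    warn("The two tables share no features; returning an empty selection.")
    return(character())
  }
  ma <- counts_matrix(table_a)
  mb <- counts_matrix(table_b)
  grid <- function(m) {
    out <- matrix(0, length(shared_space), ncol(m),
                  dimnames = list(shared_space, colnames(m)))
    out[rownames(m), ] <- m
    out
  }
  m <- cbind(grid(ma), grid(mb))
  keep <- if (mode == "total") rowSums(m) > min_total else
    apply(m, 1, function(r) all(r > min_total))
  shared_space[keep]
}

# Spearman rho on midranks; exact permutation p for k <= `exact_max`
# distinct orderings, t-approximation otherwise.
spearman_pair <- function(x, y, exact_max = 8) {
  k <- length(x)
  if (sd(x) == 0 || sd(y) == 0) {
    return(list(rho = NA_real_, p = NA_real_, constant = TRUE))
  }
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (k <= exact_max) {
    perms <- permutations_of(k)
    rhos <- apply(perms, 1, function(pm) stats::cor(rx, ry[pm]))
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
  } else {
    tstat <- rho * sqrt((k - 2) / (1 - rho^2))
    p <- 2 * pt(-abs(tstat), df = k - 2)
  }
  list(rho = rho, p = min(1, p), constant = FALSE)
}

# All k! permutations of 1..k as rows (k <= 8 in practice).
permutations_of <- function(k) {
  if (k == 1) return(matrix(1L, 1, 1))
  sub <- permutations_of(k - 1L)
  do.call(rbind, lapply(seq_len(k), function(i) {
    cbind(i, sub + (sub >= i))
  }))
}

#' Paired Spearman correlations between two sample types
#'
#' For each pair (e.g. a cow-calf couple with one meconium and one amniotic
#' fluid sample), computes the Spearman rank correlation between the two
#' absolute count vectors over a selected feature set
#' ([select_shared_features()]), with a Bonferroni correction across pairs
#' (`m` = number of pairs tested). Pairs where either vector is constant
#' have no defined rank correlation; they are flagged and excluded from the
#' average rho.
#'
#' @param table_a,table_b Feature-table tibbles for the two sample types.
#' @param metadata Sample metadata supplying `pair_id` for the samples of
#'   both tables.
#' @param features Feature identifiers to correlate over (e.g. from
#'   [select_shared_features()]); defaults to all shared features.
#' @param exact_max Use exact permutation p-values when the feature count
#'   is at most this (default 8); t-approximation above.
#' @return A tibble with one row per pair: `pair_id`, `sample_a`,
#'   `sample_b`, `n_features`, `rho`, `p_raw`, `p_bonferroni`, `constant`.
#'   The arithmetic mean of the defined rhos is attached as attribute
#'   `"rho_avg"` (also via [rho_average()]).
#' @export
paired_spearman <- function(table_a, table_b, metadata, features = NULL,
                            exact_max = 8) {
  md <- validate_sample_metadata(metadata)
  if (is.null(features)) {
    features <- intersect(table_a$feature_id, table_b$feature_id)
  }
  if (!length(features)) abort("No features selected for correlation.")
  ma <- counts_matrix(table_a)
  mb <- counts_matrix(table_b)
  get <- function(m, ids) {
    out <- matrix(0, length(features), length(ids),
                  dimnames = list(features, ids))
    have <- intersect(features, rownames(m))
    out[have, ] <- m[have, ids]
    out
  }
  pa <- md[md$sample_id %in% colnames(ma) & !is.na(md$pair_id), ]
  pb <- md[md$sample_id %in% colnames(mb) & !is.na(md$pair_id), ]
  pairs <- intersect(pa$pair_id, pb$pair_id)
  if (!length(pairs)) abort("No complete pairs across the two tables.")
  ma <- get(ma, pa$sample_id[match(pairs, pa$pair_id)])
  mb <- get(mb, pb$sample_id[match(pairs, pb$pair_id)])
  rows <- purrr::map(seq_along(pairs), function(i) {
    r <- spearman_pair(ma[, i], mb[, i], exact_max = exact_max)
    tibble::tibble(pair_id = pairs[i],
                   sample_a = colnames(ma)[i], sample_b = colnames(mb)[i],
                   n_features = length(features),
                   rho = r$rho, p_raw = r$p, constant = r$constant)
  })
  out <- dplyr::bind_rows(rows)
  out$p_bonferroni <- pmin(1, out$p_raw * length(pairs))
  out <- out[c("pair_id", "sample_a", "sample_b", "n_features",
               "rho", "p_raw", "p_bonferroni", "constant")]
  attr(out, "rho_avg") <- mean(out$rho[!out$constant])
  out
}

#' Average paired correlation
#'
#' @param paired The tibble returned by [paired_spearman()].
#' @return Arithmetic mean of the defined per-pair rhos.
#' @export
rho_average <- function(paired) {
  a <- attr(paired, "rho_avg")
  if (!is.null(a)) a else mean(paired$rho[!paired$constant])
}
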