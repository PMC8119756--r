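# Shared fixtures and independent oracles used across test files.

# A tiny two-type study: 4 meconium specimens + 2 controls, 2 amnion
# specimens + 1 control.
toy_metadata <- function() {
  tibble::tibble(
    sample_id = c("M1", "M2", "M3", "M4", "MC1", "MC2", "A1", "A2", "AC1"),
    sample_class = c(rep("specimen", 4), rep("field_control", 2),
                     rep("specimen", 2), "field_control"),
    sample_type = c(rep("meconium", 6), rep("amnion", 3)),
    pair_id = c("c1", "c2", "c3", "c4", NA, NA, "c1", "c2", NA))
}

# Random feature table + matching single-type metadata for property tests.
random_table <- function(n_features, n_samples, n_controls, max_count = 50,
                         sparsity = 0.5) {
  m <- matrix(
    ifelse(stats::runif(n_features * n_samples) < sparsity, 0,
           sample.int(max_count, n_features * n_samples, replace = TRUE)),
    n_features, n_samples)
  ids <- paste0("F", seq_len(n_features))
  cols <- paste0("S", seq_len(n_samples))
  tbl <- dplyr::bind_cols(
    tibble::tibble(feature_id = ids),
    tibble::as_tibble(matrix(as.integer(m), n_features, n_samples,
                             dimnames = list(NULL, cols))))
  md <- tibble::tibble(
    sample_id = cols,
    sample_class = c(rep("specimen", n_samples - n_controls),
                     rep("field_control", n_controls)),
    sample_type = "meconium", pair_id = NA_character_)
  list(table = tbl, metadata = md)
}

# Brute-force oracle for the contaminant filter: evaluates the two
# inequalities feature by feature with plain loops, independent of the
# vectorised implementation.
oracle_removed <- function(table, metadata, prevalence_ratio = 2,
                           abundance_ratio = 10, presence_threshold = 1) {
  m <- counts_matrix(table)
  spec <- metadata$sample_id[metadata$sample_class == "specimen"]
  ctrl <- metadata$sample_id[metadata$sample_class == "field_control"]
  removed <- character()
  for (f in rownames(m)) {
    prev <- function(ids) {
      hits <- 0
      for (s in ids) if (m[f, s] >= presence_threshold) hits <- hits + 1
      hits / length(ids)
    }
    mra <- function(ids) {
      vals <- numeric(0)
      for (s in ids) {
        depth <- sum(m[, s])
        vals <- c(vals, if (depth > 0) m[f, s] / depth else 0)
      }
      mean(vals)
    }
    crit1 <- prev(spec) <= prevalence_ratio * prev(ctrl)
    crit2 <- mra(spec) <= abundance_ratio * mra(ctrl)
    if (crit1 && crit2) removed <- c(removed, f)
  }
  removed
}

# Distance matrix of a Euclidean point cloud (rows = points).
euclidean_distances <- function(points) {
  as_distance_matrix(as.matrix(stats::dist(points)))
}
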