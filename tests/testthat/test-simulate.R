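small_config <- function(seed = 1, k_contaminant = 20, k_signal = 10, ...) {
  simulation_config(seed = seed, n_pairs = 6,
                    n_controls = c(meconium = 3, amnion = 3),
                    k_contaminant = k_contaminant, k_signal = k_signal, ...)
}

test_that("the same seed reproduces the study byte for byte", {
  a <- simulate_study(small_config(seed = 33))
  b <- simulate_study(small_config(seed = 33))
  expect_identical(a$table, b$table)
  expect_identical(a$metadata, b$metadata)
  expect_identical(a$qpcr, b$qpcr)
  c <- simulate_study(small_config(seed = 34))
  expect_false(identical(a$table, c$table))
})

test_that("generated studies satisfy the table and metadata invariants", {
  sim <- simulate_study(small_config(seed = 35))
  expect_silent(validate_feature_table(sim$table))
  expect_silent(validate_sample_metadata(sim$metadata))
  expect_equal(nrow(align_metadata(sim$table, sim$metadata)),
               ncol(sim$table) - 1)
  # every feature labelled exactly once
  expect_setequal(sim$ground_truth$feature_id, sim$table$feature_id)
  expect_true(all(sim$ground_truth$truth %in% c("contaminant", "signal")))
  # field controls carry no signal load
  ctrl <- sim$metadata$sample_id[sim$metadata$sample_class == "field_control"]
  expect_equal(sim$true_loads$signal_load[sim$true_loads$sample_id %in% ctrl],
               rep(0, length(ctrl)))
  # and no signal counts at all
  sig <- sim$ground_truth$feature_id[sim$ground_truth$truth == "signal"]
  m <- counts_matrix(sim$table)
  expect_equal(sum(m[sig, ctrl]), 0)
})

test_that("signal can leak into controls only when requested", {
  leaky <- simulate_study(small_config(seed = 36, signal_leak = 0.5,
                                       signal_presence_prob = 0.8))
  ctrl <- leaky$metadata$sample_id[leaky$metadata$sample_class == "field_control"]
  sig <- leaky$ground_truth$feature_id[leaky$ground_truth$truth == "signal"]
  expect_gt(sum(counts_matrix(leaky$table)[sig, ctrl]), 0)
})

test_that("read depths track the configured lognormal means", {
  # pool specimens over replicate small studies: ~102 meconium specimens
  depths <- unlist(lapply(1:17, function(i) {
    sim <- simulate_study(small_config(seed = 400 + i))
    md <- sim$metadata
    sample_depths(sim$table)$depth[md$sample_type == "meconium" &
                                     md$sample_class == "specimen"]
  }))
  se <- sd(depths) / sqrt(length(depths))
  expect_lt(abs(mean(depths) - 92266), 3 * se)
})

test_that("with no signal taxa the filter removes essentially everything", {
  sim <- simulate_study(small_config(seed = 37, k_signal = 0))
  rep <- apply_decontamination(sim$table, sim$metadata,
                               decontam_params(min_sample_reads = 0))
  st <- rep$stats
  # all features are contaminants with matched composition in both groups
  expect_gt(mean(st$removed), 0.95)
  expect_true(all(sim$ground_truth$truth == "contaminant"))
})

test_that("zero-copy qPCR null: no signal means exchangeable groups", {
  cf <- small_config(seed = 38, k_signal = 0)
  expect_equal(unname(cf$qpcr_signal_scale), c(0, 0))
  sim <- simulate_study(cf)
  q <- dplyr::inner_join(sim$qpcr, sim$metadata, by = "sample_id")
  mec <- q[q$sample_type == "meconium", ]
  res <- mann_whitney_u(mec$copies[mec$sample_class == "specimen"],
                        mec$copies[mec$sample_class == "field_control"])
  expect_gt(res$p_two_tailed, 0.001)  # no systematic separation
})

test_that("a contaminant-free configuration with controls is rejected", {
  expect_error(small_config(k_contaminant = 0), "controls would be empty")
})

test_that("simulated studies round-trip through the plain-text writers", {
  sim <- simulate_study(small_config(seed = 39))
  dir <- withr::local_tempdir()
  paths <- write_simulated_study(sim, dir)
  expect_equal(read_feature_table(paths[["table"]]), sim$table)
  expect_equal(read_sample_metadata(paths[["metadata"]]), sim$metadata)
  expect_equal(read_taxonomy(paths[["taxonomy"]]), sim$taxonomy)
})

test_that("distinct signal pools separate sample types; identical pools do not", {
  sim <- simulate_study(simulation_config(seed = 44, n_pairs = 10,
                                          n_controls = c(meconium = 3, amnion = 3),
                                          k_contaminant = 25, k_signal = 12,
                                          signal_overlap = 0,
                                          signal_presence_prob = 0.5))
  rep <- apply_decontamination(sim$table, sim$metadata,
                               decontam_params(min_sample_reads = 50))
  merged <- dplyr::full_join(rep$retained$meconium, rep$retained$amnion,
                             by = "feature_id")
  merged[is.na(merged)] <- 0
  merged <- merged[rowSums(counts_matrix(merged)) > 0, ]
  md <- align_metadata(merged, sim$metadata)
  res <- permanova(bray_curtis(merged), md$sample_type, n_perm = 999, seed = 8)
  expect_lte(res$p_value, 0.01)
})
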