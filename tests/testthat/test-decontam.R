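# Build a single-type table whose per-group prevalences and mean relative
# abundances are exactly controlled, to pin the filter criteria by hand.
two_group_table <- function(spec_cols, ctrl_cols) {
  n_spec <- ncol(spec_cols); n_ctrl <- ncol(ctrl_cols)
  ids <- rownames(spec_cols)
  if (is.null(ids)) ids <- paste0("f", seq_len(nrow(spec_cols)))
  tbl <- dplyr::bind_cols(
    tibble::tibble(feature_id = ids),
    tibble::as_tibble(matrix(as.integer(cbind(spec_cols, ctrl_cols)),
                             nrow(spec_cols),
                             dimnames = list(NULL, c(paste0("S", 1:n_spec),
                                                     paste0("C", 1:n_ctrl))))))
  md <- tibble::tibble(
    sample_id = c(paste0("S", 1:n_spec), paste0("C", 1:n_ctrl)),
    sample_class = c(rep("specimen", n_spec), rep("field_control", n_ctrl)),
    sample_type = "meconium", pair_id = NA_character_)
  list(table = tbl, metadata = md)
}

test_that("both criteria together decide removal (hand-evaluated cases)", {
  # f1: in 4/4 specimens and 2/2 controls, relabund 0.05 vs 0.04 -> removed
  # f2: absent from controls, present in specimens -> retained (zero-control)
  # f3: prevalence met (4/4 vs 2/2) but 0.20 > 10 x 0.01 -> retained
  spec <- rbind(f1 = rep(5L, 4), f2 = rep(10L, 4), f3 = rep(20L, 4),
                fill = rep(65L, 4))
  ctrl <- rbind(f1 = rep(4L, 2), f2 = rep(0L, 2), f3 = rep(1L, 2),
                fill = rep(95L, 2))
  tg <- two_group_table(spec, ctrl)
  st <- compute_contam_stats(tg$table, tg$metadata, "meconium")
  expect_equal(st$mean_relabund_specimen[1:3], c(0.05, 0.10, 0.20))
  expect_equal(st$mean_relabund_control[1:3], c(0.04, 0.00, 0.01))
  expect_equal(st$prev_specimen[1:3], c(1, 1, 1))
  expect_equal(st$prev_control[1:3], c(1, 0, 1))
  expect_equal(st$removed[1:3], c(TRUE, FALSE, FALSE))
  expect_equal(st$removed, st$prevalence_criterion & st$abundance_criterion)
})

test_that("a feature in 4/4 specimens but 1/2 controls sits on the prevalence boundary", {
  # prev_s = 1.0 <= 2 x 0.5 holds with equality; abundance decides
  spec <- rbind(f1 = rep(20L, 4), fill = rep(80L, 4))
  ctrl <- rbind(f1 = c(2L, 0L), fill = c(98L, 100L))
  tg <- two_group_table(spec, ctrl)
  st <- compute_contam_stats(tg$table, tg$metadata, "meconium")
  expect_true(st$prevalence_criterion[1])
  expect_equal(st$mean_relabund_specimen[1], 0.20)
  expect_equal(st$mean_relabund_control[1], 0.01)
  expect_false(st$abundance_criterion[1])  # 0.20 > 10 x 0.01
  expect_false(st$removed[1])
})

test_that("errors when a group is missing and OR logic widens removals", {
  # f2 is in 1/2 controls (prevalence criterion holds) but 10x more
  # abundant in specimens (abundance criterion fails): AND retains, OR removes
  spec <- rbind(f1 = rep(5L, 3), f2 = rep(50L, 3))
  ctrl <- rbind(f1 = rep(5L, 2), f2 = c(1L, 0L))
  tg <- two_group_table(spec, ctrl)
  expect_error(compute_contam_stats(tg$table, tg$metadata, "amnion"),
               "No specimens")
  only_spec <- tg$metadata
  only_spec$sample_class <- "specimen"
  expect_error(compute_contam_stats(tg$table, only_spec, "meconium"),
               "field controls")
  st_and <- compute_contam_stats(tg$table, tg$metadata, "meconium")
  st_or <- compute_contam_stats(tg$table, tg$metadata, "meconium",
                                decontam_params(logic = "or"))
  expect_true(all(st_or$removed >= st_and$removed))
  expect_gt(sum(st_or$removed), sum(st_and$removed))
})

test_that("sample dropout applies the strict <500 rule after feature removal", {
  # two specimens: one lands on 499 reads post-filter, one on exactly 500
  spec <- rbind(contam = c(2L, 1L), keep = c(499L, 500L))
  ctrl <- rbind(contam = c(50L, 50L), keep = c(0L, 0L))
  tg <- two_group_table(spec, ctrl)
  rep <- apply_decontamination(tg$table, tg$metadata)
  expect_equal(removed_features(rep), "contam")
  acc <- rep$samples
  expect_equal(acc$reads_after, c(499, 500))
  expect_equal(acc$dropped, c(TRUE, FALSE))
  expect_equal(names(rep$retained$meconium)[-1], "S2")
  expect_true(all(acc$reads_after <= acc$reads_before))
})

test_that("a table with nothing removable passes through identically", {
  spec <- rbind(f1 = c(600L, 700L), f2 = c(500L, 400L))
  ctrl <- rbind(f1 = c(0L, 0L), f2 = c(0L, 0L))
  # controls with zero depth for all features: nothing can be removed
  tg <- two_group_table(spec, ctrl)
  rep <- apply_decontamination(tg$table, tg$metadata)
  expect_equal(length(removed_features(rep)), 0L)
  expect_equal(counts_matrix(rep$retained$meconium),
               counts_matrix(select_samples(tg$table, c("S1", "S2"))))
  expect_false(any(rep$samples$dropped))
})

test_that("removal set matches the brute-force oracle on random tables", {
  withr::local_seed(42)
  for (i in 1:200) {
    n_feat <- sample(2:30, 1)
    n_samp <- sample(3:10, 1)
    n_ctrl <- sample(1:(n_samp - 1), 1)
    rt <- random_table(n_feat, n_samp, n_ctrl)
    st <- compute_contam_stats(rt$table, rt$metadata, "meconium")
    expect_equal(sort(st$feature_id[st$removed]),
                 sort(oracle_removed(rt$table, rt$metadata)))
  }
})

test_that("features absent from every control are never removed", {
  withr::local_seed(7)
  for (i in 1:50) {
    rt <- random_table(sample(2:25, 1), 8, 3)
    st <- compute_contam_stats(rt$table, rt$metadata, "meconium")
    zero_ctrl <- st$prev_control == 0 & st$prev_specimen > 0
    expect_false(any(st$removed[zero_ctrl]))
  }
})

test_that("loosening either ratio never shrinks the removal set", {
  withr::local_seed(99)
  for (i in 1:30) {
    rt <- random_table(20, 8, 3)
    base <- compute_contam_stats(rt$table, rt$metadata, "meconium",
                                 decontam_params())
    for (p in list(decontam_params(prevalence_ratio = 5),
                   decontam_params(abundance_ratio = 40),
                   decontam_params(prevalence_ratio = 5, abundance_ratio = 40))) {
      looser <- compute_contam_stats(rt$table, rt$metadata, "meconium", p)
      expect_true(all(looser$removed >= base$removed))
    }
  }
})

test_that("filtering is per sample type, deterministic, and single-pass", {
  withr::local_seed(5)
  sim <- simulate_study(simulation_config(seed = 5, n_pairs = 6,
                                          n_controls = c(meconium = 3, amnion = 3),
                                          k_contaminant = 20, k_signal = 10))
  r1 <- apply_decontamination(sim$table, sim$metadata)
  r2 <- apply_decontamination(sim$table, sim$metadata)
  expect_identical(r1$stats, r2$stats)
  expect_identical(r1$retained, r2$retained)
  # per-type stats equal stats computed on that type's columns alone
  md <- sim$metadata
  mec_ids <- md$sample_id[md$sample_type == "meconium"]
  solo <- compute_contam_stats(select_samples(sim$table, mec_ids),
                               md[md$sample_id %in% mec_ids, ], "meconium")
  joint <- r1$stats[r1$stats$sample_type == "meconium", names(solo)]
  expect_equal(tibble::as_tibble(joint), solo)
  # single-pass: re-running the filter on the pre-dropout table can only
  # remove more, never resurrect a removed feature
  expect_true(all(removed_features(r1, "meconium") %in% sim$table$feature_id))
})

test_that("drop_singletons removes exactly total-count-one features", {
  ft <- feature_table(c("a", "b", "c"), S1 = c(1L, 0L, 5L), S2 = c(0L, 1L, 0L))
  expect_equal(drop_singletons(ft)$feature_id, "c")
})
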