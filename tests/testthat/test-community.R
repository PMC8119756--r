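test_that("relative abundance normalises every sample to 1", {
  ft <- feature_table(c("a", "b", "c"), S1 = c(2L, 3L, 5L), S2 = c(0L, 0L, 4L))
  rel <- relative_abundance(ft)
  expect_equal(rel$S1, c(0.2, 0.3, 0.5))
  expect_equal(rel$S2, c(0, 0, 1))
  withr::local_seed(2)
  rt <- random_table(15, 6, 2, sparsity = 0.3)$table
  rt[1, -1] <- as.list(rep(1L, 6))  # guard against zero-depth columns
  expect_equal(unname(colSums(counts_matrix(relative_abundance(rt)))),
               rep(1, 6))
  zero <- feature_table("a", S1 = 1L, S2 = 0L)
  expect_error(relative_abundance(zero), "S2")
})

test_that("Shannon index matches closed forms and vegan", {
  expect_equal(shannon(rep(1 / 4, 4)), log(4))
  expect_equal(shannon(1), 0)
  expect_equal(shannon(c(0.5, 0.25, 0.25)), 1.5 * log(2))
  expect_error(shannon(c(-0.1, 1.1)), "non-negative")
  expect_error(shannon(c(0.3, 0.3)), "sum to 1")
  withr::local_seed(4)
  rt <- random_table(20, 5, 2, sparsity = 0.2)$table
  rt[1, -1] <- as.list(rep(1L, 5))
  mine <- shannon_diversity(rt)$shannon
  ref <- vegan::diversity(t(counts_matrix(rt)), index = "shannon")
  expect_equal(mine, unname(ref), tolerance = 1e-12)
})

test_that("aggregation can only decrease Shannon diversity", {
  sim <- simulate_study(simulation_config(seed = 13, n_pairs = 4,
                                          n_controls = c(meconium = 2, amnion = 2),
                                          k_contaminant = 20, k_signal = 10))
  before <- shannon_diversity(sim$table)
  for (r in c("genus", "family", "phylum")) {
    after <- shannon_diversity(aggregate_by_rank(sim$table, sim$taxonomy, r))
    expect_true(all(after$shannon <= before$shannon + 1e-12))
  }
})

test_that("Bray-Curtis matches closed forms, bounds and vegan", {
  ft <- feature_table(c("a", "b", "c"),
                      S1 = c(1L, 1L, 0L), S2 = c(0L, 1L, 1L), S3 = c(1L, 1L, 0L))
  d <- bray_curtis(ft)
  expect_equal(d["S1", "S2"], 0.5)    # (0.5,0.5,0) vs (0,0.5,0.5)
  expect_equal(d["S1", "S3"], 0)      # identical composition
  disj <- feature_table(c("a", "b"), S1 = c(3L, 0L), S2 = c(0L, 7L))
  expect_equal(bray_curtis(disj)["S1", "S2"], 1)
  withr::local_seed(6)
  rt <- random_table(25, 8, 2, sparsity = 0.4)$table
  rt[1, -1] <- as.list(rep(2L, 8))
  mine <- bray_curtis(rt)
  ref <- as.matrix(vegan::vegdist(t(counts_matrix(relative_abundance(rt))),
                                  method = "bray"))
  expect_equal(unclass(mine), ref[rownames(mine), colnames(mine)],
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_true(all(mine >= 0 & mine <= 1))
  expect_equal(unname(diag(mine)), rep(0, 8))
  # raw-count mode differs when depths differ
  raw <- bray_curtis(rt, as_proportions = FALSE)
  expect_false(isTRUE(all.equal(unclass(raw), unclass(mine))))
})

test_that("PCoA reconstructs Euclidean geometry", {
  # collinear points: axis 1 reproduces the line exactly
  pts <- cbind(c(0, 3, 7), c(0, 0, 0))
  ord <- pcoa(euclidean_distances(pts))
  ax1 <- ord$coordinates$Axis.1
  expect_equal(abs(outer(ax1, ax1, "-"))[upper.tri(diag(3))],
               c(3, 7, 4), tolerance = 1e-10)
  # a random point cloud: all pairwise distances recovered
  withr::local_seed(10)
  cloud <- matrix(stats::rnorm(12 * 4), 12, 4)
  d <- euclidean_distances(cloud)
  ord2 <- pcoa(d)
  rec <- as.matrix(stats::dist(as.matrix(ord2$coordinates[-1])))
  expect_equal(unname(rec), unname(unclass(d)), tolerance = 1e-8)
  # duplicated samples land on identical coordinates
  dd <- euclidean_distances(cloud[c(1, 1, 2, 3), ])
  cc <- as.matrix(pcoa(dd)$coordinates[-1])
  expect_equal(cc[1, ], cc[2, ], tolerance = 1e-8)
  expect_error(pcoa(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("PCoA agrees with the reference implementation on Bray-Curtis input", {
  withr::local_seed(23)
  rt <- random_table(30, 9, 3, sparsity = 0.4)$table
  rt[1, -1] <- as.list(rep(2L, 9))
  d <- bray_curtis(rt)
  mine <- pcoa(d)
  ref <- ape::pcoa(stats::as.dist(unclass(d)))
  k <- length(mine$proportion_explained)
  expect_equal(mine$eigenvalues[1:k], ref$values$Eigenvalues[1:k],
               tolerance = 1e-8)
  for (ax in 1:min(3, k)) {   # eigenvector sign is arbitrary
    a <- mine$coordinates[[paste0("Axis.", ax)]]
    b <- ref$vectors[, ax]
    expect_equal(min(sum(abs(a - b)), sum(abs(a + b))), 0, tolerance = 1e-6)
  }
})

test_that("shared-feature selection applies a strict total-count threshold", {
  ta <- feature_table(c("f1", "f2", "f3"),
                      S1 = c(60L, 50L, 0L), S2 = c(40L, 50L, 2L))
  tb <- feature_table(c("f1", "f2", "f3"),
                      T1 = c(0L, 1L, 1L), T2 = c(0L, 0L, 1L))
  # totals: f1 = 100 (excluded, strict >), f2 = 101, f3 = 4
  expect_equal(select_shared_features(ta, tb, min_total = 100), "f2")
  expect_equal(select_shared_features(ta, tb, min_total = 1000), character())
  expect_setequal(select_shared_features(ta, tb, min_total = 0),
                  c("f1", "f2", "f3"))
  # per-sample mode requires the threshold in every sample
  expect_equal(select_shared_features(ta, tb, min_total = 0,
                                      mode = "per_sample"), character())
  disjoint <- feature_table("g9", T1 = 5L, T2 = 5L)
  expect_warning(out <- select_shared_features(ta, disjoint), "no features")
  expect_equal(out, character())
})

test_that("paired Spearman matches hand ranks and cor.test", {
  md <- toy_metadata()
  ta <- feature_table(paste0("f", 1:4),
                      M1 = c(1L, 2L, 3L, 4L), M2 = c(4L, 3L, 2L, 1L))
  tb <- feature_table(paste0("f", 1:4),
                      A1 = c(1L, 3L, 2L, 4L), A2 = c(1L, 2L, 3L, 4L))
  pc <- paired_spearman(ta, tb, md, features = paste0("f", 1:4))
  expect_equal(pc$rho[pc$pair_id == "c1"], 0.8)   # (1,2,3,4) vs (1,3,2,4)
  expect_equal(pc$rho[pc$pair_id == "c2"], -1)    # reversed ranks
  expect_equal(pc$p_bonferroni, pmin(1, pc$p_raw * 2))
  expect_true(all(pc$p_bonferroni >= pc$p_raw))
  expect_equal(rho_average(pc), mean(c(0.8, -1)))
  # exact permutation p agrees with cor.test's exact Spearman p
  ref <- stats::cor.test(c(1, 2, 3, 4), c(1, 3, 2, 4), method = "spearman",
                         exact = TRUE)
  expect_equal(pc$p_raw[pc$pair_id == "c1"], ref$p.value, tolerance = 1e-12)
})

test_that("constant vectors are flagged and excluded from the average", {
  md <- toy_metadata()
  ta <- feature_table(paste0("f", 1:3), M1 = c(2L, 2L, 2L), M2 = c(1L, 5L, 9L))
  tb <- feature_table(paste0("f", 1:3), A1 = c(1L, 2L, 3L), A2 = c(9L, 5L, 1L))
  pc <- paired_spearman(ta, tb, md, features = paste0("f", 1:3))
  expect_true(pc$constant[pc$pair_id == "c1"])
  expect_true(is.na(pc$rho[pc$pair_id == "c1"]))
  expect_equal(rho_average(pc), -1)
  # monotone pair gives rho exactly 1
  tc <- feature_table(paste0("f", 1:3), M1 = c(1L, 5L, 9L), M2 = c(1L, 5L, 9L))
  pc2 <- paired_spearman(tc, tb, md, features = paste0("f", 1:3))
  expect_equal(pc2$rho[pc2$pair_id == "c2"], -1)
})

test_that("t-approximation is used above the exact cutoff", {
  withr::local_seed(17)
  x <- sample.int(100, 12); y <- sample.int(100, 12)
  md <- tibble::tibble(sample_id = c("M1", "A1"), sample_class = "specimen",
                       sample_type = c("meconium", "amnion"), pair_id = "c1")
  ta <- feature_table(paste0("f", 1:12), M1 = as.integer(x))
  tb <- feature_table(paste0("f", 1:12), A1 = as.integer(y))
  pc <- paired_spearman(ta, tb, md)
  ref <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                          exact = FALSE))
  expect_equal(pc$rho, unname(ref$estimate), tolerance = 1e-12)
  expect_equal(pc$p_raw, ref$p.value, tolerance = 1e-10)
})
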