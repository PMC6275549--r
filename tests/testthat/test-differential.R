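meta_grid <- function() {
  # dHAZ in {-2, 0, 2} so 2^(0.5*dhaz) gives exact integer counts
  tibble::tibble(
    sample_id = sprintf("S%02d", 1:12),
    delta_haz = rep(c(-2, 0, 2), each = 4),
    sex = rep(c("F", "M"), 6),
    stunted = rep(c(TRUE, FALSE, FALSE), each = 4))
}

test_that("noiseless log-linear counts are recovered exactly", {
  meta <- meta_grid()
  counts <- matrix(rep(100 * 2^(0.5 * meta$delta_haz), each = 3),
                   nrow = 3, byrow = FALSE)
  rownames(counts) <- c("f1", "f2", "f3")
  colnames(counts) <- meta$sample_id
  res <- fit_feature_models(counts, meta, rep(1, 12))
  expect_equal(res$log2fc_per_dhaz, rep(0.5, 3), tolerance = 1e-3)
  expect_equal(res$base_mean, rowMeans(counts), ignore_attr = TRUE)
})

test_that("size-factor offsets absorb per-sample scaling", {
  meta <- meta_grid()
  # moderate counts so the data-driven dispersion estimate (the only
  # non-offset pathway) is insensitive to the Poisson-level change
  sim <- simulate_nb_counts(30, meta, beta_log2 = 0.3, dispersion = 0.05,
                            size_factors = rep(1, 12),
                            base_mean_meanlog = log(1000),
                            base_mean_sdlog = 0.5, seed = 5)
  res1 <- fit_feature_models(sim$counts, meta, rep(1, 12))
  scaled <- sim$counts
  scaled[, 3] <- scaled[, 3] * 4L
  sf <- rep(1, 12); sf[3] <- 4
  res2 <- fit_feature_models(scaled, meta, sf)
  # the offset absorbs the scaling; only the data-driven dispersion
  # estimate feels the (Poisson-level) change, so agreement is near-exact
  expect_lt(max(abs(res2$log2fc_per_dhaz - res1$log2fc_per_dhaz)), 5e-3)
  expect_lt(max(abs(res2$p_value - res1$p_value)), 0.02)
})

test_that("degenerate inputs are handled per contract", {
  meta <- meta_grid()
  counts <- matrix(5L, nrow = 2, ncol = 12,
                   dimnames = list(c("a", "b"), meta$sample_id))
  counts["b", ] <- 0L
  res <- fit_feature_models(counts, meta, rep(1, 12))
  expect_true(is.na(res$p_value[res$feature_id == "b"]))
  expect_equal(unname(res$base_mean[res$feature_id == "b"]), 0)

  one_sex <- meta; one_sex$sex <- "F"
  expect_error(fit_feature_models(counts, one_sex, rep(1, 12)),
               "rank deficient")
  expect_s3_class(
    fit_feature_models(counts, one_sex, rep(1, 12), adjust_sex = FALSE),
    "tbl_df")
  expect_error(fit_feature_models(counts[, 1:4], meta[1:4, ], rep(1, 4)),
               "at least 6")
})

test_that("the categorical stunted design recovers a group difference", {
  meta <- meta_grid()
  counts <- matrix(rep(ifelse(meta$stunted, 50L, 200L), each = 4),
                   nrow = 4, byrow = FALSE,
                   dimnames = list(sprintf("f%d", 1:4), meta$sample_id))
  res <- fit_feature_models(counts, meta, rep(1, 12), design = "stunted")
  expect_equal(res$log2fc_per_dhaz, rep(-2, 4), tolerance = 1e-3)
})

test_that("BH adjustment matches the step-up formula and its invariants", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(c(1, 1)), c(1, 1))
  expect_equal(bh_fdr(0.007), 0.007)
  expect_equal(bh_fdr(numeric(0)), numeric(0))
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")
  p <- withr::with_seed(8, runif(50)^2)
  adj <- bh_fdr(p)
  expect_true(all(adj >= p))
  perm <- sample(50)
  expect_equal(bh_fdr(p[perm]), adj[perm])
  # NAs pass through without counting as tests
  expect_equal(bh_fdr(c(0.02, NA, 0.04)),
               c(0.04, NA, 0.04))
})

test_that("PCA separates constructed groups and orders variance fractions", {
  meta <- meta_grid()
  sim <- simulate_nb_counts(80, meta, beta_log2 = 0, dispersion = 0.02,
                            size_factors = rep(1, 12), seed = 9)
  counts <- sim$counts
  counts[1:20, meta$delta_haz == 2] <- counts[1:20, meta$delta_haz == 2] * 8L
  pc <- pca_samples(counts, rep(1, 12), n_top_features = 50)
  expect_true(all(diff(pc$var_explained) <= 1e-12))
  expect_lte(sum(pc$var_explained), 1 + 1e-12)
  grp <- as.integer(meta$delta_haz == 2) + 1L
  sil <- cluster::silhouette(grp, dist(pc$coordinates$PC1))
  expect_gt(mean(sil[, "sil_width"]), 0.5)
  expect_error(pca_samples(counts, rep(1, 12), n_top_features = 1),
               "at least 2")
})

test_that("correlation clustering groups replicates and flags degenerate
          input", {
  meta <- meta_grid()
  sim <- simulate_nb_counts(100, meta, beta_log2 = 0, dispersion = 0.05,
                            size_factors = rep(1, 12), seed = 10)
  counts <- sim$counts
  counts[, 2] <- counts[, 1]  # duplicate sample
  cl <- correlation_cluster(counts, rep(1, 12))
  expect_equal(cl$correlation["S01", "S02"], 1)
  # the duplicated pair merges first
  expect_setequal(abs(cl$hclust$merge[1, ]),
                  which(colnames(counts) %in% c("S01", "S02")))
  const <- counts
  const[, 3] <- 7L
  expect_error(correlation_cluster(const, rep(1, 12)), "constant")
  # a perfectly anti-correlated pair (on the log scale) sits at distance 2
  m2 <- cbind(a = 2L^(1:8) - 1L, b = 2L^(8:1) - 1L, c = 2L^c(1:4, 4:1) - 1L)
  rownames(m2) <- sprintf("f%02d", 1:8)
  cl2 <- correlation_cluster(m2, c(1, 1, 1))
  expect_equal(1 - cl2$correlation["a", "b"], 2)
})

test_that("three constructed groups cluster with higher within- than
          between-group correlation", {
  meta <- tibble::tibble(sample_id = sprintf("S%02d", 1:9),
                         delta_haz = 0, sex = "F", stunted = FALSE)
  sim <- simulate_nb_counts(150, meta, beta_log2 = 0, dispersion = 0.02,
                            size_factors = rep(1, 9), seed = 17)
  counts <- sim$counts
  grp <- rep(1:3, each = 3)
  shift <- withr::with_seed(18, matrix(rlnorm(150 * 3, 0, 0.8), ncol = 3))
  for (g in 1:3)
    counts[, grp == g] <- round(counts[, grp == g] * shift[, g])
  cl <- correlation_cluster(counts, rep(1, 9))
  r <- cl$correlation
  same <- outer(grp, grp, "==") & upper.tri(r)
  diff_g <- outer(grp, grp, "!=") & upper.tri(r)
  expect_gt(mean(r[same]), mean(r[diff_g]))
})
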