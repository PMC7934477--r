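test_that("gene correlations match a brute-force rank-then-Pearson
          oracle", {
  set.seed(2)
  v <- matrix(runif(48, 1, 30), 4, 12)
  m <- toy_matrix(v)
  cs <- gene_correlations(m, m, gene_filter = "all")
  oracle <- cor(apply(v, 1, rank))   # columns of apply() are genes
  expect_equal(unname(cs$C_wt), unname(oracle), tolerance = 1e-12)
  # self-comparison: squared-correlation difference is exactly zero
  expect_true(all(cs$sq_diff == 0))
})

test_that("duplicated genes correlate perfectly and dominate the
          average squared correlation", {
  set.seed(4)
  g1 <- runif(15, 1, 10)
  v <- rbind(g1 = g1, g2 = g1, g3 = runif(15, 1, 10))
  m <- toy_matrix(v, genes = rownames(v))
  cs <- gene_correlations(m, m, gene_filter = "all")
  expect_equal(cs$C_wt["g1", "g2"], 1)
  expect_gte(cs$avg_sq$wt[cs$avg_sq$gene_id == "g1"], 0.5)
})

test_that("constant genes are flagged and excluded", {
  v <- rbind(a = runif(12, 1, 5), b = rep(3, 12), c = runif(12, 1, 5))
  m <- toy_matrix(v, genes = rownames(v))
  cs <- gene_correlations(m, m, gene_filter = "all")
  expect_equal(cs$flagged_genes, "b")
  expect_false("b" %in% cs$gene_ids)
})

test_that("mean squared-correlation difference identity holds to
          1e-12", {
  cfg <- cohort_config(n_genes = 30, n_cells_per_condition = 40,
                       seed = 9)
  sp <- simulate_pair(cfg)
  cs <- gene_correlations(sp$wt, sp$mut, gene_filter = "all")
  off <- lower.tri(cs$sq_diff)
  expect_equal(mean(cs$sq_diff[off]),
               mean(cs$C_wt[off]^2) - mean(cs$C_mut[off]^2),
               tolerance = 1e-12)
  expect_true(all(cs$avg_sq$wt >= 0 & cs$avg_sq$wt <= 1))
  expect_true(all(abs(cs$sq_diff) <= 1))
})

test_that("declining cluster recovers a planted decorrelating block
          and is invariant to gene order", {
  cfg <- cohort_config(n_genes = 120, n_cells_per_condition = 120,
                       module_size = 40,
                       module_corr_by_condition = c(0.8, 0), seed = 15)
  sp <- simulate_pair(cfg)
  cs <- gene_correlations(sp$wt, sp$mut, gene_filter = "all")
  cl <- declining_cluster(cs, seed = 1)
  mod <- sp$truth$module_gene_ids
  jac <- length(intersect(cl, mod)) / length(union(cl, mod))
  expect_gte(jac, 0.8)
  expect_false(attr(cl, "no_structure"))

  perm <- sample(120)
  cs2 <- gene_correlations(subset_matrix(sp$wt, genes = perm),
                           subset_matrix(sp$mut, genes = perm),
                           gene_filter = "all")
  cl2 <- declining_cluster(cs2, seed = 1)
  expect_setequal(cl2, cl)

  # the paper-style largest-cluster heuristic returns the complement
  # here because the planted module is the minority block
  cl_lg <- declining_cluster(cs, seed = 1, selection = "largest")
  expect_gt(length(cl_lg), length(cl))
})

test_that("structureless input is flagged by a low silhouette", {
  set.seed(30)
  v <- matrix(rnorm(60 * 50, 10, 2), 60, 50)
  m1 <- toy_matrix(pmax(v, 0))
  m2 <- toy_matrix(pmax(matrix(rnorm(60 * 50, 10, 2), 60, 50), 0))
  cs <- gene_correlations(m1, m2, gene_filter = "all")
  cl <- declining_cluster(cs, seed = 2)
  frac <- length(cl) / length(cs$gene_ids)
  expect_gte(frac, 0.1)
  expect_lte(frac, 1)
  expect_lt(attr(cl, "silhouette"), 0.3)
})

test_that("correlation sd falls when a module decoheres, and matches
          the null Spearman dispersion for independent genes", {
  cfg <- cohort_config(n_genes = 60, n_cells_per_condition = 120,
                       module_size = 30,
                       module_corr_by_condition = c(0.8, 0), seed = 23)
  sp <- simulate_pair(cfg, gaussian_specs(60, seed = 23))
  res <- correlation_sd_compare(sp$wt, sp$mut, gene_filter = "all",
                                seed = 7)
  expect_true(all(res$replicates[, "wt"] > res$replicates[, "mut"]))

  # independent genes: off-diagonal sd ~ 1/sqrt(n_cells - 1)
  cfg0 <- cohort_config(n_genes = 80, n_cells_per_condition = 200,
                        seed = 24)
  sp0 <- simulate_pair(cfg0)
  cs0 <- gene_correlations(sp0$wt, sp0$mut, gene_filter = "all")
  expect_lt(abs(cs0$corr_sd["wt"] - 1 / sqrt(199)) / (1 / sqrt(199)),
            0.2)
})

test_that("hypergeometric enrichment equals the closed-form tail sum", {
  background <- paste0("g", 1:100)
  ann <- paste0("g", 1:10)
  cluster <- paste0("g", c(1:5, 50:54))   # overlap 5
  res <- cluster_enrichment(cluster, list(ribosome = ann), background)
  closed <- sum(choose(10, 5:10) * choose(90, 10 - (5:10))) /
    choose(100, 10)
  expect_equal(res$p_value, closed, tolerance = 1e-12)
  expect_equal(res$overlap, 5)

  # cluster = background: overlap is forced, p = 1
  res_all <- cluster_enrichment(background, list(s = ann), background)
  expect_equal(res_all$p_value, 1)

  # overlap below expectation: p > 0.5
  res_lo <- cluster_enrichment(paste0("g", 11:60), list(s = ann),
                               background)
  expect_gt(res_lo$p_value, 0.5)

  expect_warning(
    res_dis <- cluster_enrichment(cluster, list(none = "zzz"),
                                  background),
    "disjoint")
  expect_equal(res_dis$p_value, 1)
  expect_error(cluster_enrichment(c(cluster, "not_in_bg"),
                                  list(s = ann), background),
               "missing from background")
})
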