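test_that("detection median reproduces the hand-computed toy", {
  # A > B > C > D > E in every cell; detection 4/4, 3/4, 2/4, 1/4, 1/4
  v <- rbind(A = c(10, 9, 11, 10), B = c(8, 8, 8, 0),
             C = c(6, 6, 0, 0), D = c(4, 0, 0, 0), E = c(2, 0, 0, 0))
  m <- toy_matrix(v, genes = rownames(v))
  expect_equal(detection_median(m, k = 2), 0.875)   # median(1, 0.75)
  expect_equal(detection_median(m, k = 1), 1)
  expect_error(detection_median(m, k = 6), "exceeds")
})

test_that("detection median is rank-based: per-cell rescaling does not
          change it", {
  set.seed(5)
  cfg <- cohort_config(n_genes = 80, n_cells_per_condition = 50,
                       zero_inflation_by_group = c(0.2, 0.2), seed = 5)
  m <- simulate_pair(cfg)$wt
  base <- detection_median(m, k = 20)
  scaled <- m$values
  scaled[, 3] <- scaled[, 3] * 17.3
  expect_equal(detection_median(toy_matrix(scaled), k = 20), base)
})

test_that("detection median decreases along a planted dropout series", {
  wins <- 0
  for (s in 1:10) {
    cfg0 <- cohort_config(n_genes = 120, n_cells_per_condition = 150,
                          seed = 200 + s)
    base <- simulate_pair(cfg0)$wt$values
    meds <- sapply(c(0, 0.2, 0.4), function(p) {
      set.seed(1000 + s)
      v <- base
      v[matrix(runif(length(v)) < p, nrow(v))] <- 0
      detection_median(toy_matrix(v), k = 40)
    })
    if (meds[1] > meds[2] && meds[2] > meds[3]) wins <- wins + 1
  }
  expect_gte(wins, 8)
})

test_that("detection median is robust to halving the cells", {
  cfg <- cohort_config(n_genes = 200, n_cells_per_condition = 500,
                       zero_inflation_by_group = c(0.3, 0.3), seed = 77)
  m <- simulate_pair(cfg)$wt
  full <- detection_median(m, k = 50)
  set.seed(99)
  half <- detection_median(
    subset_matrix(m, cells = sample(500, 250)), k = 50)
  expect_lt(abs(full - half), 0.05)
})

test_that("per-subject wrapper excludes small subjects", {
  cfg <- cohort_config(n_genes = 60, n_cells_per_condition = 60,
                       n_subjects_per_group = 2, seed = 13)
  sim <- simulate_cohort(cfg)
  small <- subset_matrix(sim$matrices[[1]], cells = 1:10)
  df <- detection_median_by_subject(
    c(sim$matrices, list(tiny = small)), k = 30, min_cells = 50)
  expect_true(df$excluded[df$subject == "tiny"])
  expect_true(all(!df$excluded[df$subject != "tiny"]))
})

test_that("group test: complete separation of 3 vs 3 gives the exact
          enumeration p-value", {
  # disease lower in all 9 cross-pairs: one-sided p = 1 / choose(6, 3)
  p <- detection_group_test(c(0.9, 0.8, 0.85, 0.2, 0.3, 0.25),
                            rep(c("healthy", "disease"), each = 3))
  expect_equal(p$p_value, 1 / choose(6, 3))
})

test_that("group test under exchangeable groups is never significant", {
  p <- detection_group_test(c(0.8, 0.8, 0.8, 0.8),
                            c("h", "h", "d", "d"))
  expect_gte(p$p_value, 0.4)
  expect_error(detection_group_test(c(1, 2, 3), c("a", "a", "b")),
               "at least 2 subjects")
})

test_that("intra-condition distances match the closed-form Pearson
          oracle", {
  # trivial cases
  two_same <- toy_matrix(cbind(c(1, 5, 9), c(1, 5, 9), c(2, 5, 8)))
  d <- intra_condition_distance(two_same, gene_filter = "all")
  cc <- cor(two_same$values)
  expect_equal(sort(d$conditions[[1]]$distances),
               sort(1 - cc[lower.tri(cc)]), tolerance = 1e-12)
  expect_equal(min(d$conditions[[1]]$distances), 0, tolerance = 1e-12)

  rev3 <- toy_matrix(cbind(c(1, 2, 3), c(3, 2, 1), c(1, 2, 3)))
  dr <- intra_condition_distance(rev3, gene_filter = "all")
  expect_equal(max(dr$conditions[[1]]$distances), 2, tolerance = 1e-12)

  # closed-form covariance oracle on a random 3-cell toy
  set.seed(8)
  v <- matrix(runif(15, 1, 10), 5, 3)
  m <- toy_matrix(v)
  dd <- intra_condition_distance(m, gene_filter = "all")
  oracle <- function(x, y) {
    n <- length(x)
    1 - (sum(x * y) - n * mean(x) * mean(y)) /
      ((n - 1) * sd(x) * sd(y))
  }
  exp_d <- c(oracle(v[, 1], v[, 2]), oracle(v[, 1], v[, 3]),
             oracle(v[, 2], v[, 3]))
  expect_equal(sort(dd$conditions[[1]]$distances), sort(exp_d),
               tolerance = 1e-12)
})

test_that("the joint gene filter requires expression in both
          conditions", {
  wt <- toy_matrix(rbind(a = rep(10, 4), b = rep(10, 4),
                         c = c(0, 0, 0, 1)))
  mut <- toy_matrix(rbind(a = rep(10, 4), b = c(0, 0, 0, 2),
                          c = rep(10, 4)))
  d <- intra_condition_distance(wt, mut)
  expect_equal(d$gene_filter$n_genes_used, 1)   # only gene a passes both
  bad <- toy_matrix(rbind(a = c(0, 0, 0, 1)))
  expect_error(intra_condition_distance(bad), "filter")
})

test_that("distance mean is invariant to gene and cell reordering", {
  set.seed(17)
  m <- toy_matrix(matrix(runif(60, 1, 20), 10, 6))
  d0 <- intra_condition_distance(m, gene_filter = "all")
  mp <- subset_matrix(m, genes = sample(10), cells = sample(6))
  d1 <- intra_condition_distance(mp, gene_filter = "all")
  expect_equal(d1$conditions[[1]]$mean, d0$conditions[[1]]$mean,
               tolerance = 1e-12)
})

test_that("identical distance distributions are not significant;
          planted extra noise is detected across seeds", {
  set.seed(3)
  m <- toy_matrix(matrix(runif(200, 1, 20), 20, 10))
  d <- intra_condition_distance(m, m, gene_filter = "all")
  gt <- distance_group_test(d)
  expect_equal(gt$mean_difference, 0)
  expect_gte(gt$p_value, 0.49)

  # higher per-gene noise sd in the mutant lowers cell-cell Pearson
  # correlations, hence a larger mean intra-condition distance
  wins <- 0
  for (s in 1:10) {
    specs <- lapply(gaussian_specs(80, seed = 400 + s), function(g) {
      g$condition_effect <- "variance_shift"; g$magnitude <- 2; g
    })
    cfg <- cohort_config(n_genes = 80, n_cells_per_condition = 200,
                         seed = 400 + s)
    sp <- simulate_pair(cfg, specs)
    ds <- intra_condition_distance(sp$wt, sp$mut, gene_filter = "all")
    if (ds$mean_difference > 0) wins <- wins + 1
  }
  expect_gte(wins, 9)
})
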