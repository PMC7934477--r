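test_that("mean difference index follows the formula and is
          antisymmetric", {
  expect_equal(mean_difference_index(5, 5), 0)
  expect_equal(mean_difference_index(1, 2), 1 / 3)
  expect_equal(mean_difference_index(2, 1), -1 / 3)
  expect_equal(mean_difference_index(0.96, 1.04), 0.04)
  expect_true(is.na(mean_difference_index(0, 0)))
  a <- runif(10); b <- runif(10)
  expect_equal(mean_difference_index(a, b),
               -mean_difference_index(b, a))
})

test_that("similar-mean filter applies strict cutoffs and the joint
          expression filter", {
  n <- 10
  wt <- toy_matrix(rbind(
    equal = rep(19, n),        # index 0.05 exactly -> excluded
    close = rep(10, n),        # index ~0.0099 -> kept
    sparse = c(rep(10, 4), rep(0, 6)),  # 40% detection -> excluded
    weak = rep(4.9, n)))       # mean < 5 in wt -> excluded
  mut <- toy_matrix(rbind(
    equal = rep(21, n),
    close = rep(10.2, n),
    sparse = rep(10, n),
    weak = rep(10, n)))
  keep <- similar_mean_filter(wt, mut)
  expect_identical(keep, "close")
  # index 0.05 boundary really is 0.05
  expect_equal(mean_difference_index(19, 21), 0.05)
})

test_that("trimmed CV discards tail extremes", {
  expect_equal(trimmed_cv(rep(7, 50)), 0)
  x <- c(rep(10, 99), 1000)
  expect_equal(trimmed_cv(x), 0)            # outlier trimmed away
  expect_gt(sd(x) / mean(x), 1)             # untrimmed CV explodes
  expect_error(trimmed_cv(1:10), "at least 20")

  set.seed(20)
  y <- rnorm(1000, 10, 2)
  tcv <- trimmed_cv(y)
  ucv <- sd(y) / mean(y)
  expect_lt(tcv, ucv)
  expect_lt(abs(ucv - 0.2) / 0.2, 0.1)
  # closed-form oracle: sd of the normal truncated to its 5-95%
  # quantile range, divided by the (unchanged) mean
  z <- qnorm(0.95)
  sd_trunc <- sqrt(1 - 2 * z * dnorm(z) / 0.9)
  expect_lt(abs(tcv - 0.2 * sd_trunc) / (0.2 * sd_trunc), 0.05)
})

test_that("model-based DVSM calls: null, type II, unconverged", {
  set.seed(33)
  x <- rnorm(150, 10, 1.5)
  res <- dvsm_model_call(x, x, n_boot = 500, seed = 1)
  expect_equal(res$call, "not_dv")
  expect_lte(res$sd_ratio_ci[1], 1)
  expect_gte(res$sd_ratio_ci[2], 1)

  # wt pure Gaussian, mutant with heavy zero/exponential contamination
  xm <- c(rnorm(75, 10, 1.5), rexp(45, 0.2), runif(30))
  res2 <- dvsm_model_call(x, pmax(xm, 0), n_boot = 500, seed = 2,
                          n_starts = 3)
  expect_equal(res2$call, "more_variable_mut_typeII")

  unconv <- list(pi = c(1, 0, 0), mu = 1, sigma = 1, rate = 1,
                 converged = FALSE, shape_class = "pure_gaussian")
  res3 <- dvsm_model_call(x, x, fit_wt = unconv, fit_mut = unconv)
  expect_equal(res3$call, "not_applicable")
})

test_that("CV-based DVSM call: null CI contains 1, permutation p has
          the documented resolution", {
  set.seed(34)
  x <- rnorm(80, 10, 1.5)
  res <- dvsm_cv_call(x, x, n_boot = 400, n_perm = 99, seed = 3)
  expect_equal(res$cv_ratio, 1)
  expect_lte(res$ci[1], 1); expect_gte(res$ci[2], 1)
  expect_equal(res$boot_call, "not_dv")
  expect_gte(res$perm_p, 1 / 100)   # resolution 1/(n_perm + 1)

  y <- rnorm(80, 10, 3)
  res2 <- dvsm_cv_call(x, y, n_boot = 400, n_perm = 199, seed = 4)
  expect_equal(res2$boot_call, "more_variable_mut")
  expect_lt(res2$perm_p, 0.05)
})

test_that("variability rank score matches the 5-gene window-3 hand
          oracle and tie behavior", {
  means <- 1:5
  cvs <- c(0.1, 0.2, 0.3, 0.4, 0.5)   # increasing with mean order
  s <- variability_rank_score(means, cvs, window = 2)
  # window 2: interior genes average ranks from their two windows
  expect_true(all(is.na(s[c(1, 5)])))
  s3 <- variability_rank_score(means, cvs, window = 2)
  expect_equal(unname(s3[3]), 0.5)     # rank 2/2 then 1/2 -> (1+0)/2

  # window 3 on 6 genes: gene 3 sees windows (1,2,3),(2,3,4),(3,4,5)
  m6 <- 1:6; c6 <- seq(0.1, 0.6, by = 0.1)
  s6 <- variability_rank_score(m6, c6, window = 3)
  expect_equal(unname(s6[3]), mean(c(1, 0.5, 0)))
  expect_equal(unname(s6[4]), mean(c(1, 0.5, 0)))
  expect_true(all(is.na(s6[c(1, 2, 5, 6)])))

  # identical CVs: all scored genes sit at 0.5 (average tie rank)
  st <- variability_rank_score(1:10, rep(0.3, 10), window = 3)
  expect_true(all(st[3:8] == 0.5))

  expect_error(variability_rank_score(1:5, rep(1, 5), window = 3),
               "at least 6")
})

test_that("rank score is invariant to monotone transforms of the CV", {
  set.seed(55)
  means <- sort(runif(40, 1, 100))
  cvs <- runif(40, 0.1, 1)
  a <- variability_rank_score(means, cvs, window = 8)
  b <- variability_rank_score(means, cvs^3, window = 8)
  expect_equal(a, b)
})

test_that("DV calls: null guard, nesting, and direction", {
  s <- runif(20)
  names(s) <- paste0("g", 1:20)
  expect_true(all(!dv_call(s, s)$dv))

  set.seed(56)
  wt <- runif(200); mut <- wt + rnorm(200, 0, 0.02)
  names(wt) <- names(mut) <- paste0("g", 1:200)
  mut[1:5] <- wt[1:5] + 0.5
  d2 <- dv_call(wt, mut, n_std = 2)
  d1 <- dv_call(wt, mut, n_std = 1)
  expect_true(all(d2$gene_id[d2$dv] %in% d1$gene_id[d1$dv]))
  expect_true(all(d2$direction[match(paste0("g", 1:5), d2$gene_id)] ==
                    "more_variable_mutant"))
  expect_error(dv_call(s[1:5], s[1:5]), "at least 10")
})

test_that("differential expression applies the expression-sum, fold and
          FDR rules", {
  set.seed(57)
  base <- matrix(rgamma(50 * 20, 4, 0.5), 50, 20)
  wt <- toy_matrix(base)
  expect_true(all(!differential_expression(wt, wt)$de))

  # adequately expressed 4-fold gene is called; a 4-fold gene below the
  # expression-sum threshold is not
  v_mut <- base
  v_mut[1, ] <- base[1, ] * 4
  lo_wt <- base; lo_mut <- v_mut
  lo_wt[2, ] <- 2^0.45 - 1          # a_wt ~ 0.45
  lo_mut[2, ] <- 2^2.45 - 1         # a_mut ~ 2.45, sum 2.9 < 3
  de <- differential_expression(toy_matrix(lo_wt), toy_matrix(lo_mut))
  expect_true(de$de[1])
  expect_false(de$de[2])
  expect_gte(abs(de$log2_fc[2]), 1)   # excluded by the sum rule alone
})

test_that("empty DV set enrichment warns and returns p = 1", {
  expect_warning(
    res <- dv_enrichment(character(0), paste0("g", 1:5),
                         paste0("g", 1:50)),
    "empty")
  expect_equal(res$p_value, 1)
})

test_that("the variability table is coherent on a small planted pair", {
  cfg <- cohort_config(n_genes = 50, n_cells_per_condition = 80,
                       seed = 71)
  specs <- default_specs(50, n_dv = 4, seed = 71)
  sp <- simulate_pair(cfg, specs)
  vt <- dvsm_analysis(sp$wt, sp$mut, n_boot = 300, n_perm = 99,
                      window = 15, seed = 5,
                      fit_args = list(n_starts = 2, max_iter = 400))
  expect_equal(nrow(vt), 50)
  expect_true(all(vt$dvsm_call[!vt$similar_mean] == "not_applicable"))
  planted <- vt[match(sp$truth$dv_gene_ids, vt$gene_id), ]
  sig <- planted$perm_p < 0.05
  expect_gte(sum(sig, na.rm = TRUE), 2)
})
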