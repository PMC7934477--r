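test_that("quantile normalization matches the rank-average oracle", {
  m <- toy_matrix(cbind(c(1, 2, 3), c(2, 4, 6)))
  qn <- quantile_normalize(m)
  expect_equal(unname(qn$values[, 1]), c(1.5, 3.0, 4.5))
  expect_equal(unname(qn$values[, 2]), c(1.5, 3.0, 4.5))

  # identical columns are left unchanged
  same <- toy_matrix(cbind(c(3, 1, 7), c(3, 1, 7)))
  expect_equal(quantile_normalize(same)$values, same$values)
})

test_that("after normalization all sorted columns are identical and the
          operation is idempotent", {
  set.seed(7)
  m <- toy_matrix(matrix(rexp(50, 0.1), 10, 5))
  qn <- quantile_normalize(m)
  sorted <- apply(qn$values, 2, sort)
  for (j in 2:5) expect_identical(sorted[, j], sorted[, 1])
  expect_identical(quantile_normalize(qn)$values, qn$values)
})

test_that("quantile normalization agrees with an independent
          implementation", {
  skip_if_not_installed("limma")
  set.seed(11)
  x <- matrix(rgamma(60, 2, 0.1), 12, 5)
  ours <- quantile_normalize(toy_matrix(x))$values
  ref <- limma::normalizeQuantiles(x, ties = FALSE)
  expect_equal(unname(ours), unname(ref), tolerance = 1e-12)
})

test_that("single-cell input is a warned no-op", {
  m <- toy_matrix(matrix(1:3, 3, 1))
  expect_warning(out <- quantile_normalize(m), ">= 2 cells")
  expect_identical(out$values, m$values)
})

test_that("N-E index handles the quoted and limit cases", {
  v <- rbind(NES = c(6, 4, 0), TUBB3 = c(4, 0, 0),
             POU5F1 = c(2, 0, 0), NANOG = c(0, 0, 0))
  m <- toy_matrix(v, genes = rownames(v))
  idx <- ne_index(m)
  expect_equal(unname(idx[1]), 5)        # 10 / 2
  expect_equal(unname(idx[2]), Inf)      # 4 / 0
  expect_true(is.nan(idx[3]))            # 0 / 0 flagged undefined
  expect_error(ne_index(m, neural_genes = c("NES", "MISSING")),
               "MISSING")
})

test_that("read-count stage removes cells below the threshold", {
  m <- toy_matrix(matrix(10, 5, 3),
                  aligned_read_count = c(1.9e5, 2e5, 3e5),
                  genes_detected_fraction = c(0.5, 0.5, 0.5))
  suppressWarnings(res <- qc_filter(m))
  expect_equal(res$report$n_removed_by_reads, 1L)
  expect_false("c1" %in% res$report$kept_cell_ids)
  expect_equal(res$report$n_input_cells,
               length(res$report$kept_cell_ids) +
                 res$report$n_removed_by_reads +
                 res$report$n_removed_by_gene_fraction +
                 res$report$n_removed_by_ne_index +
                 res$report$n_removed_by_mad)
})

test_that("correlation outlier stage removes exactly the decorrelated
          cell", {
  m <- correlated_cells(n_genes = 40, n_cells = 20, n_outliers = 1,
                        seed = 3)
  suppressWarnings(res <- qc_filter(m))
  expect_equal(res$report$n_removed_by_mad, 1L)
  expect_false("c21" %in% res$report$kept_cell_ids)

  # oracle: direct median/MAD computation on average correlations
  rc <- cor(m$values, method = "spearman"); diag(rc) <- NA
  avg <- rowMeans(rc, na.rm = TRUE)
  flagged <- names(avg)[abs(avg - median(avg)) >
                          5 * mad(avg, constant = 1)]
  expect_identical(sort(setdiff(m$cell_ids,
                                res$report$kept_cell_ids)),
                   sort(flagged))
})

test_that("rank-identical cells are never removed, and the kept set is
          invariant to cell order", {
  # scaled copies of one profile: all pairwise Spearman correlations 1,
  # so every average correlation is equal and the MAD cut removes none
  base <- seq(1, 60, length.out = 30)
  m <- toy_matrix(outer(base, seq(0.5, 2, length.out = 15)))
  suppressWarnings(res <- qc_filter(m))
  expect_equal(length(res$report$kept_cell_ids), 15)

  mo <- correlated_cells(n_genes = 40, n_cells = 20, n_outliers = 1,
                         seed = 3)
  suppressWarnings(ref <- qc_filter(mo))
  set.seed(1)
  mp <- subset_matrix(mo, cells = sample(21))
  suppressWarnings(resp <- qc_filter(mp))
  expect_setequal(resp$report$kept_cell_ids, ref$report$kept_cell_ids)
})

test_that("missing metadata stages are skipped with a warning", {
  m <- correlated_cells(n_genes = 10, n_cells = 5, seed = 1)
  w <- capture_warnings(qc_filter(m))
  expect_true(any(grepl("aligned_read_count", w)))
  expect_true(any(grepl("genes_detected_fraction", w)))
  expect_true(any(grepl("marker genes", w)))
})
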