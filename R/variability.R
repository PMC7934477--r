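#' Mean difference index between two conditions
#'
#' `(M_mut - M_wt) / (M_mut + M_wt)`: a symmetric relative difference in
#' \[-1, 1\] that is exactly antisymmetric under swapping conditions.
#' An index below 0.05 in absolute value corresponds to roughly a 10%
#' difference in means and is the conventional "similar mean" cut.
#'
#' @param mean_wt,mean_mut Per-gene mean expression (vectors allowed).
#' @return The index; `NA` where both means are zero.
#' @export
mean_difference_index <- function(mean_wt, mean_mut) {
  out <- (mean_mut - mean_wt) / (mean_mut + mean_wt)
  out[mean_wt == 0 & mean_mut == 0] <- NA_real_
  out
}

#' Select genes with similar means and adequate expression
#'
#' A gene qualifies for variability comparison when it is detected in at
#' least `min_detect_frac` of the cells and has mean expression above
#' `min_mean` in *both* conditions, and its absolute mean difference
#' index is strictly below `cutoff`.
#'
#' @param m_wt,m_mut `ExpressionMatrix` objects with identical genes.
#' @param cutoff Mean-difference-index cutoff (default 0.05; 0.1 is the
#'   usual sensitivity setting).
#' @param min_detect_frac,min_mean Expression filter thresholds.
#' @return Character vector of qualifying gene ids.
#' @export
similar_mean_filter <- function(m_wt, m_mut, cutoff = 0.05,
                                min_detect_frac = 0.5, min_mean = 5) {
  m_wt <- as_expression_matrix(m_wt); m_mut <- as_expression_matrix(m_mut)
  if (!identical(m_wt$gene_ids, m_mut$gene_ids))
    stop("matrices must share an identical gene set")
  expressed <- filter_genes_joint(list(m_wt, m_mut), min_detect_frac,
                                  min_mean)
  idx <- mean_difference_index(rowMeans(m_wt$values),
                               rowMeans(m_mut$values))
  m_wt$gene_ids[expressed & !is.na(idx) & abs(idx) < cutoff]
}

#' Trimmed coefficient of variation
#'
#' The CV (sd/mean) after discarding the `floor(n * trim)` largest and
#' smallest values, which immunizes the statistic against the 1-2
#' extreme cells that can otherwise move a gene's CV by up to 100%.
#'
#' @param x Numeric vector, `n >= 20` so at least one value is trimmed
#'   per tail at the default trim.
#' @param trim Fraction trimmed from each tail (default 0.05).
#' @return The trimmed CV; 0 for a constant trimmed sample; `NaN`
#'   (undefined) when the trimmed mean is 0.
#' @export
trimmed_cv <- function(x, trim = 0.05) {
  n <- length(x)
  if (n < 20) stop("need at least 20 observations, got ", n)
  if (trim < 0 || trim >= 0.5) stop("trim must lie in [0, 0.5)")
  t1 <- floor(n * trim)
  xs <- sort(x)
  core <- xs[(t1 + 1):(n - t1)]
  m <- mean(core)
  if (m == 0) return(NaN)
  s <- stats::sd(core)
  s / m
}

# trimmed sd/mean for every column of a matrix (bootstrap/permutation
# workhorse); returns NaN columns where the trimmed mean is 0
trimmed_cv_cols <- function(X, trim = 0.05) {
  n <- nrow(X)
  t1 <- floor(n * trim)
  Xs <- apply(X, 2, sort)
  core <- Xs[(t1 + 1):(n - t1), , drop = FALSE]
  mu <- colMeans(core)
  k <- nrow(core)
  sds <- sqrt((colSums(core^2) - k * mu^2) / (k - 1))
  sds <- pmax(sds, 0)  # numeric guard for constant columns
  out <- sds / mu
  out[mu == 0] <- NaN
  out
}

col_vars <- function(X) {
  n <- nrow(X)
  mu <- colMeans(X)
  pmax((colSums(X^2) - n * mu^2) / (n - 1), 0)
}

#' Model-based differential variability call for a similar-mean gene
#'
#' Applies the two-branch rule on the fitted mixture shapes:
#' * both conditions pure Gaussian (type I): bootstrap both samples
#'   `n_boot` times, form the mutant/WT sd ratio per pair, and call the
#'   gene more variable in whichever condition the percentile
#'   confidence interval places entirely above or below a ratio of 1;
#' * one condition pure Gaussian, the other with Gaussian weight below
#'   0.8 (type II): the low-Gaussian condition carries extreme zeros
#'   and/or large values and is called more variable outright;
#' * anything else: no call.
#'
#' @param x_wt,x_mut Per-cell expression of one gene in each condition.
#' @param fit_wt,fit_mut Optional precomputed [fit_mixture()] results;
#'   fitted here when missing.
#' @param n_boot Bootstrap pairs (default 10000).
#' @param ci Confidence level (0.95).
#' @param seed Optional seed for bootstrap and fitting.
#' @param ... Passed to [fit_mixture()] when fits are computed here.
#' @return A list: `call` (one of `more_variable_mut_typeI`,
#'   `more_variable_wt_typeI`, `more_variable_mut_typeII`,
#'   `more_variable_wt_typeII`, `not_dv`, `not_applicable`),
#'   `sd_ratio_ci` (mutant/WT, type I only), `shape_wt`, `shape_mut`,
#'   and `reason` when not applicable.
#' @export
dvsm_model_call <- function(x_wt, x_mut, fit_wt = NULL, fit_mut = NULL,
                            n_boot = 10000, ci = 0.95, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(fit_wt)) fit_wt <- fit_mixture(x_wt, ...)
  if (is.null(fit_mut)) fit_mut <- fit_mixture(x_mut, ...)
  res <- list(sd_ratio_ci = c(NA_real_, NA_real_),
              shape_wt = fit_wt$shape_class,
              shape_mut = fit_mut$shape_class, reason = NA_character_)
  if (!fit_wt$converged || !fit_mut$converged) {
    res$call <- "not_applicable"
    res$reason <- "unconverged mixture fit"
    return(res)
  }
  pure_wt <- fit_wt$shape_class == "pure_gaussian"
  pure_mut <- fit_mut$shape_class == "pure_gaussian"
  if (pure_wt && pure_mut) {
    nw <- length(x_wt); nm <- length(x_mut)
    sd_w <- sqrt(col_vars(matrix(
      x_wt[sample.int(nw, nw * n_boot, replace = TRUE)], nw)))
    sd_m <- sqrt(col_vars(matrix(
      x_mut[sample.int(nm, nm * n_boot, replace = TRUE)], nm)))
    ratio <- sd_m / sd_w
    alpha <- (1 - ci) / 2
    ci_lims <- unname(stats::quantile(ratio, c(alpha, 1 - alpha)))
    res$sd_ratio_ci <- ci_lims
    res$call <- if (ci_lims[1] > 1) "more_variable_mut_typeI"
      else if (ci_lims[2] < 1) "more_variable_wt_typeI"
      else "not_dv"
  } else if (pure_wt && fit_mut$shape_class == "low_gaussian") {
    res$call <- "more_variable_mut_typeII"
  } else if (pure_mut && fit_wt$shape_class == "low_gaussian") {
    res$call <- "more_variable_wt_typeII"
  } else {
    res$call <- "not_dv"
  }
  res
}

#' Trimmed-CV differential variability call with bootstrap and
#' permutation
#'
#' Bootstraps the mutant/WT trimmed-CV ratio (`n_boot` percentile
#' resamples per condition) and runs a label-permutation test
#' (`n_perm` shuffles of cell identity between conditions, two-sided on
#' the log ratio). The smallest reportable permutation p-value is
#' `1 / (n_perm + 1)`.
#'
#' @param x_wt,x_mut Per-cell expression of one gene in each condition.
#' @param n_boot Bootstrap resamples (default 10000).
#' @param n_perm Permutations (default 10000).
#' @param ci Confidence level for the bootstrap interval (0.95).
#' @param trim Trim fraction for [trimmed_cv()].
#' @param seed Optional seed.
#' @return A list: `cv_ratio` (observed mutant/WT), `ci` (lo, hi),
#'   `boot_call` (`more_variable_mut` / `more_variable_wt` / `not_dv` /
#'   `not_applicable`), `perm_p`.
#' @export
dvsm_cv_call <- function(x_wt, x_mut, n_boot = 10000, n_perm = 10000,
                         ci = 0.95, trim = 0.05, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cv_w <- trimmed_cv(x_wt, trim); cv_m <- trimmed_cv(x_mut, trim)
  if (!is.finite(cv_w) || !is.finite(cv_m) || cv_w == 0) {
    return(list(cv_ratio = NA_real_, ci = c(NA_real_, NA_real_),
                boot_call = "not_applicable", perm_p = NA_real_))
  }
  obs <- cv_m / cv_w
  nw <- length(x_wt); nm <- length(x_mut)
  bw <- trimmed_cv_cols(matrix(
    x_wt[sample.int(nw, nw * n_boot, replace = TRUE)], nw), trim)
  bm <- trimmed_cv_cols(matrix(
    x_mut[sample.int(nm, nm * n_boot, replace = TRUE)], nm), trim)
  ratio <- bm / bw
  ratio <- ratio[is.finite(ratio) & ratio > 0]
  alpha <- (1 - ci) / 2
  ci_lims <- unname(stats::quantile(ratio, c(alpha, 1 - alpha)))
  boot_call <- if (ci_lims[1] > 1) "more_variable_mut"
    else if (ci_lims[2] < 1) "more_variable_wt" else "not_dv"

  pooled <- c(x_wt, x_mut)
  n_tot <- nw + nm
  lobs <- abs(log(obs))
  exceed <- 0L
  for (p in seq_len(n_perm)) {
    idx <- sample.int(n_tot, nw)
    pcv_w <- trimmed_cv(pooled[idx], trim)
    pcv_m <- trimmed_cv(pooled[-idx], trim)
    if (!is.finite(pcv_w) || !is.finite(pcv_m) || pcv_w == 0 ||
        pcv_m == 0) { exceed <- exceed + 1L; next }
    if (abs(log(pcv_m / pcv_w)) >= lobs) exceed <- exceed + 1L
  }
  perm_p <- (exceed + 1) / (n_perm + 1)
  list(cv_ratio = obs, ci = ci_lims, boot_call = boot_call,
       perm_p = perm_p)
}

#' Mean-decorrelated variability rank score
#'
#' The trimmed CV falls with mean expression, so raw CVs cannot be
#' compared across expression levels. The rank score removes the trend
#' nonparametrically: genes are sorted by mean expression; within every
#' sliding window of `window` consecutive genes (stride 1), each gene's
#' trimmed CV is ranked (average ranks on ties) and the rank rescaled
#' to \[0, 1\]; a gene's score is the mean of its rescaled ranks over
#' all windows containing it. The `window - 1` genes at either extreme
#' of the mean ordering belong to fewer than `window` windows and are
#' dropped (score `NA`).
#'
#' @param means Per-gene mean expression (named or in gene order).
#' @param cvs Per-gene trimmed CVs, same length/order.
#' @param window Window size (default 150).
#' @return Numeric vector of scores in \[0, 1\], aligned with the
#'   input, `NA` for the dropped extremes.
#' @export
variability_rank_score <- function(means, cvs, window = 150) {
  G <- length(means)
  if (length(cvs) != G) stop("means and cvs must have equal length")
  if (window < 2) stop("window must be >= 2")
  if (G < 2 * window)
    stop("need at least ", 2 * window, " genes for window = ", window)
  ord <- order(means)
  cv_sorted <- cvs[ord]
  n_win <- G - window + 1
  acc <- numeric(G); cnt <- integer(G)
  for (w in seq_len(n_win)) {
    span <- w:(w + window - 1)
    r <- (rank(cv_sorted[span]) - 1) / (window - 1)
    acc[span] <- acc[span] + r
    cnt[span] <- cnt[span] + 1L
  }
  score_sorted <- ifelse(cnt == window, acc / window, NA_real_)
  out <- numeric(G)
  out[ord] <- score_sorted
  names(out) <- names(means)
  out
}

#' Call differentially variable genes from rank-score differences
#'
#' Takes the per-gene difference of variability rank scores (mutant
#' minus WT) and flags genes whose difference deviates from the mean
#' difference by more than `n_std` standard deviations of the
#' difference distribution. With a zero standard deviation (identical
#' score vectors) no gene is flagged.
#'
#' @param rank_wt,rank_mut Named per-gene scores on a common gene set
#'   (`NA` scores are dropped).
#' @param n_std 1 (permissive) or 2 (stringent); the 1-std set always
#'   contains the 2-std set.
#' @return A data.frame: `gene_id`, `rank_diff`, `dv` (logical),
#'   `direction` (`more_variable_mutant` / `more_variable_wt` / none).
#' @export
dv_call <- function(rank_wt, rank_mut, n_std = 2) {
  if (!is.null(names(rank_wt)) && !is.null(names(rank_mut))) {
    common <- intersect(names(rank_wt), names(rank_mut))
    rank_wt <- rank_wt[common]; rank_mut <- rank_mut[common]
  } else if (length(rank_wt) != length(rank_mut)) {
    stop("unnamed score vectors must have equal length")
  }
  ok <- !is.na(rank_wt) & !is.na(rank_mut)
  rank_wt <- rank_wt[ok]; rank_mut <- rank_mut[ok]
  if (length(rank_wt) < 10) stop("need at least 10 scored genes")
  d <- rank_mut - rank_wt
  m <- mean(d); s <- stats::sd(d)
  dv <- if (s == 0) rep(FALSE, length(d)) else abs(d - m) > n_std * s
  direction <- ifelse(!dv, "none",
                      ifelse(d - m > 0, "more_variable_mutant",
                             "more_variable_wt"))
  data.frame(gene_id = if (is.null(names(d)))
    paste0("gene_", seq_along(d)) else names(d),
    rank_diff = unname(d), dv = unname(dv),
    direction = unname(direction), row.names = NULL)
}

#' Differential expression between two conditions
#'
#' Per-gene screen on `a_cond = mean(log2(x + 1))`: a gene is called DE
#' when `a_wt + a_mut > sum_threshold` (adequately expressed), the
#' conditions differ by at least `lfc_threshold` on the log2 scale (a
#' 2-fold change at the default 1), and the Benjamini-Hochberg adjusted
#' p-value of a two-sample test is below `alpha`. The default test is
#' the Wilcoxon rank-sum test (robust to the non-Gaussian expression
#' shapes); Welch's t-test is available.
#'
#' @param m_wt,m_mut `ExpressionMatrix` objects, >= 3 cells each.
#' @param sum_threshold,lfc_threshold,alpha Call thresholds.
#' @param test `"wilcox"` or `"t"`.
#' @return A data.frame: `gene_id`, `a_wt`, `a_mut`, `log2_fc`,
#'   `p_value`, `p_adjusted`, `de` (logical).
#' @export
differential_expression <- function(m_wt, m_mut, sum_threshold = 3,
                                    lfc_threshold = 1, alpha = 0.05,
                                    test = c("wilcox", "t")) {
  test <- match.arg(test)
  m_wt <- as_expression_matrix(m_wt); m_mut <- as_expression_matrix(m_mut)
  if (!identical(m_wt$gene_ids, m_mut$gene_ids))
    stop("matrices must share an identical gene set")
  if (ncol(m_wt$values) < 3 || ncol(m_mut$values) < 3)
    stop("need >= 3 cells per condition")
  lw <- log2(m_wt$values + 1); lm <- log2(m_mut$values + 1)
  a_wt <- rowMeans(lw); a_mut <- rowMeans(lm)
  p <- vapply(seq_len(nrow(lw)), function(i) {
    x <- lw[i, ]; y <- lm[i, ]
    if (stats::sd(x) == 0 && stats::sd(y) == 0 && mean(x) == mean(y))
      return(1)
    if (test == "wilcox")
      suppressWarnings(stats::wilcox.test(x, y)$p.value)
    else
      tryCatch(stats::t.test(x, y)$p.value, error = function(e) 1)
  }, 1)
  padj <- stats::p.adjust(p, method = "BH")
  lfc <- a_mut - a_wt
  data.frame(gene_id = m_wt$gene_ids, a_wt = a_wt, a_mut = a_mut,
             log2_fc = lfc, p_value = p, p_adjusted = padj,
             de = (a_wt + a_mut > sum_threshold) &
               (abs(lfc) >= lfc_threshold) & (padj < alpha),
             row.names = NULL)
}

#' Enrichment of an annotation in a differentially variable gene set
#'
#' Upper-tail hypergeometric test of the overlap between a DV gene set
#' and an annotation (for example, known protein-interaction partners
#' of the disease gene) against the expressed-gene background.
#'
#' @param dv_set Character vector of DV gene ids (subset of
#'   `background`).
#' @param annotation Character vector (or named list) of annotation
#'   gene ids.
#' @param background Expressed-gene background ids.
#' @return As [cluster_enrichment()].
#' @export
dv_enrichment <- function(dv_set, annotation, background) {
  if (!length(dv_set)) {
    warning("empty DV set; enrichment p = 1")
    sets <- if (is.list(annotation)) annotation else
      list(set1 = annotation)
    return(data.frame(set = names(sets) %||%
                        paste0("set", seq_along(sets)),
                      set_size = vapply(sets, function(a)
                        length(intersect(a, background)), 1L),
                      cluster_size = 0L, overlap = 0L, p_value = 1,
                      p_adjusted = 1))
  }
  cluster_enrichment(dv_set, annotation, background)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Full per-gene variability table for a condition pair
#'
#' Runs the complete differential-variability workflow on two matched
#' matrices: expression and similar-mean filtering, per-condition
#' trimmed CVs, mixture fits and model-based calls for similar-mean
#' genes, trimmed-CV bootstrap/permutation calls, variability rank
#' scores over all expressed genes, and rank-score DV calls.
#'
#' @param m_wt,m_mut `ExpressionMatrix` objects with identical genes.
#' @param mean_cutoff Mean-difference-index cutoff (0.05).
#' @param min_detect_frac,min_mean Expression filter for the
#'   similar-mean stage.
#' @param n_boot,n_perm Resampling sizes for the CV call.
#' @param window Rank-score window (150).
#' @param n_std DV threshold in std of the rank-difference (2).
#' @param trim Trim fraction (0.05).
#' @param seed Pipeline seed; per-gene substreams derive from it.
#' @param fit_args List of extra arguments for [fit_mixture()]
#'   (e.g. `n_starts`, `max_iter`).
#' @return A data.frame with one row per gene (the variability table):
#'   means, index, filters, trimmed CVs, shapes and DVSM calls for
#'   similar-mean genes, CV ratio CI and BH-adjusted permutation p,
#'   rank scores, rank difference, and the DV call.
#' @export
dvsm_analysis <- function(m_wt, m_mut, mean_cutoff = 0.05,
                          min_detect_frac = 0.5, min_mean = 5,
                          n_boot = 10000, n_perm = 10000, window = 150,
                          n_std = 2, trim = 0.05, seed = 1L,
                          fit_args = list()) {
  m_wt <- as_expression_matrix(m_wt); m_mut <- as_expression_matrix(m_mut)
  if (!identical(m_wt$gene_ids, m_mut$gene_ids))
    stop("matrices must share an identical gene set")
  gid <- m_wt$gene_ids
  G <- length(gid)
  mean_wt <- rowMeans(m_wt$values); mean_mut <- rowMeans(m_mut$values)
  idx <- mean_difference_index(mean_wt, mean_mut)
  expressed <- filter_genes_joint(list(m_wt, m_mut), min_detect_frac,
                                  min_mean)
  similar <- expressed & !is.na(idx) & abs(idx) < mean_cutoff

  tcv_wt <- apply(m_wt$values, 1, trimmed_cv, trim = trim)
  tcv_mut <- apply(m_mut$values, 1, trimmed_cv, trim = trim)

  tab <- data.frame(gene_id = gid, mean_wt = mean_wt,
                    mean_mut = mean_mut, mean_diff_index = idx,
                    expressed = expressed, similar_mean = similar,
                    tcv_wt = tcv_wt, tcv_mut = tcv_mut,
                    shape_wt = NA_character_, shape_mut = NA_character_,
                    dvsm_call = "not_applicable",
                    cv_ratio = NA_real_, cv_ci_lo = NA_real_,
                    cv_ci_hi = NA_real_, cv_boot_call = NA_character_,
                    perm_p = NA_real_, row.names = NULL)

  for (i in which(similar)) {
    sub <- gene_subseed(seed, i)
    set.seed(sub)
    fw <- do.call(fit_mixture, c(list(m_wt$values[i, ]), fit_args))
    fm <- do.call(fit_mixture, c(list(m_mut$values[i, ]), fit_args))
    mc <- dvsm_model_call(m_wt$values[i, ], m_mut$values[i, ],
                          fit_wt = fw, fit_mut = fm, n_boot = n_boot)
    cc <- dvsm_cv_call(m_wt$values[i, ], m_mut$values[i, ],
                       n_boot = n_boot, n_perm = n_perm, trim = trim)
    tab$shape_wt[i] <- fw$shape_class
    tab$shape_mut[i] <- fm$shape_class
    tab$dvsm_call[i] <- mc$call
    tab$cv_ratio[i] <- cc$cv_ratio
    tab$cv_ci_lo[i] <- cc$ci[1]; tab$cv_ci_hi[i] <- cc$ci[2]
    tab$cv_boot_call[i] <- cc$boot_call
    tab$perm_p[i] <- cc$perm_p
  }
  tab$perm_p_adj <- NA_real_
  tab$perm_p_adj[similar] <- stats::p.adjust(tab$perm_p[similar],
                                             method = "BH")

  tab$rank_score_wt <- NA_real_
  tab$rank_score_mut <- NA_real_
  tab$rank_diff <- NA_real_
  tab$dv <- FALSE
  tab$dv_direction <- "none"
  scorable <- is.finite(tcv_wt) & is.finite(tcv_mut)
  if (sum(scorable) >= 2 * window) {
    sw <- stats::setNames(variability_rank_score(
      mean_wt[scorable], tcv_wt[scorable], window), gid[scorable])
    sm <- stats::setNames(variability_rank_score(
      mean_mut[scorable], tcv_mut[scorable], window), gid[scorable])
    tab$rank_score_wt[match(names(sw), tab$gene_id)] <- sw
    tab$rank_score_mut[match(names(sm), tab$gene_id)] <- sm
    calls <- tryCatch(dv_call(sw, sm, n_std = n_std),
                      error = function(e) {
                        warning("DV calling skipped: ",
                                conditionMessage(e))
                        NULL
                      })
    if (!is.null(calls)) {
      j <- match(calls$gene_id, tab$gene_id)
      tab$rank_diff[j] <- calls$rank_diff
      tab$dv[j] <- calls$dv
      tab$dv_direction[j] <- calls$direction
    }
  } else {
    warning("too few scorable genes for the rank score at window = ",
            window, "; DV calls skipped")
  }
  tab
}
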