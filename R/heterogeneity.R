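#' Detection-median heterogeneity statistic
#'
#' A sequencing-depth-robust summary of cell-to-cell heterogeneity for
#' one subject and cell type. Genes are ranked within each cell by
#' expression (ascending, average ranks on ties, so the most expressed
#' gene has the largest rank); the `k` genes with the largest across-cell
#' average rank are selected; for each the fraction of cells with a
#' nonzero value is computed; the median of those `k` detection
#' fractions is returned. Values near 1 mean the most highly expressed
#' genes are seen in essentially every cell (a homogeneous population);
#' low values mean even top genes drop out in many cells (high
#' heterogeneity).
#'
#' @param m An `ExpressionMatrix` holding the cells of one subject and
#'   cell type.
#' @param k Number of top-ranked genes (default 200; 100/500/1000 are
#'   common sensitivity settings).
#' @param min_cells Minimum number of cells; with fewer cells the
#'   subject is excluded and `NA` is returned with a `"excluded"`
#'   attribute.
#' @return The median detection fraction in \[0, 1\], or `NA` when
#'   excluded.
#' @export
detection_median <- function(m, k = 200, min_cells = 1) {
  em <- as_expression_matrix(m)
  if (k > nrow(em$values))
    stop("k (", k, ") exceeds the number of genes (", nrow(em$values), ")")
  if (ncol(em$values) < min_cells) {
    out <- NA_real_
    attr(out, "excluded") <- TRUE
    return(out)
  }
  ranks <- apply(em$values, 2, rank)   # ascending, average ties
  avg_rank <- rowMeans(ranks)
  top <- order(avg_rank, decreasing = TRUE)[seq_len(k)]
  detect <- rowMeans(em$values[top, , drop = FALSE] > 0)
  stats::median(detect)
}

#' Per-subject detection medians across a cohort
#'
#' Applies [detection_median()] to every subject (optionally split by
#' cell type) of a cohort and records exclusions.
#'
#' @param matrices Named list of per-subject `ExpressionMatrix` objects,
#'   or one `ExpressionMatrix` with `subject` metadata.
#' @param k,min_cells As in [detection_median()]; subjects with fewer
#'   than `min_cells` cells are excluded (default 50, the conventional
#'   floor for a stable median).
#' @return A data.frame with columns `subject`, `n_cells`, `statistic`,
#'   `excluded`.
#' @export
detection_median_by_subject <- function(matrices, k = 200,
                                        min_cells = 50) {
  if (inherits(matrices, "ExpressionMatrix")) {
    subj <- matrices$cell_meta$subject
    if (is.null(subj)) stop("subject metadata required")
    matrices <- lapply(split(matrices$cell_ids, subj),
                       function(cc) subset_matrix(matrices, cells = cc))
  }
  if (is.null(names(matrices)))
    names(matrices) <- paste0("S", seq_along(matrices))
  res <- lapply(names(matrices), function(nm) {
    mm <- matrices[[nm]]
    s <- detection_median(mm, k = k, min_cells = min_cells)
    data.frame(subject = nm, n_cells = ncol(mm$values),
               statistic = as.numeric(s),
               excluded = isTRUE(attr(s, "excluded")))
  })
  do.call(rbind, res)
}

#' Group comparison of per-subject detection medians
#'
#' One-sided Wilcoxon rank-sum test of the per-subject statistics, by
#' default testing whether the disease group has *lower* detection
#' medians (higher heterogeneity) than the reference group.
#'
#' @param statistics Numeric vector of per-subject detection medians.
#' @param groups Factor/character of group labels, two levels; the
#'   first level is taken as the reference ("healthy") group.
#' @param direction `"disease_lower"` (one-sided, default),
#'   `"disease_higher"` or `"two_sided"`.
#' @return A list with `statistic` (rank-sum W) and `p_value`.
#' @export
detection_group_test <- function(statistics, groups,
                                 direction = c("disease_lower",
                                               "disease_higher",
                                               "two_sided")) {
  direction <- match.arg(direction)
  groups <- factor(as.character(groups),
                   levels = unique(as.character(groups)))
  if (nlevels(groups) != 2)
    stop("groups must have exactly 2 levels, got ", nlevels(groups))
  ok <- !is.na(statistics)
  statistics <- statistics[ok]; groups <- droplevels(groups[ok])
  if (any(table(groups) < 2))
    stop("each group needs at least 2 subjects")
  x <- statistics[groups == levels(groups)[2]]  # disease
  y <- statistics[groups == levels(groups)[1]]  # reference
  alt <- switch(direction, disease_lower = "less",
                disease_higher = "greater", two_sided = "two.sided")
  wt <- suppressWarnings(stats::wilcox.test(x, y, alternative = alt))
  list(statistic = unname(wt$statistic), p_value = wt$p.value)
}

# genes passing the detection/mean filter in every supplied matrix
filter_genes_joint <- function(mats, min_detect_frac, min_mean) {
  ok <- rep(TRUE, nrow(mats[[1]]$values))
  for (m in mats) {
    ok <- ok & rowMeans(m$values > 0) >= min_detect_frac &
      rowMeans(m$values) > min_mean
  }
  ok
}

#' Intra-condition cell-to-cell distance distribution
#'
#' For each condition, computes 1 - Pearson correlation between the
#' expression profiles of every unordered pair of cells (a value in
#' \[0, 2\]); the distribution of these distances summarizes population
#' heterogeneity. With two matrices, the gene filter (detected in at
#' least `min_detect_frac` of cells and mean above `min_mean`) is
#' applied jointly: a gene must pass in both conditions. Set
#' `gene_filter = "all"` to use every gene (the convention for shallow
#' droplet data).
#'
#' @param m1 `ExpressionMatrix` of the first condition.
#' @param m2 Optional `ExpressionMatrix` of the second condition.
#' @param gene_filter `"expressed"` (default) or `"all"`.
#' @param min_detect_frac,min_mean Filter thresholds (0.5 and 5
#'   normalized counts).
#' @return A `DistanceDistribution` list: per-condition distance
#'   vectors, per-condition mean, `mean_difference` (condition 2 minus
#'   condition 1, when two conditions are given), the gene filter
#'   record, and per-subject median distances when subject metadata is
#'   present.
#' @export
intra_condition_distance <- function(m1, m2 = NULL,
                                     gene_filter = c("expressed", "all"),
                                     min_detect_frac = 0.5,
                                     min_mean = 5) {
  gene_filter <- match.arg(gene_filter)
  mats <- list(as_expression_matrix(m1))
  if (!is.null(m2)) mats <- c(mats, list(as_expression_matrix(m2)))
  if (length(mats) == 2 &&
      !identical(mats[[1]]$gene_ids, mats[[2]]$gene_ids))
    stop("the two matrices must share an identical gene set")
  for (m in mats)
    if (ncol(m$values) < 3) stop("need >= 3 cells per condition")
  if (gene_filter == "expressed") {
    keep <- filter_genes_joint(mats, min_detect_frac, min_mean)
    if (!any(keep))
      stop("no genes pass the filter (detected in >= ",
           min_detect_frac * 100, "% of cells, mean > ", min_mean, ")")
  } else {
    keep <- rep(TRUE, nrow(mats[[1]]$values))
  }
  per_cond <- lapply(mats, function(m) {
    v <- m$values[keep, , drop = FALSE]
    cc <- stats::cor(v)
    d <- 1 - cc[lower.tri(cc)]
    subj <- m$cell_meta$subject
    subj_median <- NULL
    if (!is.null(subj) && length(unique(subj)) > 1) {
      idx <- which(lower.tri(cc), arr.ind = TRUE)
      same <- subj[idx[, 1]] == subj[idx[, 2]]
      subj_median <- tapply(d[same], subj[idx[, 1]][same], stats::median)
    }
    list(distances = d, mean = mean(d), subject_medians = subj_median)
  })
  out <- list(
    conditions = per_cond,
    gene_filter = list(mode = gene_filter,
                       min_detect_frac = min_detect_frac,
                       min_mean = min_mean, n_genes_used = sum(keep)),
    mean_difference = if (length(per_cond) == 2)
      per_cond[[2]]$mean - per_cond[[1]]$mean else NA_real_)
  structure(out, class = "DistanceDistribution")
}

#' Compare two intra-condition distance distributions
#'
#' At cell-pair resolution (deep plate-based data) the comparison is a
#' two-sample t-test on the raw pairwise distances; at subject
#' resolution (multi-subject droplet cohorts) it is a Wilcoxon rank-sum
#' test on per-subject median distances.
#'
#' @param d1,d2 `DistanceDistribution` objects (single-condition), or a
#'   single two-condition `DistanceDistribution` as `d1`.
#' @param unit `"cell_pair"` or `"subject_median"`.
#' @return List with `mean_difference` (second minus first),
#'   `statistic`, `p_value` and `method`.
#' @export
distance_group_test <- function(d1, d2 = NULL,
                                unit = c("cell_pair", "subject_median")) {
  unit <- match.arg(unit)
  if (is.null(d2)) {
    if (length(d1$conditions) != 2)
      stop("need two conditions to compare")
    a <- d1$conditions[[1]]; b <- d1$conditions[[2]]
  } else {
    a <- d1$conditions[[1]]; b <- d2$conditions[[1]]
  }
  if (!length(a$distances) || !length(b$distances))
    stop("empty distance distribution")
  if (unit == "cell_pair") {
    if (stats::sd(a$distances) == 0 && stats::sd(b$distances) == 0) {
      warning("degenerate variances; falling back to rank-sum test")
      ht <- suppressWarnings(stats::wilcox.test(b$distances, a$distances))
      return(list(mean_difference = mean(b$distances) - mean(a$distances),
                  statistic = unname(ht$statistic), p_value = ht$p.value,
                  method = "wilcoxon_fallback"))
    }
    ht <- stats::t.test(b$distances, a$distances)
    list(mean_difference = mean(b$distances) - mean(a$distances),
         statistic = unname(ht$statistic), p_value = ht$p.value,
         method = "t_test")
  } else {
    if (is.null(a$subject_medians) || is.null(b$subject_medians))
      stop("subject metadata needed for unit = 'subject_median'")
    ht <- suppressWarnings(
      stats::wilcox.test(b$subject_medians, a$subject_medians))
    list(mean_difference = mean(b$subject_medians) -
           mean(a$subject_medians),
         statistic = unname(ht$statistic), p_value = ht$p.value,
         method = "wilcoxon_subject_medians")
  }
}
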