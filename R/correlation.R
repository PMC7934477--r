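#' Gene-gene correlation summary for two conditions
#'
#' Computes the full Spearman correlation matrix among genes in each
#' condition, the per-gene average squared off-diagonal correlation (a
#' gene's overall coupling to the rest of the regulatory network), the
#' squared-correlation difference matrix (WT squared minus mutant
#' squared, so positive entries mean decorrelation in the mutant), and
#' the standard deviation of off-diagonal correlations per condition.
#' Genes with zero variance in either condition have undefined
#' correlations; they are flagged and excluded from all summaries.
#'
#' @param m_wt,m_mut `ExpressionMatrix` objects with identical gene
#'   sets and at least 10 cells each.
#' @param gene_filter,min_detect_frac,min_mean Joint gene filter as in
#'   [intra_condition_distance()].
#' @return A `CorrelationSummary` list: `gene_ids`, `C_wt`, `C_mut`,
#'   `avg_sq` (data.frame per gene/condition), `sq_diff`, `corr_sd`
#'   (per condition), `flagged_genes` (constant in some condition).
#' @export
gene_correlations <- function(m_wt, m_mut,
                              gene_filter = c("expressed", "all"),
                              min_detect_frac = 0.5, min_mean = 5) {
  gene_filter <- match.arg(gene_filter)
  m_wt <- as_expression_matrix(m_wt); m_mut <- as_expression_matrix(m_mut)
  if (!identical(m_wt$gene_ids, m_mut$gene_ids))
    stop("matrices must share an identical gene set")
  if (ncol(m_wt$values) < 10 || ncol(m_mut$values) < 10)
    stop("need >= 10 cells per condition")
  keep <- if (gene_filter == "expressed")
    filter_genes_joint(list(m_wt, m_mut), min_detect_frac, min_mean)
  else rep(TRUE, nrow(m_wt$values))
  if (sum(keep) < 2) stop("fewer than 2 genes pass the filter")
  gid <- m_wt$gene_ids[keep]
  vw <- m_wt$values[keep, , drop = FALSE]
  vm <- m_mut$values[keep, , drop = FALSE]
  const <- apply(vw, 1, stats::sd) == 0 | apply(vm, 1, stats::sd) == 0
  flagged <- gid[const]
  gid <- gid[!const]
  vw <- vw[!const, , drop = FALSE]; vm <- vm[!const, , drop = FALSE]
  if (length(gid) < 2) stop("fewer than 2 non-constant genes")
  C_wt <- stats::cor(t(vw), method = "spearman")
  C_mut <- stats::cor(t(vm), method = "spearman")
  dimnames(C_wt) <- dimnames(C_mut) <- list(gid, gid)
  n <- length(gid)
  avg_sq_one <- function(C) (rowSums(C^2) - 1) / (n - 1)  # drop diagonal
  sq_diff <- C_wt^2 - C_mut^2
  off <- lower.tri(C_wt)
  structure(list(
    gene_ids = gid,
    C_wt = C_wt, C_mut = C_mut,
    avg_sq = data.frame(gene_id = gid,
                        wt = avg_sq_one(C_wt),
                        mut = avg_sq_one(C_mut), row.names = NULL),
    sq_diff = sq_diff,
    corr_sd = c(wt = stats::sd(C_wt[off]), mut = stats::sd(C_mut[off])),
    flagged_genes = flagged), class = "CorrelationSummary")
}

#' Compare correlation dispersion between conditions over subsample
#' replicates
#'
#' The standard deviation of off-diagonal gene-gene correlations
#' summarizes how tightly coupled the regulatory network is; a
#' decohered network has correlations concentrated near zero, hence a
#' smaller sd. To attach uncertainty, each replicate subsamples an
#' equal number of cells from both conditions without replacement and
#' recomputes the off-diagonal correlation sd.
#'
#' @param m_wt,m_mut `ExpressionMatrix` objects (identical gene sets).
#' @param n_replicates Number of subsample replicates (default 10).
#' @param subsample_frac Fraction of the smaller condition's cells per
#'   replicate (default 0.8, without replacement).
#' @param gene_filter,min_detect_frac,min_mean Joint gene filter as in
#'   [gene_correlations()].
#' @param seed Optional seed for the subsampling.
#' @return A list with `sd` (data.frame: condition, mean_sd,
#'   replicate_sd), `replicates` (matrix n_replicates x 2), and a
#'   two-tailed t-test (`statistic`, `p_value`) across replicates.
#' @export
correlation_sd_compare <- function(m_wt, m_mut, n_replicates = 10,
                                   subsample_frac = 0.8,
                                   gene_filter = c("expressed", "all"),
                                   min_detect_frac = 0.5, min_mean = 5,
                                   seed = NULL) {
  gene_filter <- match.arg(gene_filter)
  m_wt <- as_expression_matrix(m_wt); m_mut <- as_expression_matrix(m_mut)
  if (n_replicates < 2) stop("n_replicates must be >= 2")
  if (!is.null(seed)) set.seed(seed)
  n_sub <- floor(min(ncol(m_wt$values), ncol(m_mut$values)) *
                   subsample_frac)
  if (n_sub < 10) stop("subsample too small (< 10 cells)")
  keep <- if (gene_filter == "expressed")
    filter_genes_joint(list(m_wt, m_mut), min_detect_frac, min_mean)
  else rep(TRUE, nrow(m_wt$values))
  vw <- m_wt$values[keep, , drop = FALSE]
  vm <- m_mut$values[keep, , drop = FALSE]
  one_sd <- function(v, cells) {
    C <- suppressWarnings(stats::cor(t(v[, cells, drop = FALSE]),
                                     method = "spearman"))
    stats::sd(C[lower.tri(C)], na.rm = TRUE)
  }
  reps <- matrix(NA_real_, n_replicates, 2,
                 dimnames = list(NULL, c("wt", "mut")))
  for (r in seq_len(n_replicates)) {
    reps[r, 1] <- one_sd(vw, sample.int(ncol(vw), n_sub))
    reps[r, 2] <- one_sd(vm, sample.int(ncol(vm), n_sub))
  }
  ht <- stats::t.test(reps[, "wt"], reps[, "mut"])
  list(sd = data.frame(condition = c("wt", "mut"),
                       mean_sd = colMeans(reps),
                       replicate_sd = apply(reps, 2, stats::sd),
                       row.names = NULL),
       replicates = reps,
       statistic = unname(ht$statistic), p_value = ht$p.value)
}

#' Extract the cluster of genes that lose correlation together
#'
#' Clusters genes by their squared-correlation difference profiles
#' (each gene's row of the WT-squared minus mutant-squared matrix) with
#' k-means, repeats the whole clustering `n_runs` times, picks the run
#' with the lowest total within-cluster sum of squares, and returns the
#' largest cluster - in a decohering network, the coherent block of
#' genes whose mutual correlations drop together. A mean silhouette
#' width below `silhouette_min` marks the result as unstructured.
#'
#' @param summary A `CorrelationSummary` from [gene_correlations()].
#' @param k Number of clusters (default 2).
#' @param n_restarts k-means restarts within each run (default 6).
#' @param n_runs Independent repetitions; best inertia wins (10).
#' @param max_iter Maximum k-means iterations (10000).
#' @param seed Optional seed making the extraction deterministic.
#' @param selection `"declining"` (default) returns the cluster whose
#'   genes show the largest mean squared-correlation difference - the
#'   block actually losing correlation in the mutant. `"largest"`
#'   returns the biggest cluster, the original heuristic, which
#'   coincides with the declining block when most of the network
#'   decoheres but not when the decohering module is a minority.
#' @param silhouette_min Threshold under which the `no_structure`
#'   attribute is set (0.1). Set to `NA` to skip the silhouette
#'   computation on large gene sets.
#' @return Character vector of member gene ids, with attributes
#'   `cluster_sizes`, `silhouette` and `no_structure`.
#' @export
declining_cluster <- function(summary, k = 2, n_restarts = 6,
                              n_runs = 10, max_iter = 10000,
                              seed = NULL,
                              selection = c("declining", "largest"),
                              silhouette_min = 0.1) {
  stopifnot(inherits(summary, "CorrelationSummary"))
  selection <- match.arg(selection)
  x <- summary$sq_diff
  if (k > nrow(x)) stop("k exceeds the number of genes")
  if (nrow(unique(x)) < k) {
    # fewer distinct difference profiles than clusters (e.g. the exact
    # null where sq_diff is identically 0): no structure to extract
    members <- summary$gene_ids
    attr(members, "cluster_sizes") <- length(members)
    attr(members, "silhouette") <- NA_real_
    attr(members, "no_structure") <- TRUE
    return(members)
  }
  if (!is.null(seed)) set.seed(seed)
  best <- NULL
  for (run in seq_len(n_runs)) {
    km <- stats::kmeans(x, centers = k, nstart = n_restarts,
                        iter.max = max_iter)
    if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
  }
  sizes <- best$size
  pick <- if (selection == "largest") {
    which.max(sizes)
  } else {
    signal <- tapply(rowMeans(x), best$cluster, mean)
    as.integer(names(signal)[which.max(signal)])
  }
  members <- summary$gene_ids[best$cluster == pick]
  sil <- NA_real_
  if (!is.na(silhouette_min)) {
    sw <- cluster::silhouette(best$cluster, stats::dist(x))
    sil <- mean(sw[, "sil_width"])
  }
  attr(members, "cluster_sizes") <- sizes
  attr(members, "silhouette") <- sil
  attr(members, "no_structure") <- !is.na(sil) && sil < silhouette_min
  members
}

#' Hypergeometric gene-set enrichment
#'
#' Exact upper-tail hypergeometric test of the overlap between a gene
#' cluster and one or more annotation sets against an expressed-gene
#' background, with Benjamini-Hochberg adjustment across the supplied
#' sets.
#'
#' @param cluster Character vector of gene ids (must be a subset of
#'   `background`).
#' @param annotation_sets A named list of gene-id vectors, or a single
#'   vector.
#' @param background Character vector of background gene ids (the
#'   expressed genes).
#' @return A data.frame with one row per annotation set: `set`,
#'   `set_size` (in background), `cluster_size`, `overlap`, `p_value`,
#'   `p_adjusted`.
#' @export
cluster_enrichment <- function(cluster, annotation_sets, background) {
  if (!is.list(annotation_sets))
    annotation_sets <- list(set1 = annotation_sets)
  if (is.null(names(annotation_sets)))
    names(annotation_sets) <- paste0("set", seq_along(annotation_sets))
  cluster <- unique(as.character(cluster))
  background <- unique(as.character(background))
  extra <- setdiff(cluster, background)
  if (length(extra))
    stop("cluster genes missing from background: ",
         paste(utils::head(extra, 5), collapse = ", "))
  N <- length(background); n <- length(cluster)
  rows <- lapply(names(annotation_sets), function(nm) {
    ann <- intersect(unique(as.character(annotation_sets[[nm]])),
                     background)
    if (!length(ann)) {
      warning("annotation set '", nm, "' is disjoint from background")
      return(data.frame(set = nm, set_size = 0L, cluster_size = n,
                        overlap = 0L, p_value = 1))
    }
    K <- length(ann)
    x <- length(intersect(cluster, ann))
    # P(X >= x) for X ~ Hypergeometric(N, K, n)
    p <- stats::phyper(x - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set = nm, set_size = K, cluster_size = n, overlap = x,
               p_value = p)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
  out
}
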