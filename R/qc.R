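#' Quantile-normalize an expression matrix across cells
#'
#' Forces every cell (column) to share the same empirical distribution:
#' values are sorted within each cell, each rank is replaced by the mean
#' of that rank's values across cells, and the means are mapped back in
#' rank order. Removes the bias a handful of very highly expressed genes
#' introduces into per-cell totals. The operation is idempotent.
#'
#' @param m An `ExpressionMatrix` (or plain matrix) with at least 2 cells.
#' @return The normalized `ExpressionMatrix` with identical ids/metadata.
#' @export
quantile_normalize <- function(m) {
  em <- as_expression_matrix(m)
  x <- em$values
  if (ncol(x) < 2) {
    warning("quantile normalization needs >= 2 cells; returning input")
    return(em)
  }
  ord <- apply(x, 2, order)
  sorted <- matrix(0, nrow(x), ncol(x))
  for (j in seq_len(ncol(x))) sorted[, j] <- x[ord[, j], j]
  ref <- rowMeans(sorted)
  out <- x
  for (j in seq_len(ncol(x))) out[ord[, j], j] <- ref
  expression_matrix(out, gene_ids = em$gene_ids, cell_ids = em$cell_ids,
                    cell_meta = em$cell_meta)
}

#' Neural-to-embryonic marker index per cell
#'
#' Ratio of summed neural progenitor marker expression (canonically NES
#' and TUBB3) to summed embryonic stem cell marker expression (POU5F1 and
#' NANOG), used to flag residual undifferentiated cells. A zero
#' denominator with positive numerator gives `Inf` (clearly neural); a
#' 0/0 cell is returned as `NaN` and should be treated as undetermined.
#'
#' @param m An `ExpressionMatrix`.
#' @param neural_genes Character vector of neural marker gene ids.
#' @param embryonic_genes Character vector of embryonic marker gene ids.
#' @return Named numeric vector of per-cell index values.
#' @export
ne_index <- function(m, neural_genes = c("NES", "TUBB3"),
                     embryonic_genes = c("POU5F1", "NANOG")) {
  em <- as_expression_matrix(m)
  missing <- setdiff(c(neural_genes, embryonic_genes), em$gene_ids)
  if (length(missing))
    stop("marker gene(s) absent from matrix: ",
         paste(missing, collapse = ", "))
  num <- colSums(em$values[neural_genes, , drop = FALSE])
  den <- colSums(em$values[embryonic_genes, , drop = FALSE])
  idx <- num / den
  names(idx) <- em$cell_ids
  idx
}

#' Cell-level quality-control filter
#'
#' Applies four filters in a fixed order: (1) cells with fewer than
#' `min_reads` aligned reads are removed; (2) cells detecting fewer than
#' `min_gene_fraction` of all genes are removed; (3) cells with a
#' neural-to-embryonic marker index below `ne_threshold` are removed;
#' (4) outlier cells whose average Spearman correlation with the other
#' cells of their condition lies more than `mad_k` median absolute
#' deviations (unscaled MAD) from the condition median are removed.
#'
#' Stages 1 and 2 require the metadata columns `aligned_read_count` and
#' `genes_detected_fraction`; stage 3 requires the marker genes in the
#' matrix. A stage whose inputs are unavailable is skipped with a
#' warning. The correlation stage runs per condition when a `condition`
#' column is present (set `mad_per_condition = FALSE` to pool), and is
#' skipped when fewer than 3 cells remain in a stratum.
#'
#' @param m An `ExpressionMatrix`.
#' @param min_reads Minimum aligned read count (default 2e5).
#' @param min_gene_fraction Minimum fraction of genes detected (0.15).
#' @param ne_threshold Minimum neural-to-embryonic index (2); cells with
#'   index strictly smaller are discarded.
#' @param mad_k Outlier cut in MADs (5). The MAD is unscaled (no 1.4826
#'   consistency factor).
#' @param neural_genes,embryonic_genes Marker ids for the index stage.
#' @param mad_per_condition Compute the correlation outlier stage within
#'   each condition (default) or across all cells jointly.
#' @return A list with `matrix` (the filtered `ExpressionMatrix`) and
#'   `report`, a `QCReport` with per-stage removal counts and kept ids.
#' @export
qc_filter <- function(m, min_reads = 2e5, min_gene_fraction = 0.15,
                      ne_threshold = 2, mad_k = 5,
                      neural_genes = c("NES", "TUBB3"),
                      embryonic_genes = c("POU5F1", "NANOG"),
                      mad_per_condition = TRUE) {
  em <- as_expression_matrix(m)
  n_input <- length(em$cell_ids)
  keep <- em$cell_ids

  removed <- c(reads = 0L, gene_fraction = 0L, ne_index = 0L, mad = 0L)

  reads <- em$cell_meta$aligned_read_count
  if (is.null(reads)) {
    warning("no aligned_read_count metadata; read-count stage skipped")
  } else {
    bad <- em$cell_ids[!is.na(reads) & reads < min_reads]
    removed["reads"] <- length(intersect(keep, bad))
    keep <- setdiff(keep, bad)
  }

  frac <- em$cell_meta$genes_detected_fraction
  if (is.null(frac)) {
    warning("no genes_detected_fraction metadata; gene-fraction stage skipped")
  } else {
    bad <- em$cell_ids[!is.na(frac) & frac < min_gene_fraction]
    removed["gene_fraction"] <- length(intersect(keep, bad))
    keep <- setdiff(keep, bad)
  }

  if (all(c(neural_genes, embryonic_genes) %in% em$gene_ids)) {
    ne <- ne_index(em, neural_genes, embryonic_genes)
    # NaN (0/0) cells are undetermined marker states: discarded
    bad <- em$cell_ids[is.nan(ne) | ne < ne_threshold]
    removed["ne_index"] <- length(intersect(keep, bad))
    keep <- setdiff(keep, bad)
  } else {
    warning("marker genes absent from matrix; N-E index stage skipped")
  }

  kept <- subset_matrix(em, cells = keep)
  cond <- if (mad_per_condition) condition_of(kept) else NULL
  strata <- if (is.null(cond)) list(kept$cell_ids) else
    split(kept$cell_ids, cond)
  mad_bad <- character(0)
  for (cells in strata) {
    if (length(cells) < 3) {
      warning("fewer than 3 cells in a stratum; MAD stage skipped there")
      next
    }
    sub <- subset_matrix(kept, cells = cells)
    rc <- suppressWarnings(stats::cor(sub$values, method = "spearman"))
    diag(rc) <- NA
    avg <- rowMeans(rc, na.rm = TRUE)
    med <- stats::median(avg)
    dev <- stats::mad(avg, constant = 1)
    if (dev > 0)
      mad_bad <- c(mad_bad, cells[abs(avg - med) > mad_k * dev])
  }
  removed["mad"] <- length(mad_bad)
  keep <- setdiff(keep, mad_bad)

  out <- subset_matrix(em, cells = keep)
  report <- structure(list(
    n_input_cells = n_input,
    n_removed_by_reads = unname(removed["reads"]),
    n_removed_by_gene_fraction = unname(removed["gene_fraction"]),
    n_removed_by_ne_index = unname(removed["ne_index"]),
    n_removed_by_mad = unname(removed["mad"]),
    kept_cell_ids = keep), class = "QCReport")
  list(matrix = out, report = report)
}

#' @export
print.QCReport <- function(x, ...) {
  cat("QCReport:", x$n_input_cells, "cells in,",
      length(x$kept_cell_ids), "kept\n")
  cat("  removed: reads", x$n_removed_by_reads,
      "| gene fraction", x$n_removed_by_gene_fraction,
      "| N-E index", x$n_removed_by_ne_index,
      "| MAD outliers", x$n_removed_by_mad, "\n")
  invisible(x)
}
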