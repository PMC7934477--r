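#' Construct an expression matrix with per-cell metadata
#'
#' The central container of the package: a dense non-negative gene x cell
#' matrix of normalized expression values with unique gene and cell
#' identifiers and an optional per-cell metadata table. Metadata columns
#' recognised downstream are `subject`, `condition`, `cell_type`,
#' `aligned_read_count` and `genes_detected_fraction`; any other columns
#' are carried along untouched.
#'
#' @param values Numeric matrix, genes in rows, cells in columns. All
#'   values must be finite and non-negative.
#' @param gene_ids Character vector of unique gene identifiers. Defaults
#'   to `rownames(values)`.
#' @param cell_ids Character vector of unique cell identifiers. Defaults
#'   to `colnames(values)`.
#' @param cell_meta Optional data.frame of per-cell metadata with one row
#'   per cell, either in column order or keyed by a `cell_id` column.
#'
#' @return An object of class `ExpressionMatrix`: a list with elements
#'   `values`, `gene_ids`, `cell_ids`, `cell_meta`.
#' @export
#' @examples
#' m <- expression_matrix(matrix(1:6, 3, 2,
#'   dimnames = list(paste0("g", 1:3), c("c1", "c2"))))
#' dim(m)
expression_matrix <- function(values, gene_ids = rownames(values),
                              cell_ids = colnames(values),
                              cell_meta = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(gene_ids)) gene_ids <- paste0("gene_", seq_len(nrow(values)))
  if (is.null(cell_ids)) cell_ids <- paste0("cell_", seq_len(ncol(values)))
  gene_ids <- as.character(gene_ids)
  cell_ids <- as.character(cell_ids)
  if (length(gene_ids) != nrow(values))
    stop("gene_ids length (", length(gene_ids), ") != number of rows (",
         nrow(values), ")")
  if (length(cell_ids) != ncol(values))
    stop("cell_ids length (", length(cell_ids), ") != number of columns (",
         ncol(values), ")")
  if (anyDuplicated(gene_ids)) stop("gene_ids must be unique")
  if (anyDuplicated(cell_ids)) stop("cell_ids must be unique")
  if (any(!is.finite(values))) stop("expression values must be finite")
  if (any(values < 0)) stop("expression values must be non-negative")
  dimnames(values) <- list(gene_ids, cell_ids)

  if (!is.null(cell_meta)) {
    cell_meta <- as.data.frame(cell_meta)
    if ("cell_id" %in% names(cell_meta)) {
      idx <- match(cell_ids, as.character(cell_meta$cell_id))
      if (anyNA(idx))
        stop("cell_meta is missing rows for cells: ",
             paste(utils::head(cell_ids[is.na(idx)], 5), collapse = ", "))
      cell_meta <- cell_meta[idx, setdiff(names(cell_meta), "cell_id"),
                             drop = FALSE]
    } else if (nrow(cell_meta) != length(cell_ids)) {
      stop("cell_meta has ", nrow(cell_meta), " rows but there are ",
           length(cell_ids), " cells (add a cell_id column to match by id)")
    }
    rownames(cell_meta) <- cell_ids
  } else {
    cell_meta <- data.frame(row.names = cell_ids)
  }

  structure(list(values = values, gene_ids = gene_ids, cell_ids = cell_ids,
                 cell_meta = cell_meta),
            class = "ExpressionMatrix")
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat("ExpressionMatrix:", nrow(x$values), "genes x", ncol(x$values),
      "cells\n")
  if (ncol(x$cell_meta))
    cat("cell_meta columns:", paste(names(x$cell_meta), collapse = ", "),
        "\n")
  invisible(x)
}

#' Coerce to ExpressionMatrix
#'
#' Accepts a plain matrix or a `SummarizedExperiment`-derived object (for
#' example a `SingleCellExperiment`); column data becomes `cell_meta`.
#'
#' @param x Object to coerce.
#' @param ... Passed on to [expression_matrix()].
#' @return An `ExpressionMatrix`.
#' @export
as_expression_matrix <- function(x, ...) UseMethod("as_expression_matrix")

#' @export
as_expression_matrix.ExpressionMatrix <- function(x, ...) x

#' @export
as_expression_matrix.matrix <- function(x, ...) expression_matrix(x, ...)

#' @export
as_expression_matrix.default <- function(x, ...) {
  if (methods::is(x, "SummarizedExperiment") &&
      requireNamespace("SummarizedExperiment", quietly = TRUE)) {
    vals <- SummarizedExperiment::assay(x)
    meta <- as.data.frame(SummarizedExperiment::colData(x))
    return(expression_matrix(as.matrix(vals), cell_meta = meta, ...))
  }
  expression_matrix(as.matrix(x), ...)
}

#' Subset an ExpressionMatrix by genes and/or cells
#'
#' @param m An `ExpressionMatrix`.
#' @param genes Gene ids or logical/integer index over genes; `NULL` keeps
#'   all genes.
#' @param cells Cell ids or logical/integer index over cells; `NULL` keeps
#'   all cells.
#' @return The subset `ExpressionMatrix`.
#' @export
subset_matrix <- function(m, genes = NULL, cells = NULL) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  gi <- if (is.null(genes)) seq_along(m$gene_ids) else resolve_index(genes, m$gene_ids, "gene")
  ci <- if (is.null(cells)) seq_along(m$cell_ids) else resolve_index(cells, m$cell_ids, "cell")
  expression_matrix(m$values[gi, ci, drop = FALSE],
                    gene_ids = m$gene_ids[gi], cell_ids = m$cell_ids[ci],
                    cell_meta = m$cell_meta[ci, , drop = FALSE])
}

resolve_index <- function(idx, ids, what) {
  if (is.character(idx)) {
    pos <- match(idx, ids)
    if (anyNA(pos))
      stop("unknown ", what, " id(s): ",
           paste(utils::head(idx[is.na(pos)], 5), collapse = ", "))
    pos
  } else if (is.logical(idx)) {
    which(idx)
  } else {
    as.integer(idx)
  }
}

# condition labels as factor with stable level order (order of appearance)
condition_of <- function(m) {
  cond <- m$cell_meta$condition
  if (is.null(cond)) return(NULL)
  factor(as.character(cond), levels = unique(as.character(cond)))
}
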