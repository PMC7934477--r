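#' Read an expression matrix from disk
#'
#' Reads a dense TSV/CSV matrix (genes in rows, header row of cell ids,
#' first column of gene ids) or a MatrixMarket triplet file with gene and
#' cell name sidecars, and optionally merges a per-cell metadata table.
#'
#' @param path Path to the matrix file. For `format = "mtx"` the gene and
#'   cell sidecars default to `<path>.genes.txt` and `<path>.cells.txt`
#'   (one id per line).
#' @param format One of `"tsv"`, `"csv"`, `"mtx"`.
#' @param meta Optional path to a per-cell metadata TSV keyed by a
#'   `cell_id` column, or a data.frame.
#' @param genes,cells For MTX input, explicit sidecar paths.
#' @return An [expression_matrix()].
#' @export
read_matrix <- function(path, format = c("tsv", "csv", "mtx"), meta = NULL,
                        genes = NULL, cells = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format %in% c("tsv", "csv")) {
    sep <- if (format == "tsv") "\t" else ","
    df <- utils::read.table(path, header = TRUE, sep = sep,
                            check.names = FALSE, row.names = 1)
    vals <- as.matrix(df)
    if (!is.numeric(vals)) stop("matrix file contains non-numeric values")
  } else {
    if (is.null(genes)) genes <- paste0(path, ".genes.txt")
    if (is.null(cells)) cells <- paste0(path, ".cells.txt")
    for (f in c(genes, cells))
      if (!file.exists(f)) stop("MTX sidecar not found: ", f)
    sm <- Matrix::readMM(path)
    gid <- readLines(genes)
    cid <- readLines(cells)
    if (length(gid) != nrow(sm))
      stop("gene sidecar has ", length(gid), " ids but matrix has ",
           nrow(sm), " rows")
    if (length(cid) != ncol(sm))
      stop("cell sidecar has ", length(cid), " ids but matrix has ",
           ncol(sm), " columns")
    vals <- as.matrix(sm)
    dimnames(vals) <- list(gid, cid)
  }
  if (any(vals < 0)) stop("negative expression values in ", path)
  meta_df <- NULL
  if (!is.null(meta)) {
    meta_df <- if (is.character(meta)) {
      utils::read.table(meta, header = TRUE, sep = "\t",
                        check.names = FALSE, stringsAsFactors = FALSE)
    } else {
      as.data.frame(meta)
    }
  }
  expression_matrix(vals, cell_meta = meta_df)
}

#' Write an expression matrix to disk
#'
#' @param m An `ExpressionMatrix`.
#' @param path Output path.
#' @param format One of `"tsv"`, `"csv"`, `"mtx"`. MTX output writes the
#'   `<path>.genes.txt` and `<path>.cells.txt` name sidecars alongside.
#' @param meta Optional path for the per-cell metadata TSV (written only
#'   when given and metadata is non-empty).
#' @return `path`, invisibly.
#' @export
write_matrix <- function(m, path, format = c("tsv", "csv", "mtx"),
                         meta = NULL) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  format <- match.arg(format)
  if (format %in% c("tsv", "csv")) {
    sep <- if (format == "tsv") "\t" else ","
    df <- data.frame(gene_id = m$gene_ids, m$values, check.names = FALSE)
    utils::write.table(df, path, sep = sep, quote = FALSE,
                       row.names = FALSE)
  } else {
    Matrix::writeMM(Matrix::Matrix(m$values, sparse = TRUE), path)
    writeLines(m$gene_ids, paste0(path, ".genes.txt"))
    writeLines(m$cell_ids, paste0(path, ".cells.txt"))
  }
  if (!is.null(meta) && ncol(m$cell_meta)) {
    md <- data.frame(cell_id = m$cell_ids, m$cell_meta,
                     check.names = FALSE)
    utils::write.table(md, meta, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
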