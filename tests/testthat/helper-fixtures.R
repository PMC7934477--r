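# Small fixture builders shared across test files.

`%||%` <- function(a, b) if (is.null(a)) b else a

# all-Gaussian gene specs, convenient for planted-module simulations
gaussian_specs <- function(n, mu_range = c(8, 40), cv = 0.2, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    mu <- runif(1, mu_range[1], mu_range[2])
    gene_spec(sprintf("gene_%04d", i), "gaussian", mu = mu,
              sigma = cv * mu)
  })
}

# matrix with named genes/cells and optional metadata columns
toy_matrix <- function(values, genes = NULL, cells = NULL, ...) {
  values <- as.matrix(values)
  if (is.null(genes))
    genes <- rownames(values) %||% paste0("g", seq_len(nrow(values)))
  if (is.null(cells))
    cells <- colnames(values) %||% paste0("c", seq_len(ncol(values)))
  meta <- list(...)
  cm <- if (length(meta)) as.data.frame(meta) else NULL
  expression_matrix(values, gene_ids = genes, cell_ids = cells,
                    cell_meta = cm)
}

# a population of highly correlated cells around a shared profile,
# plus optional decorrelated outlier cells (shuffled profiles)
correlated_cells <- function(n_genes = 40, n_cells = 20, n_outliers = 0,
                             noise = 0.3, seed = 1) {
  set.seed(seed)
  base <- sort(runif(n_genes, 1, 100))
  vals <- sapply(seq_len(n_cells), function(i)
    pmax(base + rnorm(n_genes, 0, noise * sd(base) / 4), 0))
  if (n_outliers > 0) {
    out <- sapply(seq_len(n_outliers), function(i) sample(base))
    vals <- cbind(vals, out)
  }
  toy_matrix(vals)
}

# expression pair drawn from one shared matrix (exact global null)
null_pair <- function(n_genes = 100, n_cells = 60, seed = 1) {
  cfg <- cohort_config(n_genes = n_genes,
                       n_cells_per_condition = n_cells, seed = seed)
  sp <- simulate_pair(cfg)
  list(wt = sp$wt, mut = sp$wt, truth = sp$truth)
}
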