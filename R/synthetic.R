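#' Specify the expression distribution of one simulated gene
#'
#' Each gene draws its per-cell expression from a three-component
#' mixture: a Gaussian (truncated at 0), an exponential, and a
#' near-zero uniform on (0, 1) standing in for dropout. Pure families
#' are mixtures with a degenerate weight vector. A condition effect
#' describes how the second ("mutant") condition differs:
#' * `none` — identical distribution in both conditions;
#' * `variance_shift` — Gaussian sd multiplied by `magnitude`, mean
#'   unchanged (a differentially variable gene with similar mean);
#' * `gaussian_fraction_shift` — `magnitude` of the Gaussian weight is
#'   moved to an exponential with matching mean (a type II variability
#'   shift: more extreme values, similar mean);
#' * `mean_shift` — all values multiplied by `magnitude` (a fold-change
#'   differential expression effect).
#'
#' @param gene_id Gene identifier.
#' @param family `"gaussian"`, `"exponential"`, `"zero_spike"` or
#'   `"mixture"`.
#' @param weights Mixture weights (Gaussian, exponential, uniform);
#'   ignored unless `family = "mixture"`. Must be non-negative and sum
#'   to 1.
#' @param mu,sigma Gaussian mean and sd (expression units, sigma > 0).
#' @param rate Exponential rate (> 0).
#' @param condition_effect One of `"none"`, `"variance_shift"`,
#'   `"gaussian_fraction_shift"`, `"mean_shift"`.
#' @param magnitude Effect size for the condition effect.
#' @return A `GeneSpec` list.
#' @export
gene_spec <- function(gene_id, family = c("gaussian", "exponential",
                                          "zero_spike", "mixture"),
                      weights = NULL, mu = 10, sigma = 2, rate = 0.5,
                      condition_effect = c("none", "variance_shift",
                                           "gaussian_fraction_shift",
                                           "mean_shift"),
                      magnitude = 1) {
  family <- match.arg(family)
  condition_effect <- match.arg(condition_effect)
  weights <- switch(family,
    gaussian = c(1, 0, 0),
    exponential = c(0, 1, 0),
    zero_spike = c(0, 0, 1),
    mixture = weights)
  if (is.null(weights) || length(weights) != 3 || any(weights < 0) ||
      abs(sum(weights) - 1) > 1e-9)
    stop("weights must be a non-negative 3-vector summing to 1")
  if (sigma <= 0) stop("sigma must be > 0")
  if (rate <= 0) stop("rate must be > 0")
  if (condition_effect != "none" && magnitude <= 0)
    stop("magnitude must be > 0")
  structure(list(gene_id = as.character(gene_id), family = family,
                 weights = weights, mu = mu, sigma = sigma, rate = rate,
                 condition_effect = condition_effect,
                 magnitude = magnitude),
            class = "GeneSpec")
}

#' Configuration of a simulated two-condition cohort
#'
#' @param n_genes Number of genes.
#' @param n_cells_per_condition Cells per condition (or per subject in
#'   cohort mode).
#' @param n_subjects_per_group Subjects per group in cohort mode.
#' @param depth_range Range of multiplicative per-cell depth factors,
#'   applied before dropout.
#' @param zero_inflation_by_group Length-2 vector of dropout
#'   probabilities for the two conditions/groups, each in \[0, 1\].
#' @param module_size Number of genes in a planted co-expression module
#'   (0 for none).
#' @param module_corr_by_condition Latent-factor loadings of the module
#'   per condition; the expected pairwise gene correlation is the
#'   squared loading.
#' @param add_markers Append the four QC marker genes (NES, TUBB3 high;
#'   POU5F1, NANOG near zero)?
#' @param seed Integer seed; identical seed gives bit-identical output.
#' @return A `CohortConfig` list.
#' @export
cohort_config <- function(n_genes = 1000, n_cells_per_condition = 100,
                          n_subjects_per_group = 1,
                          depth_range = c(1, 1),
                          zero_inflation_by_group = c(0, 0),
                          module_size = 0,
                          module_corr_by_condition = c(0, 0),
                          add_markers = FALSE, seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes),
              n_cells_per_condition = as.integer(n_cells_per_condition),
              n_subjects_per_group = as.integer(n_subjects_per_group),
              depth_range = as.numeric(depth_range),
              zero_inflation_by_group = as.numeric(zero_inflation_by_group),
              module_size = as.integer(module_size),
              module_corr_by_condition = as.numeric(module_corr_by_condition),
              add_markers = isTRUE(add_markers),
              seed = as.integer(seed))
  if (cfg$n_genes < 1 || cfg$n_cells_per_condition < 1 ||
      cfg$n_subjects_per_group < 1)
    stop("counts must be >= 1")
  if (any(cfg$zero_inflation_by_group < 0 |
          cfg$zero_inflation_by_group > 1))
    stop("dropout probabilities must lie in [0, 1]")
  if (length(cfg$depth_range) != 2 || any(cfg$depth_range <= 0) ||
      diff(cfg$depth_range) < 0)
    stop("depth_range must be an increasing pair of positive factors")
  if (cfg$module_size > cfg$n_genes)
    stop("module_size cannot exceed n_genes")
  if (any(abs(cfg$module_corr_by_condition) > 1))
    stop("module loadings must lie in [-1, 1]")
  structure(cfg, class = "CohortConfig")
}

#' Default gene specifications for a simulated experiment
#'
#' A realistic mix of distribution shapes (60% Gaussian, 15%
#' exponential, 5% zero-spike, 20% mixed) with optional planted
#' condition effects: `n_dv` variance-shift genes (sd ratio `dv_sd_ratio`
#' with identical means), `n_type2` Gaussian-fraction-shift genes and
#' `n_de` mean-shift genes (fold change `de_fold`). Planted genes are
#' taken from the Gaussian pool so downstream similar-mean filters see
#' them. Gaussian means span 5-50 expression units with sd set to a
#' 0.15-0.3 coefficient of variation, the range over which variability
#' statistics are well behaved on normalized single-cell data.
#'
#' @param n_genes Number of genes.
#' @param n_dv,n_type2,n_de Numbers of planted effect genes.
#' @param dv_sd_ratio Mutant/WT Gaussian sd ratio for variance-shift
#'   genes.
#' @param type2_drop Gaussian weight moved to the heavy-tail component
#'   for type II genes.
#' @param de_fold Fold change for mean-shift genes.
#' @param seed Seed for drawing the per-gene parameters.
#' @return List of [gene_spec()] objects of length `n_genes`.
#' @export
default_specs <- function(n_genes, n_dv = 0, n_type2 = 0, n_de = 0,
                          dv_sd_ratio = 2, type2_drop = 0.4, de_fold = 2,
                          seed = 1L) {
  if (n_dv + n_type2 + n_de > n_genes)
    stop("more planted effect genes than genes")
  set.seed(seed)
  fam <- sample(c("gaussian", "exponential", "zero_spike", "mixture"),
                n_genes, replace = TRUE,
                prob = c(0.60, 0.15, 0.05, 0.20))
  n_eff <- n_dv + n_type2 + n_de
  if (n_eff > 0) fam[seq_len(n_eff)] <- "gaussian"
  specs <- vector("list", n_genes)
  for (i in seq_len(n_genes)) {
    mu <- stats::runif(1, 5, 50)
    cv <- stats::runif(1, 0.15, 0.3)
    rate <- 1 / stats::runif(1, 2, 20)
    eff <- "none"; mag <- 1
    if (i <= n_dv) {
      eff <- "variance_shift"; mag <- dv_sd_ratio
    } else if (i <= n_dv + n_type2) {
      eff <- "gaussian_fraction_shift"; mag <- type2_drop
    } else if (i <= n_eff) {
      eff <- "mean_shift"; mag <- de_fold
    }
    w <- NULL
    if (fam[i] == "mixture") {
      w <- stats::runif(3); w <- w / sum(w)
    }
    specs[[i]] <- gene_spec(sprintf("gene_%04d", i), family = fam[i],
                            weights = w, mu = mu, sigma = cv * mu,
                            rate = rate, condition_effect = eff,
                            magnitude = mag)
  }
  specs
}

# Draw n values for one gene from its mixture under a given condition.
# Module genes receive their Gaussian noise through a shared latent
# factor `latent` with loading `loading`; others pass latent = NULL.
draw_gene <- function(spec, n, condition, latent = NULL, loading = 0) {
  w <- spec$weights
  mu <- spec$mu; sigma <- spec$sigma; rate <- spec$rate
  if (condition == 2) {
    if (spec$condition_effect == "variance_shift")
      sigma <- sigma * spec$magnitude
    if (spec$condition_effect == "gaussian_fraction_shift") {
      shift <- min(w[1], spec$magnitude)
      w <- c(w[1] - shift, w[2] + shift, w[3])
      # heavy tail matched in mean so the average expression is preserved
      rate <- if (mu > 0) 1 / mu else rate
    }
  }
  comp <- sample.int(3, n, replace = TRUE, prob = w)
  x <- numeric(n)
  ng <- sum(comp == 1)
  if (ng) {
    if (!is.null(latent)) {
      eps <- stats::rnorm(ng)
      z <- loading * latent[comp == 1] + sqrt(1 - loading^2) * eps
      x[comp == 1] <- mu + sigma * z
    } else {
      x[comp == 1] <- stats::rnorm(ng, mu, sigma)
    }
  }
  if (any(comp == 2)) x[comp == 2] <- stats::rexp(sum(comp == 2), rate)
  if (any(comp == 3)) x[comp == 3] <- stats::runif(sum(comp == 3))
  if (condition == 2 && spec$condition_effect == "mean_shift")
    x <- x * spec$magnitude
  pmax(x, 0)
}

marker_specs <- function() {
  list(NES    = gene_spec("NES", "gaussian", mu = 60, sigma = 10),
       TUBB3  = gene_spec("TUBB3", "gaussian", mu = 40, sigma = 8),
       POU5F1 = gene_spec("POU5F1", "zero_spike"),
       NANOG  = gene_spec("NANOG", "zero_spike"))
}

simulate_condition <- function(specs, n_cells, condition, cfg,
                               module_idx, loading, dropout,
                               cell_prefix) {
  latent <- stats::rnorm(n_cells)
  vals <- matrix(0, length(specs), n_cells)
  for (i in seq_along(specs)) {
    in_module <- i %in% module_idx
    vals[i, ] <- draw_gene(specs[[i]], n_cells, condition,
                           latent = if (in_module) latent else NULL,
                           loading = if (in_module) loading else 0)
  }
  depth <- stats::runif(n_cells, cfg$depth_range[1], cfg$depth_range[2])
  vals <- sweep(vals, 2, depth, "*")
  if (dropout > 0) {
    drop <- matrix(stats::runif(length(vals)) < dropout,
                   nrow(vals), ncol(vals))
    vals[drop] <- 0
  }
  gid <- vapply(specs, `[[`, "", "gene_id")
  cid <- paste0(cell_prefix, seq_len(n_cells))
  list(values = vals, gene_ids = gid, cell_ids = cid)
}

#' Simulate a matched two-condition expression pair with planted truth
#'
#' Draws two gene x cell matrices ("WT" and "mutant") with
#' `n_cells_per_condition` cells each. Every gene follows its
#' [gene_spec()] mixture, with condition effects applied to the mutant
#' matrix. An optional co-expression module of `module_size` genes is
#' driven by a shared per-cell latent factor whose loading differs by
#' condition, so the expected pairwise correlation among module genes is
#' the squared loading. Per-cell depth factors and per-condition dropout
#' follow the config. The returned truth records planted differentially
#' variable, differentially expressed, module, and marker genes.
#'
#' @param config A [cohort_config()].
#' @param specs List of [gene_spec()] of length `n_genes`; defaults to
#'   [default_specs()] drawn from the config seed.
#' @return A list with elements `wt`, `mut` (both `ExpressionMatrix`)
#'   and `truth` (a `SyntheticTruth` list: `dv_gene_ids`,
#'   `dv_direction`, `de_gene_ids`, `module_gene_ids`,
#'   `marker_gene_ids`).
#' @export
simulate_pair <- function(config, specs = NULL) {
  stopifnot(inherits(config, "CohortConfig"))
  set.seed(config$seed)
  if (is.null(specs)) specs <- default_specs(config$n_genes,
                                             seed = config$seed)
  if (length(specs) != config$n_genes)
    stop("specs length (", length(specs), ") != n_genes (",
         config$n_genes, ")")
  module_idx <- integer(0)
  if (config$module_size > 0) {
    gaussian_like <- which(vapply(specs, function(s)
      s$weights[1] >= 0.99 && s$condition_effect == "none", TRUE))
    if (length(gaussian_like) < config$module_size)
      stop("not enough unperturbed Gaussian genes for the module")
    module_idx <- gaussian_like[seq_len(config$module_size)]
  }
  n <- config$n_cells_per_condition
  zi <- config$zero_inflation_by_group
  wt <- simulate_condition(specs, n, 1L, config, module_idx,
                           config$module_corr_by_condition[1], zi[1], "WT_")
  mut <- simulate_condition(specs, n, 2L, config, module_idx,
                            config$module_corr_by_condition[2], zi[2],
                            "MUT_")
  if (config$add_markers) {
    mk <- marker_specs()
    for (nm in names(mk)) {
      wt$values <- rbind(wt$values, draw_gene(mk[[nm]], n, 1L))
      mut$values <- rbind(mut$values, draw_gene(mk[[nm]], n, 2L))
      wt$gene_ids <- c(wt$gene_ids, nm)
      mut$gene_ids <- c(mut$gene_ids, nm)
    }
  }
  as_em <- function(x, condition) {
    nc <- length(x$cell_ids)
    expression_matrix(x$values, gene_ids = x$gene_ids,
                      cell_ids = x$cell_ids,
                      cell_meta = data.frame(
                        subject = rep("S1", nc),
                        condition = rep(condition, nc),
                        cell_type = rep("NPC", nc),
                        row.names = x$cell_ids))
  }
  gid <- vapply(specs, `[[`, "", "gene_id")
  eff <- vapply(specs, `[[`, "", "condition_effect")
  mag <- vapply(specs, `[[`, 1, "magnitude")
  dv <- gid[eff %in% c("variance_shift", "gaussian_fraction_shift")]
  dv_dir <- ifelse(eff[match(dv, gid)] == "gaussian_fraction_shift" |
                     mag[match(dv, gid)] > 1,
                   "more_variable_mutant", "more_variable_wt")
  names(dv_dir) <- dv
  truth <- structure(list(
    dv_gene_ids = dv,
    dv_direction = dv_dir,
    de_gene_ids = gid[eff == "mean_shift"],
    module_gene_ids = gid[module_idx],
    marker_gene_ids = if (config$add_markers)
      c(neural = "NES", neural2 = "TUBB3",
        embryonic = "POU5F1", embryonic2 = "NANOG") else character(0)),
    class = "SyntheticTruth")
  list(wt = as_em(wt, "WT"), mut = as_em(mut, "mutant"), truth = truth)
}

#' Simulate a multi-subject two-group cohort
#'
#' Emulates droplet-style per-subject data: each subject gets an
#' independent matrix drawn from the same gene specifications, with
#' per-cell depth factors from `depth_range` and group-specific dropout
#' from `zero_inflation_by_group` (group 2 typically receives the extra
#' zero inflation). Used to validate detection-median style group
#' comparisons.
#'
#' @param config A [cohort_config()].
#' @param specs Optional gene specs as in [simulate_pair()]; condition
#'   effects are ignored here (both groups draw from condition 1).
#' @return A list with `matrices` (list of per-subject
#'   `ExpressionMatrix`) and `groups` (character vector of group labels,
#'   one per subject).
#' @export
simulate_cohort <- function(config, specs = NULL) {
  stopifnot(inherits(config, "CohortConfig"))
  set.seed(config$seed)
  if (is.null(specs)) specs <- default_specs(config$n_genes,
                                             seed = config$seed)
  n_sub <- config$n_subjects_per_group
  zi <- config$zero_inflation_by_group
  mats <- list(); groups <- character(0)
  for (g in 1:2) {
    for (s in seq_len(n_sub)) {
      sid <- sprintf("G%d_S%02d", g, s)
      sim <- simulate_condition(specs, config$n_cells_per_condition, 1L,
                                config, integer(0), 0, zi[g],
                                paste0(sid, "_c"))
      nc <- length(sim$cell_ids)
      meta <- data.frame(subject = rep(sid, nc),
                         condition = rep(paste0("group", g), nc),
                         cell_type = rep("neuron", nc),
                         row.names = sim$cell_ids)
      mats[[sid]] <- expression_matrix(sim$values,
                                       gene_ids = sim$gene_ids,
                                       cell_ids = sim$cell_ids,
                                       cell_meta = meta)
      groups <- c(groups, paste0("group", g))
    }
  }
  names(groups) <- names(mats)
  list(matrices = mats, groups = groups)
}

#' Write a synthetic truth table to TSV
#'
#' @param truth A `SyntheticTruth` from [simulate_pair()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  block <- function(ids, role, detail = "") {
    n <- length(ids)
    data.frame(gene_id = as.character(ids), role = rep(role, n),
               detail = rep_len(if (length(detail)) detail else "", n))
  }
  rows <- rbind(
    block(truth$dv_gene_ids, "dv", unname(truth$dv_direction)),
    block(truth$de_gene_ids, "de"),
    block(truth$module_gene_ids, "module"),
    block(unname(truth$marker_gene_ids), "marker",
          names(truth$marker_gene_ids)))
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
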