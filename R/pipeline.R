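#' Default pipeline configuration
#'
#' Every stage parameter of the end-to-end analysis with its standard
#' default. Returned as a nested list that can be serialized to YAML
#' and round-tripped losslessly.
#'
#' @return A `PipelineConfig` list.
#' @export
#' @examples
#' cfg <- default_pipeline_config()
#' cfg$variability$window
default_pipeline_config <- function() {
  structure(list(
    input = list(wt_path = NULL, mut_path = NULL, format = "tsv",
                 meta_path = NULL, condition_col = "condition",
                 subject_col = "subject", cell_type_col = "cell_type"),
    qc = list(enabled = TRUE, min_reads = 2e5, min_gene_fraction = 0.15,
              ne_threshold = 2, mad_k = 5, mad_per_condition = TRUE),
    normalize = list(quantile = TRUE),
    heterogeneity = list(k = 200, min_cells = 50,
                         gene_filter = "expressed",
                         min_detect_frac = 0.5, min_mean = 5),
    correlation = list(gene_filter = "expressed", min_detect_frac = 0.5,
                       min_mean = 5, kmeans_k = 2, kmeans_restarts = 6,
                       kmeans_runs = 10, kmeans_max_iter = 10000,
                       n_replicates = 10, subsample_frac = 0.8),
    mixture = list(n_starts = 5, tol = 1e-8, max_iter = 1000,
                   rescale = FALSE),
    variability = list(mean_cutoff = 0.05, min_detect_frac = 0.5,
                       min_mean = 5, n_boot = 10000, n_perm = 10000,
                       window = 150, n_std = 2, trim = 0.05),
    enrichment = list(gene_sets_path = NULL),
    seed = 1L,
    out_dir = "txhet_out"), class = "PipelineConfig")
}

#' Validate a pipeline configuration
#'
#' Reads a YAML configuration file (or takes a list), fills every
#' missing key with its default, rejects unknown keys by name, and
#' collects all type/range errors rather than stopping at the first.
#'
#' @param config Path to a YAML file, or a (possibly partial) config
#'   list. An empty file yields the full default configuration.
#' @return A validated `PipelineConfig`, or an error listing every
#'   problem found.
#' @export
validate_config <- function(config = list()) {
  if (is.character(config)) {
    config <- yaml::read_yaml(config)
    if (is.null(config)) config <- list()
  }
  defaults <- default_pipeline_config()
  errors <- character(0)

  unknown_top <- setdiff(names(config), names(defaults))
  if (length(unknown_top))
    errors <- c(errors, paste0("unknown key(s): ",
                               paste(unknown_top, collapse = ", ")))
  merged <- defaults
  for (section in intersect(names(config), names(defaults))) {
    if (is.list(defaults[[section]])) {
      unknown <- setdiff(names(config[[section]]),
                         names(defaults[[section]]))
      if (length(unknown))
        errors <- c(errors, paste0("unknown key(s) in ", section, ": ",
                                   paste(unknown, collapse = ", ")))
      for (k in intersect(names(config[[section]]),
                          names(defaults[[section]])))
        if (!is.null(config[[section]][[k]]))   # NULL = keep default
          merged[[section]][[k]] <- config[[section]][[k]]
    } else {
      merged[[section]] <- config[[section]]
    }
  }

  num_check <- function(val, name, min = NULL, max = NULL,
                        strict_min = FALSE) {
    if (!is.numeric(val) || length(val) != 1 || !is.finite(val)) {
      errors <<- c(errors, paste0(name, " must be a finite number"))
      return()
    }
    if (!is.null(min)) {
      bad <- if (strict_min) val <= min else val < min
      if (bad) errors <<- c(errors, paste0(
        name, " must be ", if (strict_min) "> " else ">= ", min))
    }
    if (!is.null(max) && val > max)
      errors <<- c(errors, paste0(name, " must be <= ", max))
  }
  num_check(merged$variability$window, "variability$window", min = 2)
  num_check(merged$variability$trim, "variability$trim", min = 0,
            max = 0.49)
  num_check(merged$variability$mean_cutoff, "variability$mean_cutoff",
            min = 0, strict_min = TRUE)
  num_check(merged$variability$n_boot, "variability$n_boot", min = 1)
  num_check(merged$variability$n_perm, "variability$n_perm", min = 1)
  num_check(merged$variability$n_std, "variability$n_std", min = 1,
            max = 2)
  num_check(merged$heterogeneity$k, "heterogeneity$k", min = 1)
  num_check(merged$heterogeneity$min_cells, "heterogeneity$min_cells",
            min = 1)
  num_check(merged$qc$mad_k, "qc$mad_k", min = 0, strict_min = TRUE)
  num_check(merged$correlation$subsample_frac,
            "correlation$subsample_frac", min = 0, max = 1,
            strict_min = TRUE)
  num_check(merged$mixture$n_starts, "mixture$n_starts", min = 1)
  num_check(merged$seed, "seed", min = -2^31, max = 2^31 - 1)

  if (length(errors))
    stop("invalid configuration:\n  - ",
         paste(errors, collapse = "\n  - "))
  merged$seed <- as.integer(merged$seed)
  class(merged) <- "PipelineConfig"
  merged
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

read_gmt <- function(path) {
  if (requireNamespace("fgsea", quietly = TRUE))
    return(fgsea::gmtPathways(path))
  lines <- strsplit(readLines(path), "\t")
  stats::setNames(lapply(lines, function(x) x[-(1:2)]),
                  vapply(lines, `[[`, "", 1))
}

#' Run the full heterogeneity and differential-variability pipeline
#'
#' Orchestrates all stages on a WT/mutant condition pair: cell quality
#' control, quantile normalization, detection-median heterogeneity and
#' intra-condition distances, gene-correlation structure with declining
#' cluster extraction, per-gene mixture fits, the differential
#' variability table (DVSM calls, trimmed-CV tests, rank-score DV
#' calls), differential expression, and optional gene-set enrichment of
#' the DV set. All outputs are written as TSV to `config$out_dir`
#' together with a YAML run manifest; identical config and seed give
#' identical outputs. A stage failure aborts with the stage name and
#' leaves a `FAILED` marker in the output directory.
#'
#' @param config A `PipelineConfig` (see [validate_config()]).
#' @param wt,mut Optional `ExpressionMatrix` inputs; when missing they
#'   are read from `config$input`. Alternatively pass a single matrix
#'   as `wt` whose condition column has exactly two levels.
#' @return Invisibly, the report bundle: a list with `qc`,
#'   `heterogeneity`, `distance`, `correlation`, `mixture_fits`,
#'   `variability`, `de`, `enrichment` and `manifest`.
#' @export
run_pipeline <- function(config = validate_config(), wt = NULL,
                         mut = NULL) {
  config <- validate_config(unclass(config))
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  failed_marker <- file.path(out_dir, "FAILED")
  if (file.exists(failed_marker)) unlink(failed_marker)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(paste0(name, ": ", conditionMessage(e)), failed_marker)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  bundle <- list()

  stage("input", {
    if (is.null(wt)) {
      if (is.null(config$input$wt_path))
        stop("no input matrix: supply wt/mut or set input paths")
      wt <- read_matrix(config$input$wt_path,
                         format = config$input$format,
                         meta = config$input$meta_path)
      if (!is.null(config$input$mut_path))
        mut <- read_matrix(config$input$mut_path,
                            format = config$input$format,
                            meta = config$input$meta_path)
    }
    wt <- as_expression_matrix(wt)
    if (is.null(mut)) {
      cond <- condition_of(wt)
      if (is.null(cond) || nlevels(cond) != 2)
        stop("condition column '", config$input$condition_col,
             "' must have exactly 2 levels, found ",
             if (is.null(cond)) 0 else nlevels(cond))
      lv <- levels(cond)
      mut <- subset_matrix(wt, cells = which(cond == lv[2]))
      wt <- subset_matrix(wt, cells = which(cond == lv[1]))
    } else {
      mut <- as_expression_matrix(mut)
    }
    if (!identical(wt$gene_ids, mut$gene_ids))
      stop("the two condition matrices must share a gene set")
  })

  seed <- config$seed

  if (isTRUE(config$qc$enabled)) {
    stage("qc", {
      qw <- qc_filter(wt, min_reads = config$qc$min_reads,
                      min_gene_fraction = config$qc$min_gene_fraction,
                      ne_threshold = config$qc$ne_threshold,
                      mad_k = config$qc$mad_k,
                      mad_per_condition = config$qc$mad_per_condition)
      qm <- qc_filter(mut, min_reads = config$qc$min_reads,
                      min_gene_fraction = config$qc$min_gene_fraction,
                      ne_threshold = config$qc$ne_threshold,
                      mad_k = config$qc$mad_k,
                      mad_per_condition = config$qc$mad_per_condition)
      wt <- qw$matrix; mut <- qm$matrix
      rep_df <- data.frame(
        condition = c("wt", "mut"),
        n_input = c(qw$report$n_input_cells, qm$report$n_input_cells),
        removed_reads = c(qw$report$n_removed_by_reads,
                          qm$report$n_removed_by_reads),
        removed_gene_fraction = c(qw$report$n_removed_by_gene_fraction,
                                  qm$report$n_removed_by_gene_fraction),
        removed_ne_index = c(qw$report$n_removed_by_ne_index,
                             qm$report$n_removed_by_ne_index),
        removed_mad = c(qw$report$n_removed_by_mad,
                        qm$report$n_removed_by_mad),
        n_kept = c(length(qw$report$kept_cell_ids),
                   length(qm$report$kept_cell_ids)))
      bundle$qc <- rep_df
      write_tsv(rep_df, file.path(out_dir, "qc_report.tsv"))
    })
  }

  if (isTRUE(config$normalize$quantile)) {
    stage("normalize", {
      wt <- quantile_normalize(wt)
      mut <- quantile_normalize(mut)
    })
  }

  stage("heterogeneity", {
    het <- data.frame(
      condition = c("wt", "mut"),
      detection_median = c(
        detection_median(wt, k = min(config$heterogeneity$k,
                                     nrow(wt$values))),
        detection_median(mut, k = min(config$heterogeneity$k,
                                      nrow(mut$values)))))
    dist <- intra_condition_distance(
      wt, mut, gene_filter = config$heterogeneity$gene_filter,
      min_detect_frac = config$heterogeneity$min_detect_frac,
      min_mean = config$heterogeneity$min_mean)
    dtest <- distance_group_test(dist, unit = "cell_pair")
    dist_df <- data.frame(
      condition = c("wt", "mut"),
      mean_distance = c(dist$conditions[[1]]$mean,
                        dist$conditions[[2]]$mean),
      n_pairs = c(length(dist$conditions[[1]]$distances),
                  length(dist$conditions[[2]]$distances)),
      mean_difference = dist$mean_difference,
      test_statistic = dtest$statistic, p_value = dtest$p_value)
    bundle$heterogeneity <- het
    bundle$distance <- dist_df
    write_tsv(het, file.path(out_dir, "heterogeneity.tsv"))
    write_tsv(dist_df, file.path(out_dir, "distance.tsv"))
  })

  stage("correlation", {
    cs <- gene_correlations(
      wt, mut, gene_filter = config$correlation$gene_filter,
      min_detect_frac = config$correlation$min_detect_frac,
      min_mean = config$correlation$min_mean)
    cl <- declining_cluster(
      cs, k = config$correlation$kmeans_k,
      n_restarts = config$correlation$kmeans_restarts,
      n_runs = config$correlation$kmeans_runs,
      max_iter = config$correlation$kmeans_max_iter,
      seed = seed, silhouette_min = NA)
    corr_df <- cs$avg_sq
    corr_df$in_declining_cluster <- corr_df$gene_id %in% cl
    bundle$correlation <- list(summary = cs, cluster = cl,
                                corr_sd = cs$corr_sd)
    write_tsv(corr_df, file.path(out_dir, "correlation_summary.tsv"))
    writeLines(cl, file.path(out_dir, "declining_cluster.txt"))
  })

  stage("variability", {
    vt <- dvsm_analysis(
      wt, mut, mean_cutoff = config$variability$mean_cutoff,
      min_detect_frac = config$variability$min_detect_frac,
      min_mean = config$variability$min_mean,
      n_boot = config$variability$n_boot,
      n_perm = config$variability$n_perm,
      window = config$variability$window,
      n_std = config$variability$n_std,
      trim = config$variability$trim, seed = seed,
      fit_args = list(n_starts = config$mixture$n_starts,
                      tol = config$mixture$tol,
                      max_iter = config$mixture$max_iter,
                      rescale = config$mixture$rescale))
    bundle$variability <- vt
    write_tsv(vt, file.path(out_dir, "variability_table.tsv"))
    fits <- vt[vt$similar_mean,
               c("gene_id", "shape_wt", "shape_mut", "dvsm_call")]
    bundle$mixture_fits <- fits
    write_tsv(fits, file.path(out_dir, "mixture_calls.tsv"))
  })

  stage("differential_expression", {
    de <- differential_expression(wt, mut)
    bundle$de <- de
    write_tsv(de, file.path(out_dir, "differential_expression.tsv"))
  })

  if (!is.null(config$enrichment$gene_sets_path)) {
    stage("enrichment", {
      sets <- read_gmt(config$enrichment$gene_sets_path)
      vt <- bundle$variability
      background <- vt$gene_id[vt$expressed]
      dv_set <- intersect(vt$gene_id[vt$dv], background)
      enr <- dv_enrichment(dv_set, sets, background)
      bundle$enrichment <- enr
      write_tsv(enr, file.path(out_dir, "enrichment.tsv"))
    })
  }

  stage("manifest", {
    manifest <- list(package = "txhet",
                     version = as.character(
                       utils::packageVersion("txhet")),
                     seed = seed,
                     n_genes = nrow(wt$values),
                     n_cells = c(wt = ncol(wt$values),
                                 mut = ncol(mut$values)),
                     parameters = unclass(config))
    bundle$manifest <- manifest
    yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  })

  invisible(bundle)
}
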