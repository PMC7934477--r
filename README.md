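# txhet — transcriptional heterogeneity and differential variability in single-cell data

Neurological-disease mutations can leave a cell population's *average*
transcriptome nearly untouched while loosening the cell-to-cell control
of many genes — an effect invisible to standard differential-expression
analysis. `txhet` is an R package for detecting that effect in
single-cell RNA-seq comparisons of two conditions (for example a
disease mutant and its isogenic control, or patient and healthy
subject cohorts). It is written for computational biologists who have
normalized gene × cell expression matrices and want
variability-centric statistics with honest calibration.

## What it computes

**Population heterogeneity, robust to sequencing depth.** For each
subject, genes are ranked within each cell; the *k* = 200 genes with
the largest average rank are taken; the statistic is the median
fraction of cells detecting them:

> *detection median* = median over top-*k* genes of
> (#cells with value > 0) / (#cells).

Values near 1 mean even the top genes are seen everywhere
(homogeneous); low values mean high heterogeneity. Groups are compared
with a one-sided Wilcoxon rank-sum test on per-subject statistics.
Complementing it, the *intra-condition distance* is `1 − Pearson r`
between every pair of cells within a condition.

**Network disarray.** Spearman correlations C<sub>ij</sub> between all
gene pairs per condition; each gene's average squared correlation; the
squared-correlation difference (C<sup>WT</sup>)² − (C<sup>mut</sup>)²;
and k-means extraction of the cluster of genes that lose correlation
together.

**Per-gene distribution shape.** A 5-parameter mixture fitted by EM:

> f(x) = π<sub>G</sub> N(x; μ, σ) + π<sub>E</sub> λe<sup>−λx</sup> +
> π<sub>U</sub> 1[0 ≤ x ≤ 1]

(Gaussian = regulated expression, exponential = heavy tail,
uniform = zero-spike/dropout). π<sub>G</sub> > 0.9 is "pure Gaussian",
π<sub>G</sub> < 0.8 flags extreme-value contamination.

**Differential variability with similar means (DVSM).** For genes
whose mean difference index |(M<sup>mut</sup> − M<sup>WT</sup>) /
(M<sup>mut</sup> + M<sup>WT</sup>)| < 0.05: bootstrap CIs on the sd
ratio of two pure-Gaussian fits (type I), outright calls when one
condition alone is contaminated by extremes (type II), plus
trimmed-CV (5% per tail) bootstrap and permutation tests. For *all*
genes, the *variability rank score* — the trimmed CV ranked within
sliding windows of 150 mean-sorted genes, rescaled to [0, 1] and
averaged — removes the CV–mean dependence; genes whose score
difference exceeds 1 or 2 sd of the difference distribution are called
differentially variable (DV).

A synthetic-data generator (`simulate_pair()`, `simulate_cohort()`)
produces cohorts with planted variance shifts, mean shifts,
co-expression modules, depth variation and dropout, with ground truth
for validation.

## Worked example

Simulate a 12-subject cohort in which the disease group loses 40% of
detections, and test the heterogeneity difference:

```r
library(txhet)
cohort <- simulate_cohort(cohort_config(
  n_genes = 300, n_cells_per_condition = 200, n_subjects_per_group = 6,
  zero_inflation_by_group = c(0, 0.4), seed = 1))
med <- vapply(cohort$matrices, detection_median, numeric(1), k = 100)
round(tapply(med, cohort$groups, median), 3)
#> group1 group2
#>  1.000  0.605
signif(detection_group_test(med, cohort$groups)$p_value, 3)
#> [1] 0.00113
```

The healthy group detects its top genes in every cell (median 1.0);
dropout drags the disease group to 0.605, and the one-sided rank-sum
test finds the difference (p = 0.0011).

Plant a doubled noise sd in every gene of a mutant and measure
cell-to-cell distances:

```r
specs <- lapply(seq_len(200), function(i) {
  set.seed(i); mu <- runif(1, 8, 40)
  gene_spec(paste0("gene_", i), "gaussian", mu = mu, sigma = 0.2 * mu,
            condition_effect = "variance_shift", magnitude = 2)
})
pair <- simulate_pair(cohort_config(n_genes = 200,
  n_cells_per_condition = 150, seed = 2), specs)
d <- intra_condition_distance(pair$wt, pair$mut)
round(c(wt = d$conditions[[1]]$mean, mut = d$conditions[[2]]$mean), 3)
#>    wt   mut
#> 0.226 0.535
```

Noisier cells correlate less: the mutant's mean distance more than
doubles (0.226 → 0.535, t-test p ≈ 0).

Run the per-gene differential-variability table on a pair with 15
planted variance-shift genes (sd ratio 2, equal means) among 300:

```r
specs <- default_specs(300, n_dv = 15, n_de = 10, de_fold = 4, seed = 42)
sim <- simulate_pair(cohort_config(n_genes = 300,
  n_cells_per_condition = 120, seed = 42), specs)
vt <- dvsm_analysis(sim$wt, sim$mut, n_boot = 1000, n_perm = 999,
                    window = 50, seed = 1,
                    fit_args = list(n_starts = 3, max_iter = 500))
table(vt$dvsm_call[vt$similar_mean])
#>  more_variable_mut_typeI more_variable_mut_typeII   more_variable_wt_typeI
#>                       17                        1                        1
#>           not_applicable                   not_dv
#>                        4                      201

planted <- vt[vt$gene_id %in% sim$truth$dv_gene_ids & vt$similar_mean, ]
head(round(planted[, c("mean_wt", "mean_mut", "tcv_wt", "tcv_mut", "perm_p")], 3), 4)
#>   mean_wt mean_mut tcv_wt tcv_mut perm_p
#> 1  26.687   27.787  0.170   0.376  0.001
#> 2  19.761   21.720  0.227   0.400  0.001
#> 3  22.550   23.127  0.144   0.253  0.001
#> 4  18.348   19.258  0.126   0.244  0.001
```

The planted genes keep their means (first two columns) while their
trimmed CVs roughly double, and the permutation test calls them at its
resolution floor (p = 1/1000). The model-based calls find 17 genes
more variable in the mutant, type I. The accompanying DE screen
recovers exactly the 10 planted 4-fold genes:

```r
de <- differential_expression(sim$wt, sim$mut)
c(called = sum(de$de),
  true_positives = length(intersect(de$gene_id[de$de], sim$truth$de_gene_ids)))
#>         called true_positives
#>             10             10
```

`run_pipeline(validate_config("config.yaml"))` chains all stages (QC →
quantile normalization → heterogeneity → correlation structure →
mixture fits → DVSM/DV → DE → enrichment) and writes TSV reports plus
a reproducibility manifest; `inst/cli/txhet.R` exposes the same
functions as shell subcommands.

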