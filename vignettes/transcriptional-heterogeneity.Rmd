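---
title: "Quantifying transcriptional heterogeneity and differential variability between conditions"
author: "txhet authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying transcriptional heterogeneity and differential variability between conditions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(txhet)
```

## The question the package answers

Two cell populations — say neural progenitor cells carrying a disease
mutation and their isogenic gene-corrected controls — can have nearly
identical *average* transcriptomes and still differ in how tightly each
gene's expression is controlled from cell to cell. `txhet` implements a
family of statistics designed to detect exactly that: increased
cell-to-cell transcriptional heterogeneity and per-gene differential
variability, isolated from differences in mean expression and robust to
the technical nuisances (sequencing depth, dropout, 1–2 outlier cells)
that dominate naive variance estimates in single-cell RNA-seq.

The pipeline has four layers, each usable on its own:

1. **Population-level heterogeneity** — the detection-median statistic
   and the intra-condition distance distribution.
2. **Network-level disarray** — gene–gene Spearman correlation
   structure, its dispersion, and the cluster of genes that lose
   correlation together.
3. **Per-gene distribution shape** — a three-component mixture model
   fitted by EM.
4. **Per-gene differential variability** — similar-mean filtering,
   model-based and trimmed-CV calls with bootstrap/permutation
   inference, and the mean-decorrelated variability rank score.

## Input scale and quality control

All statistics operate on normalized, non-negative expression values
(TPM-like units). `quantile_normalize()` forces every cell to share the
same empirical distribution — each rank is replaced by the across-cell
mean of that rank's values — removing the bias a handful of very highly
expressed genes introduces into per-cell totals. The operation is exact
and idempotent; with tied values the tie is resolved by sort order, and
a column identical to the reference distribution passes through
unchanged.

`qc_filter()` applies four cell filters in a fixed order, mirroring the
stages a plate-based (Smart-seq2-style) experiment needs: minimum
aligned reads (default `2e5`), minimum fraction of genes detected
(`0.15`, "detected" meaning a value strictly above 0 — no expression
floor is imposed), a marker-ratio filter (`ne_index()`, the summed
neural markers NES + TUBB3 over the summed embryonic markers POU5F1 +
NANOG, with cells below 2 discarded, the boundary value kept), and a
correlation-outlier filter: within each condition, a cell whose average
Spearman correlation with the other cells sits more than `mad_k = 5`
*unscaled* MADs (no 1.4826 consistency factor; the multiplier is
configurable) from the median is removed. The MAD cut is two-sided and
computed per condition by default (`mad_per_condition = FALSE` pools all
cells); with fewer than three cells in a stratum the stage is skipped
with a warning rather than guessed.

## The detection-median heterogeneity statistic

Droplet-scale patient data can vary a hundred-fold in reads per cell,
which makes variance-based comparisons between subjects meaningless.
`detection_median()` therefore only asks a rank-level question: *do the
most highly expressed genes show up in every cell?* Genes are ranked
within each cell (ascending, average ranks on ties, so "largest average
rank" means highest expression — a convention the statistic's
scale-invariance does not depend on); the `k = 200` genes with the
largest across-cell average rank are selected; each gene's detection
fraction (cells with a nonzero value) is computed; and the median of
those `k` fractions is returned. A homogeneous population yields values
near 1; heterogeneous populations leak zeros even into their top genes
and drift toward 0. `k` is configurable (100/500/1000 are the usual
sensitivity settings — smaller datasets warrant smaller `k`). In
multi-subject mode (`detection_median_by_subject()`) subjects under
`min_cells = 50` are excluded and recorded, and
`detection_group_test()` compares the per-subject statistics with a
one-sided Wilcoxon rank-sum test (disease lower, i.e. more
heterogeneous, by default).

Because the statistic only uses within-cell ranks and detection, it is
invariant to any per-cell rescaling (depth), and subsampling cells to
50% moves it by less than 0.05 on populations of a few hundred cells —
properties asserted directly in the test suite.

## Intra-condition distances and correlation disarray

`intra_condition_distance()` computes `1 − Pearson r` between the
expression profiles of every unordered pair of cells within a
condition, a value in [0, 2]; the distribution's location summarizes
population heterogeneity. For deep plate-based data, genes are first
filtered to those detected in at least half the cells with mean
expression above 5 normalized counts — jointly, so a gene must pass in
*both* conditions being compared; for shallow droplet data
`gene_filter = "all"` is the appropriate setting. Two distributions are
compared either per cell pair (two-sample t-test, with a rank-sum
fallback when variances degenerate) or per subject median (rank-sum),
matching the two resolutions at which such data come.

`gene_correlations()` moves from cells to genes: Spearman correlation
matrices per condition, each gene's average squared off-diagonal
correlation (its overall coupling to the rest of the network), and the
squared-correlation difference matrix, oriented WT² − mutant² so that
positive values mean decorrelation in the mutant. Constant genes have
no defined correlation and are flagged and excluded rather than
imputed. `correlation_sd_compare()` attaches uncertainty to the
dispersion of correlations by recomputing it over `n_replicates = 10`
subsamples (80% of the smaller condition's cells, drawn without
replacement — the resampling scheme is a package choice, exposed as
parameters).

`declining_cluster()` extracts the block of genes that lose correlation
together: k-means (`k = 2`, 6 restarts, 10 independent runs, best total
within-cluster sum of squares wins) on the rows of the
squared-correlation difference matrix. Two genuinely open choices are
documented here:

* **Feature space.** Each gene's *row* of the difference matrix is its
  feature vector — genes decorrelating with the same partners cluster
  together. A scalar per-gene summary (difference of average squared
  correlations) is a coarser alternative; the row profile retains the
  information about *which* correlations moved and is the default.
* **Cluster selection.** When most of a network decoheres, the
  decorrelating block is also the biggest cluster and
  `selection = "largest"` (the simple heuristic) finds it. When the
  decorrelating module is a minority — as in any experiment with a
  localized effect, and in our planted-truth validations — the largest
  cluster is exactly the *unaffected* complement. The default
  `selection = "declining"` therefore picks the cluster with the larger
  mean squared-correlation difference, which is the scientifically
  intended object in both regimes. A mean silhouette width below 0.1
  marks the extraction as unstructured, and the exact-null case
  (identical conditions, difference matrix all zero) short-circuits
  with a `no_structure` flag instead of clustering noise.

Gene-set enrichment of any extracted cluster uses the exact upper-tail
hypergeometric test against an expressed-gene background
(`cluster_enrichment()`), with Benjamini–Hochberg adjustment across the
annotation sets supplied.

## The three-component expression mixture

Per-gene expression distributions in normalized single-cell data fall
into a small set of shapes: a regulated, roughly Gaussian state; a
heavy-tailed exponential; a near-zero spike from dropout; and mixtures
of these. `fit_mixture()` models a gene's values as

$$f(x) = \pi_G\,\mathcal{N}(x;\mu,\sigma) + \pi_E\,\lambda e^{-\lambda x}
       + \pi_U\,\mathbf{1}[0 \le x \le 1],$$

five free parameters in all (two weights, `mu`, `sigma`, `lambda`; the
uniform has none). Fitting is plain EM — closed-form M-steps for every
parameter — with these numerical choices:

* **Initialization.** One moment-based start (`pi` uniform; `mu`,
  `sigma` from the moments of values above 1; `lambda` as the
  reciprocal mean of the positive values below the median) plus
  `n_starts − 1 = 4` randomized perturbations; the best final
  log-likelihood wins.
* **Degeneracy guards.** `sigma` is floored at `1e-3` times the data
  sd so the Gaussian cannot collapse onto a point; observations with
  essentially zero density under every component (possible when weights
  vanish) are attributed to the zero-spike with an `1e-12` floor so the
  E-step stays defined; an all-constant gene returns a flagged
  degenerate fit rather than running EM.
* **Convergence.** Absolute log-likelihood change below `tol = 1e-8`
  or `max_iter = 1000`. The log-likelihood trace is returned, and its
  monotonicity is asserted in the tests (to `1e-8` slack).
* **Scale.** Fits run on the quantile-normalized values as given; the
  zero-spike component lives on (0, 1) of that scale. Because the
  appropriate scale can be debatable for other normalizations, a
  `rescale` flag (divide by the gene's maximum) is provided.

`classify_shape()` reduces a fit to three classes with strict
inequalities: Gaussian weight above 0.9 is `pure_gaussian`, below 0.8
is `low_gaussian` (extreme zeros and/or large values present), between
them `mixed`.

## Differential variability with similar means

Comparing variability is only meaningful once mean differences are
controlled. A gene qualifies for the similar-mean analysis when it is
detected in at least half the cells with mean above 5 in both
conditions, and its mean difference index
$(M^{mut} - M^{WT}) / (M^{mut} + M^{WT})$ is strictly below 0.05 in
absolute value (roughly a 10% mean difference; 0.1 is the standard
sensitivity setting). The index, not the ratio it approximates, is the
authoritative cutoff.

For qualifying genes two complementary calls are made:

* **Model-based (`dvsm_model_call()`).** Both conditions pure Gaussian
  → *type I*: bootstrap both samples (10,000 pairs by default), form
  the mutant/WT sd ratio per pair, and call the gene in whichever
  direction the 95% percentile interval clears 1. One condition pure
  Gaussian, the other with Gaussian weight below 0.8 → *type II*: the
  contaminated condition is called more variable outright. Everything
  else is no call; unconverged fits are `not_applicable` with a reason.
* **CV-based (`dvsm_cv_call()`).** The trimmed CV (sd/mean after
  dropping `floor(n · 0.05)` values per tail — at least one per tail
  for the required `n ≥ 20` — which immunizes the statistic against the
  1–2 extreme cells that can otherwise double a CV) is compared via a
  percentile bootstrap interval on the ratio and a label-permutation
  test (two-sided on the log ratio, `p = (b + 1)/(n_{perm} + 1)`, so
  the smallest reportable p is `1/(n_{perm}+1)`).

The ratio orientation is mutant/WT throughout, so interval bounds read
directly as "mutant more variable" above 1. Benjamini–Hochberg
adjustment of permutation p-values across genes is applied by the
table-level caller (`dvsm_analysis()`), not inside the per-gene
function. All resampling derives from one pipeline seed through
deterministic per-gene substreams, so results do not depend on the
order in which genes are processed.

## The variability rank score

The trimmed CV falls systematically with mean expression, so raw CVs
cannot be compared across expression levels, and any between-condition
mean shift would masquerade as a variability change.
`variability_rank_score()` removes the trend nonparametrically: sort
genes by mean; slide a window of 150 consecutive genes (stride 1);
within each window rank the trimmed CVs (average ranks on ties — the
tie convention is a documented choice) and rescale ranks to [0, 1]; a
gene's score is the mean over the windows containing it. The 149 genes
at each extreme of the mean ordering belong to fewer windows and are
dropped (`NA`) rather than scored on partial evidence. Because the
construction only uses ranks, the score is invariant to any strictly
monotone transform of the CVs, and on data with a planted
`1/sqrt(mean)` CV trend its Spearman correlation with the mean is below
0.05 in magnitude while the raw CV's exceeds 0.3 — the decorrelation
the score exists to provide. The window width trades locality of the
mean correction against rank resolution; 150 is stable in practice and
is the default.

`dv_call()` takes the per-gene score difference (mutant − WT) and flags
genes deviating from the mean difference by more than 1 or 2 standard
deviations of the difference distribution (the 1-std set always
contains the 2-std set; identical score vectors give a zero sd and,
deliberately, zero calls). Because the threshold is empirical, two
*independent* samples from the same distribution will still flag a few
percent of genes — only the exact null (the same data as both
conditions) guarantees zero calls, which is how the pipeline's
global-null invariant is validated.

## Differential expression

The accompanying DE screen calls a gene when the sum of the two
conditions' `mean(log2(x + 1))` values exceeds 3 (adequately
expressed), the conditions differ by at least 1 on that scale (2-fold),
and the BH-adjusted p-value of a two-sample test is below 0.05. The
per-gene test is the Wilcoxon rank-sum by default — robust to the
mixture shapes above — with Welch's t-test behind a flag. Note one
interaction worth knowing: the +1 pseudo-count shrinks fold changes at
moderate expression, so a gene whose raw mean doubles lands slightly
*below* the 2-fold rule; planted-recovery validations therefore use
4-fold effects.

## The synthetic cohort generator

`simulate_pair()` and `simulate_cohort()` generate data with exactly
the structure the statistics assume, plus planted ground truth for
recovery tests. Per-gene values are drawn from the same mixture family
the model fits (Gaussian truncated at zero — expression is
non-negative; exponential; Uniform(0, 1) as the zero-spike, mirroring
the component being recovered). Condition effects: `variance_shift`
multiplies the Gaussian sd leaving the population mean untouched (the
canonical DVSM gene); `gaussian_fraction_shift` moves Gaussian weight
onto an exponential matched in mean (a type II gene: more extreme
values, similar mean); `mean_shift` scales all values (a DE gene). A
planted co-expression module runs a shared per-cell latent factor
through each member gene with per-condition loading `a`, giving
expected pairwise correlations of `a²` while *preserving each gene's
marginal variance* — which is why module loadings model decorrelation
but not noise differences; noise differences are planted with
`variance_shift`. Depth variation is multiplicative per cell (uniform
over `depth_range`), applied before Bernoulli dropout with per-group
probability, emulating droplet cohorts where one group detects fewer
genes per cell.

The default gene mix (60% Gaussian, 15% exponential, 5% zero-spike,
20% random mixtures; Gaussian means uniform on 5–50 expression units
with CVs of 0.15–0.3) reflects the composition of normalized
plate-based data at moderate depth. What the generator does *not*
emulate: UMI/read-level sampling noise, batch structure beyond
depth/dropout, mean–variance coupling beyond the configured CV range,
and correlated dropout. Passing recovery tests on these simulations
therefore demonstrates correctness of the statistics under their own
assumptions, not robustness to every artifact of real data.

## Pipeline, determinism, and problem sizes

`run_pipeline()` chains QC → quantile normalization → heterogeneity →
correlation structure → mixture fits → differential variability → DE →
optional enrichment, writing one TSV per stage plus a YAML manifest
(package version, seed, full parameter snapshot) sufficient to
reproduce the run; identical config and seed give byte-identical
outputs. A stage failure aborts with the stage name and leaves a
`FAILED` marker next to whatever partial outputs exist.
`validate_config()` fills every default, rejects unknown keys by name,
and reports *all* type/range errors at once. A thin command-line
wrapper over these functions ships in `inst/cli/txhet.R`.

The test suite and the acceptance script run entirely on generated
data, at sizes chosen to make each property measurable in seconds to a
few minutes on one core: tens to hundreds of genes and 40–500 cells for
unit properties; 1,000 genes × 150 cells for planted-module recovery;
1,000-gene nulls with 500-resample bootstraps and 199-permutation tests
for calibration; 1,000 simulations for bootstrap CI coverage; 5,000
genes for the rank-score decorrelation property. These are the
package's validation conditions; the statistics themselves carry no
size-dependent constants beyond the documented defaults.

## Known limitations

* The mixture EM maximizes likelihood over a fixed three-component
  family; it does not select model order, and bursty-kinetics
  (negative-binomial) alternatives are deliberately out of scope.
* The 2-std DV threshold is empirical per dataset pair; DV sets are
  not comparable across pairs without recalibration.
* The MAD outlier filter assumes a unimodal population per condition;
  a genuine subpopulation can be clipped if small enough.
* Permutation p-values are bounded below by `1/(n_perm + 1)`;
  genome-scale FDR control at stringent thresholds needs
  correspondingly many permutations.
* The generator's dropout is uncorrelated Bernoulli after depth
  scaling; the joint depth–dropout law of real droplet data is not
  modeled and both knobs are free parameters.
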