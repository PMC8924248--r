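---
title: "Benchmarking brain transcriptome deconvolution: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking brain transcriptome deconvolution: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(deconvbench)
```

## The problem

Bulk RNA-seq of brain tissue measures a mixture: each sample's expression
vector $X$ is, to a good approximation, a non-negative combination of the
expression profiles of its constituent cell types,

$$X \approx S\,P,$$

where $S$ is a gene $\times$ cell-type *signature matrix* of pure-cell-type
profiles and $P$ is the vector of cell-type proportions. *Partial
deconvolution* estimates $P$ given $X$ and $S$. Because cell types differ
substantially in RNA content (neurons carry roughly twice the mRNA of glia),
what deconvolution actually recovers is the share of sequenced RNA
contributed by each type (**pRNA**), not the share of cells (**pCt**). The
package records both ground truths for every simulated mixture and treats
pRNA as the evaluation default; the pRNA-vs-pCt comparison is itself one of
the benchmarked claims.

Composition matters beyond composition itself: when two groups of samples
differ in cell-type make-up, genes that mark the shifted type appear
differentially expressed even though no cell changed its expression. The
package quantifies this confound and the efficacy of including composition
estimates as model covariates.

## The synthetic-data generator

Real single-nucleus resources cannot be redistributed with a package, so
every benchmark here runs on synthetic data with *planted* structure. The
generator (`synthetic_config()`, `generate_single_cell()`) is a stand-in,
not a fitted model of any particular dataset; its distributional choices
are deliberately generic RNA-seq assumptions:

* **Baseline means** are log-normal (`meanlog = 1`, `sdlog = 1.5`),
  reproducing the long-tailed dynamic range that expression-threshold rules
  (e.g. "> 1 CPM in at least one type") implicitly assume.
* **Markers**: each type receives a disjoint set of marker genes whose mean
  is multiplied by `marker_fold` (default 8) in that type. Markers are
  planted among genes above the lower expression quartile so that marker
  recovery is a property of the selection method, not of sequencing depth.
* **Counts** are negative-binomial with a shared overdispersion (default
  0.3, a typical single-cell value); `dispersion = 0` degenerates to
  Poisson, which the exact small-sample tests exploit.
* **Library sizes** are log-normal per cell with a per-type location. The
  default gives neuronal types ~4000 counts/cell and glial types ~2000, a
  2-fold RNA-content difference — the condition under which pRNA and pCt
  visibly diverge. This knob is first-class because the pRNA/pCt contract
  is vacuous when all types have equal RNA content.
* **Subjects**: cells are assigned uniformly to `n_subjects` (default 4)
  subjects, each contributing multiplicative per-gene noise
  (`subject_sd = 0.1` on the log scale). This is what the subject-weighted
  solver exploits.
* **Compartment genes**: disjoint nuclear-enriched and nuclear-depleted
  sets (100 + 100, fold 2) drive the paired whole-cell/nuclear bulk
  simulator (`generate_paired_compartments()`), which draws five samples
  per arm at 10M counts with mild overdispersion (0.02), i.e. close to
  technical replication of the same tissue.
* **Mitochondrial fraction** is an independent Beta(2, 98) draw per cell
  (mean 2%), exercising the QC path; datasets may omit it, in which case
  the QC filter skips that rule.

The default composition is a five-type cortical profile (40% excitatory,
20% inhibitory, 20% astrocyte, 15% oligodendrocyte, 5% microglia). What the
generator does **not** emulate: doublets, ambient RNA, UMI saturation,
zero-inflation beyond NB sampling, gene length (all normalisation is CPM),
or realistic gene–gene correlation structure. Passing benchmarks here
therefore demonstrates correctness of the machinery and the qualitative
confound phenomena, not performance on any real tissue.

## Mixture designs

All mixtures are built by summing raw counts of sampled cells (without
replacement within a mixture) and normalising to CPM. Summing then
normalising is equivalent to averaging up to a scalar that CPM removes.
Four designs are provided:

1. **Random** (`simulate_random_mixtures()`): 100 mixtures of 500 cells
   drawn from the whole dataset; compositions concentrate near the dataset
   frequencies.
2. **Wide-range** (`simulate_wide_range_mixtures()`): per type $j$ a
   uniform draw between 1 and $n_j = (n/k) / (s_j / \min s)$ cells, where
   $s_j$ is the type's total library size; overshoot is subsampled to $n$
   and undershoot topped up from any type. $n_j$ is rounded to the nearest
   integer and clamped below at 1 (with a warning). The caps deflate
   RNA-rich, abundant types, so compositions span a much wider range —
   the intended regime for testing identifiability across abundances.
   Note that on strongly imbalanced datasets the caps for dominant types
   become small and the top-up step pulls compositions back toward the
   dataset frequencies; the variance-widening guarantee is therefore
   demonstrated on a balanced dataset.
3. **Confounded groups** (`simulate_confounded_groups()`): two 50-sample
   groups; group A samples contain $n \sim U\{200..300\}$ target-type
   cells out of 500, group B shifts that range by $k$, giving an expected
   pCt difference of $k/500$.
4. **Perturbed expression** (`perturb_expression()`): plants known
   fold-changes (100 top markers of the target type plus 100 random
   non-markers, half up-, half down-regulated) either on mixture counts
   before re-normalisation ("bulk" mode) or only on cells of one type
   before aggregation ("cell-type" mode). Which group carries the
   perturbation is a required explicit argument rather than a default,
   since the direction of the comparison is an experimental choice.

`truth_pRNA` is exactly recomputable from the stored manifest and source
counts (`recompute_pRNA()`); the test suite asserts bit-identity.

## The four solvers

All solvers consume linear-scale CPM/RPKM expression (log transforms happen
only inside the marker-offset estimator), return row-normalised
non-negative mixture × cell-type estimates, and are deterministic.

* **NNLS** (`deconvolve_nnls()`): per mixture, $\min \|Sp - x\|_2$ subject
  to $p \ge 0$ (Lawson–Hanson, via `pracma::lsqnonneg`), then renormalise.
  Because estimates are defined only up to scale after renormalisation, the
  brute-force oracle used in tests scans the simplex with the overall scale
  profiled out per grid point.
* **nu-SVR** (`deconvolve_svr()`): mixture and signature columns are
  standardised over the used genes, a linear-kernel nu-SVR is fit for each
  nu in {0.25, 0.5, 0.75} (via `e1071::svm`), and the fit with the lowest
  reconstruction RMSE is kept. Coefficients are mapped back to the original
  column scales — dividing by each signature column's standard deviation —
  before clipping at zero and renormalising; without this back-transform
  the per-column standardisation systematically biases the renormalised
  proportions. Following the convention of SVR-based tools, which operate
  on compact signatures of a few hundred discriminative genes, the fit is
  restricted to the `max_genes = 1000` genes with the largest log-scale
  spread across types when the aligned space is larger. This is a
  faithful re-implementation of the nu-grid/RMSE-selection/clip/renormalise
  core only; permutation p-values and signature construction of the
  original tools are out of scope.
* **Marker-offset linear mixing** (`deconvolve_dtangle()`): for each type,
  the average offset between mixture and signature over that type's
  markers on the $\log_2(x + 0.5)$ scale; proportions are renormalised
  antilogs. This is a deliberately simple reading of marker-based
  linear-mixing estimators ("dtangle-style"), not a clone of any package.
* **Subject-weighted NNLS** (`deconvolve_wnnls()`): starting from plain
  NNLS, gene weights are the reciprocal of (cross-subject variance of the
  gene's reconstruction under current proportions + current residual
  variance), and weighted NNLS is iterated until the proportion change
  falls below 1e-6 or 50 iterations. The cross-subject variance term is
  the essential idea retained from multi-subject weighting schemes; the
  original cell-size corrections are not reproduced. A single-subject
  reference falls back to NNLS with a warning.

## Signatures and markers

Signatures are per-type means of normalised single-cell profiles.
Thresholding keeps genes strictly above `min_expr` (default 1 CPM/RPKM) in
at least one type — strict because the rule is worded "> 1". Merging
(`merge_signatures()`) quantile-normalises **all columns of all inputs
jointly** (target = mean of sorted columns, ties by average rank), then
averages each cell type across sources. Whether to normalise jointly or
per-source is genuinely open; joint normalisation is implemented because
averaging across sources is only meaningful on a common scale, and the
alternative is a one-line change.

The marker "diff" score of gene $g$ for type $j$ is
$\overline{\log_2(x+0.5)}_j - \max_{j' \ne j} \overline{\log_2(x+0.5)}_{j'}$;
each gene belongs to the type maximising its score, and the top count (or
fraction) per type is kept, ties broken by gene id. This is our reading of
the "diff" marker method of marker-based deconvolution tools, which do not
print a formula.

The compartment filter (`filter_compartment_genes()`) runs a per-gene
pooled-variance OLS t-test on $\log_2(x+0.5)$ between nuclear and
whole-cell arms and flags genes with **linear-scale** fold-change magnitude
> 1.3 *and* BH-FDR < 0.05 — the fold gate is computed on the ratio of arm
means on the linear scale, consistent with how such thresholds are usually
stated, while the test runs on the log scale where variances are stable.

## Differential expression and the confound experiment

`differential_expression()` fits per-gene OLS of $\log_2(\text{CPM}+0.5)$
on a two-group indicator plus optional covariate terms — linear, quadratic,
or a cubic B-spline basis with interior knots at the covariate's
25th/50th/75th percentiles — using one QR decomposition shared across all
genes, with two-sided t p-values and BH correction. Genes with mean CPM
below 1 are excluded in the orchestrated experiment
(`run_confound_experiment()`): at 10,000 genes this retains ~99% of genes
while removing count-poor genes whose discretised p-values would distort
calibration; the enrichment background is the filtered set.

Marker enrichment among false positives uses the hypergeometric upper tail
(one-sided Fisher) per type and is only computed when more than 100 false
positives exist (strictly; at exactly 100 it reports missing values), to
ensure the test is adequately powered. Discriminatory power is the
fraction of truly perturbed genes among the top-$|perturbed|$ genes by
p-value, with ties broken by $|\log_2 FC|$ descending then gene id, so the
ranking is deterministic — tie handling is unspecified in the original
description and had to be fixed somehow. The robustness threshold is the
smallest tested composition shift whose power falls below 0.95 times the
uncorrected zero-shift baseline; if none does, the largest tested shift is
returned flagged "not reached".

The covariate used for correction is configurable: the true target-type
pRNA (oracle) or an NNLS estimate. Oracle truth is the default in the
acceptance quantities so that the *correction* mechanism is evaluated
separately from estimator error.

A practical note on small gene panels: perturbing the target type's top
markers moves a non-trivial share of the library when the panel is small
(e.g. 1000 genes), so CPM renormalisation shifts *all* genes and creates
genuine — if artifactual — group differences even at zero composition
shift. At the standard 10,000-gene scale the perturbed genes are a
negligible library share and this effect vanishes; the test suite asserts
the inflation/correction claims at that scale only.

## Numerical choices and degenerate inputs

* Undefined correlations (zero-variance truth) and undefined nmae (zero
  mean truth) are reported as missing, never coerced to 0.
* Estimates with every SVR coefficient non-positive return uniform
  proportions and are flagged in diagnostics.
* A signature with an all-zero column is rejected (unidentifiable type).
* All randomness flows from one seed through named, order-independent
  substreams (`substream_seed()`), so inserting a stage does not shift the
  randomness of others and any stage can be replayed in isolation.
* QC count thresholds are strict ("fewer than 1000 counts" removes a
  999-count cell, keeps a 1000-count cell); types dropping below 200 cells
  after cell filters are removed entirely.
* `collinearity_diagnostics()` uses Spearman's rho by default (the
  published threshold is stated as "rho" without further specification;
  rank correlation is what degrades separability), switchable to Pearson.
* Goodness-of-fit quantile normalisation pools mixtures and signature as
  one column set by default; per-matrix and no-normalisation modes exist
  because the pooling convention is not uniquely determined.

## Problem sizes

The shipped tests and the acceptance script run entirely on synthetic data
at sizes chosen to exercise every claim while keeping a full run fast on a
single CPU: unit fixtures use 1,000–2,000 genes and a few hundred cells;
the calibration and confound experiments use the full default conditions
(10,000 genes, 3,000 cells, 100 samples of 500 cells each); null
calibration uses 20 seeds in the test suite and 10 in the acceptance
script. Identifiability uses 100 noiseless constructed mixtures; the
two-type grid oracle uses 50 noisy instances at grid step 1e-3.

## Known limitations

* The generator's independence across genes understates the correlation
  structure of real tissue; collinearity between synthetic cell types is
  mild compared to, say, neuronal subtypes.
* The SVR core reproduces the estimation step only — not the original
  tools' preprocessing, permutation statistics, or signature construction;
  likewise the marker-offset and subject-weighted solvers are documented
  simplifications.
* Reference-free (complete) deconvolution, enrichment-score tools, and
  negative-binomial GLM differential expression are out of scope; the OLS
  arm fully covers the covariate-correction comparison implemented here.
* RPKM normalisation requires user-supplied gene lengths; lengths are
  never computed from annotation.
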