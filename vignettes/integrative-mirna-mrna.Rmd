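---
title: "Integrative miRNA-mRNA signature analysis with mirmint"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrative miRNA-mRNA signature analysis with mirmint}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirmint)
```

# The problem

Small cohorts of treated patients are often profiled on two molecular
layers at once: miRNA and mRNA expression measured on the *same* samples,
with a binary clinical outcome (here: long versus short progression-free
survival under an anti-EGFR regimen). Each layer alone has far more
features than samples (p, q >> n), and miRNAs act by repressing their
target transcripts, so the biologically interesting structure lives in
the *joint* anticorrelation between the layers, filtered through what
target-prediction databases consider plausible.

`mirmint` implements the complete analysis chain for this setting:

1. **Detection filter** — keep miRNAs detected in at least a fraction
   (default 10%) of samples, using `ceiling(fraction * n)` so exactly the
   boundary count passes.
2. **Sparse PLS-DA** (`fit_splsda`, `tune_splsda`) on each layer —
   supervised latent components whose weight vectors are constrained to
   `keepX` non-zero loadings, tuned by stratified cross-validated
   misclassification under max-distance prediction.
3. **Random-variance t-test** (`random_variance_ttest`) — moderated
   differential expression with BH FDR (default 0.15), a fold-change
   filter (|log2 FC| > 1, strict), and a global label-permutation test.
4. **Trait GSEA** (`gsea_phenotype_permutation`) — gene sets ranked by
   Pearson correlation of each gene with a *continuous* trait (an sPLS-DA
   component score), scored by the weighted running-sum statistic, with a
   phenotype-permutation null, NES, FDR (kept at < 0.05) and a
   bubble-plot z-score per set.
5. **Regularized CCA** (`fit_rcca`, `tune_rcca`) of the two selected
   submatrices — within-block covariances ridged as `Cov + lambda I`;
   dimension count chosen before the largest gap in the canonical
   correlation profile; features projected on the first two compromise
   variates (correlation circle, inner radius 0.3) and bi-clustered into
   a CIM similarity matrix (Euclidean distance, average linkage).
6. **Integrated network** (`build_integrated_network`) — Pearson
   anticorrelation of every retained miRNA-gene pair (one-sided negative
   test, BH over all pairs, q < 0.1) intersected with the 2-of-3
   consensus of three target-prediction databases; hub statistics on the
   result.
7. **stSVM** (`run_stsvm`) — per-feature |t| statistics smoothed over the
   network with the random-walk kernel `K = (aI - L)^p` (normalized
   Laplacian `L`), feature selection by label permutation, and a linear
   SVM evaluated by 10x10 repeated stratified cross-validation with a
   rank-statistic AUC.

`run_pipeline()` wires these stages together from a single seeded
configuration and writes a reproducible report bundle.

# The model assumptions, stage by stage

**sPLS-DA.** The class factor is coded as a centered two-column dummy
matrix. Each component solves a power iteration on the deflated
cross-covariance; sparsity is imposed by hard truncation of the weight
vector to its `keepX` largest-magnitude entries (renormalized each
iteration, tolerance 1e-6, at most 500 iterations). Truncation ties are
broken by feature index and the weight sign is fixed so the largest
loading is positive — fits are exactly reproducible. Deflation is
regression-mode (X and Y regressed on the score), which makes successive
scores orthogonal and explained-variance fractions additive. Features
are centered and unit-variance scaled internally; although log2
intensities share a scale, variance scaling is the convention of the
discriminant method this reproduces. The cross-validated error is the
*overall* misclassification rate (a single number, as reported in the
kind of analysis this mirrors), which with a 14/26 class imbalance
weights the majority class more; interpret accordingly.

**Random-variance t-test.** Each feature's pooled variance is shrunk
toward an inverse-gamma prior fitted across all features:
`s2_mod = (nu s2 + 2a/b) / (nu + 2a)` with `df = nu + 2a`. The prior is
fitted by method of moments on log pooled variances (trigamma inversion;
closed form in `?random_variance_ttest`); if the observed spread of
log-variances does not exceed what the chi-square sampling noise alone
explains, the prior weight is set to zero and the statistic reduces
exactly to the pooled two-sample t. The global permutation test reports
`(1 + #{permutations with >= as many significant features}) /
(n_perm + 1)` — the add-one convention avoids zero p-values. Because its
statistic is a discrete count that is usually zero under the null, this
p-value is *valid but conservative* (mass at 1), not uniform; the test
suite asserts super-uniformity rather than exact uniformity.

**Trait GSEA.** The default weight exponent is 1 (the standard weighted
statistic). The permutation scheme permutes the continuous trait across
samples — a phenotype permutation, preserving the gene-gene correlation
structure — rather than permuting gene labels. Running-sum ties between
an equal positive and negative extremum (possible with weight 0) resolve
deterministically to the positive one. Set sizes are bounded to
[10, 500] after intersecting with the expression matrix.

**rCCA.** Solved through the symmetric generalized-eigenvalue form with
`(Cov + lambda I)` inverses; reported canonical correlations are the
correlations of the paired unit-variance variates (at `lambda = 0` these
equal classical CCA). Penalty tuning maximizes the mean held-out
correlation of the *first* variate pair — the cheapest faithful CV score;
the full grid of the original analysis (100 x 100 over
(0.001, 0.05) x (0.0001, 0.05)) remains the function default, while the
pipeline configuration uses a coarser 8 x 8 grid by default. Circle
coordinates correlate each feature with the *compromise* variate (mean
of the x- and z-variates per dimension), since either block's variate
alone would favor its own features; only dimensions 1-2 are used for the
circle and CIM, mirroring the restriction to the first two variates in
this kind of analysis.

**Integrated network.** The one-sided (negative tail) correlation test
encodes the repression hypothesis; a two-sided variant is available via
`alternative`. BH is applied over *all* tested pairs, not per miRNA (a
choice the source analysis leaves open; per-miRNA correction would be
less conservative for high-degree miRNAs). The top-75% variance filter
is ranked on the full gene matrix and then intersected with the
rCCA-retained genes: re-ranking variance inside the already-enriched
retained subset would systematically discard low-variance true targets.

**stSVM.** Kernel defaults `a = 2`, `steps = 2` (the convention of the
smoothing method; `a >= 2` is required because normalized-Laplacian
eigenvalues reach 2, so smaller offsets lose positive semidefiniteness).
The node statistic is the random-variance |t| computed on the combined
miRNA+gene matrix so both blocks share one scale. The permutation test
compares *raw* smoothed scores between observed and permuted labels;
the unit-maximum rescale of `smooth_statistics` is applied only to
reported scores, because rescaling inside the null would cancel exactly
the overall signal strength the test must detect. By default feature
selection is *not* redone inside the CV folds — this mirrors the
evaluation wiring of the analysis being reproduced and is optimistic;
`nested_selection = TRUE` gives the honest estimate. The SVM uses fixed
cost 1 and class weights inversely proportional to class sizes.

# The synthetic cohort generator

`generate_cohort()` defines the study conditions every test runs under:
40 samples in two unbalanced classes (14 "long" vs 26 "short"), 614
miRNAs, 2,000 genes (a desk-scale stand-in for the ~17,000 of a full
array), Gaussian log2 intensities with U(6, 12) baselines and unit
within-class noise.

* **Component 1** — 10 miRNAs shifted up in the "short" class by
  `effect_size` (default 2) within-class standard deviations: strong
  univariate discriminators.
* **Component 2** — 10 miRNAs in 5 pairs sharing a latent N(0, 20^2)
  factor; "short" samples are shifted by +/- `effect_size` along the
  within-pair contrast. Each miRNA's marginal two-sample t is swamped by
  the shared factor (approximately null), while a linear discriminant on
  a pair separates the classes — the multivariate-but-not-univariate
  structure that distinguishes discriminant from differential analysis.
* **Signature** — 3 of the component-1 miRNAs jointly repress 5 genes
  (`gene = baseline - slope * mean(miRNAs) + N(0, noise_sd)`, defaults
  slope 1, noise 0.5). Every miRNA x gene pair is a true edge (15
  edges): the co-targeting hub topology that miRNA-target networks
  typically show, and the structure the consensus filter needs so that a
  node does not vanish whenever one database misses one edge.
* **Pathways** — one 40-gene block per component, driven negatively by
  the component's summary score, forming a truly enriched gene set per
  component, plus 8 size-matched random null sets.
* **Databases** — three edge lists containing each true edge with
  sensitivity 0.8 and each random non-edge with false-positive rate
  0.02, so a true edge reaches 2-of-3 consensus with probability
  `3 * 0.8^2 * 0.2 + 0.8^3 = 0.896`.
* **Detection** — expressed miRNAs are flagged detected per cell with
  probability 0.95 (planted miRNAs always); 2% of background miRNAs are
  rarely detected (rate 0.05) so the 10% filter has work to do.

What the generator deliberately does **not** emulate: probe-level array
noise, batch effects, FFPE degradation, heavy-tailed intensities,
correlated background genes, and miRNAs that repress via translation
only (invisible to anticorrelation). Passing tests therefore show that
the chain recovers planted linear-Gaussian structure at realistic sizes
and noise — not that it is robust to every artifact of real arrays.

# Numerical choices and degenerate inputs

* Detection threshold: `count >= ceiling(fraction * n)`, so "at least
  10%" includes the boundary (4 of 40 passes).
* Fold-change filter: `q <= max_q` but strictly `|log2FC| > cut`.
* BH correction is `stats::p.adjust(method = "BH")`; tests pin it
  against a brute-force min-over-tail oracle.
* All permutation p-values use the add-one convention.
* sPLS-DA refuses constant features (naming them) and
  `ncomp > min(n - 1, p)`; prediction on data missing model features
  lists the missing ids.
* rCCA at `lambda = 0` refuses singular covariances and advises a
  positive penalty; dimension selection with all-equal correlation drops
  returns 1 with a "no clear gap" warning; a manual dimension override
  is honored and logged.
* Degree-zero nodes get a zero Laplacian row, so kernel smoothing leaves
  isolated features untouched (up to the global rescale).
* Tie rules are explicit everywhere randomness could creep in:
  truncation ties by feature index, variance-ranking ties by feature id,
  degree ties by node id, prediction ties to the first class,
  running-sum extremum ties to the positive side.
* One global seed drives everything; per-stage seeds are derived as
  `(seed * 1000 + stage_index) mod (2^31 - 1)`, so any stage can be
  reproduced in isolation.

# Problem sizes used by the test suite

Module tests run on compact cohorts (20 samples, 100 miRNAs, 300
genes). The end-to-end recovery checks use the full default design (40
samples, 614 miRNAs, 2,000 genes) over ten seeds with 300 permutations
for stSVM selection and 10x10 CV; calibration checks use 10,000 null
features/pairs. The pipeline's default configuration uses the coarse
tuning grids noted above; all paper-scale grids remain available through
the configuration.

# Known limitations

* The non-nested CV default inherits the selection bias of the wiring it
  reproduces; use `nested_selection = TRUE` for unbiased AUCs.
* The rCCA CV score only uses the first variate pair; signals living
  purely in later dimensions would not steer the penalty choice.
* GSEA FDR follows the NES-based procedure, whose q-values are known to
  be non-monotone in small set collections; they are capped at 1 but not
  monotonized.
* The anticorrelation test assumes approximately Gaussian log2
  intensities (it is a Pearson/t procedure); rank-based alternatives are
  not implemented.
* Feature identifiers are opaque strings: mapping miRNA/gene namespaces
  across databases is the caller's responsibility.

# A minimal run

```{r example, eval = FALSE}
cfg <- default_config(seed = 1)
cfg$output_dir <- "mirmint_report"
report <- run_pipeline(cfg)
print(report)
report$signature$selected
```
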