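---
title: "Linear modeling of single-cell proteomics data with scplm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linear modeling of single-cell proteomics data with scplm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scplm)
library(dplyr)
```

## The problem

Mass-spectrometry single-cell proteomics (SCP) quantifies thousands of
peptides across hundreds to thousands of single cells. Two features of
these data dominate their analysis: strong technical structure (MS
acquisition runs, label channels, per-cell loading differences) and a
high proportion of missing values whose pattern is itself shaped by the
batch structure — a peptide can be absent from an entire acquisition run.
The common response, imputing missing values and chaining normalization
and batch-correction steps before analysis, introduces bias, discards
estimation uncertainty, and can make inestimable comparisons look
estimable.

`scplm` takes the opposite route: minimal processing, then a linear model
per peptide that uses only the observed measurements and adapts its
parameter set to each peptide's missingness pattern. Everything
downstream — variance decomposition, differential abundance, component
analysis, batch-corrected reconstruction — is read off the fitted model.

## Minimal processing

Four steps, in a fixed order, and nothing else:

1. **Feature quality control** (`filter_features()`): drop decoy and
   contaminant PSMs, and PSMs with low sample-to-carrier ratio, low
   spectral purity or high identification FDR. All thresholds are
   fractions in [0, 1] and each rule is optional.
2. **Cell quality control** (`filter_cells()`): drop cells with too few
   quantified peptides, a median log2 intensity outside a plausible
   window (for SCoPE-style TMT data a window like (6, 8)), or a median
   within-protein coefficient of variation above a threshold (e.g. 60%).
   The CV of a protein in a cell is computed on relative intensities —
   each peptide divided by its own mean across cells — with the sample
   standard deviation, over proteins with at least 3 observed peptides
   (configurable); the cell's value is the median over proteins. The CV
   literature leaves details open; these choices are recorded here
   because they affect which cells survive.
3. **Aggregation** (`aggregate_to_peptides()`): PSM/precursor rows
   collapse to peptides by the median of observed child intensities per
   cell. Peptides mapping to several proteins error by default
   (configurable to `drop` or `keep_first`), because silently picking a
   protein would bias protein-level summaries.
4. **Log transform** (`log_transform()`): base 2 by default, so model
   coefficients read directly as log2 fold changes and the median-log QC
   window above matches the usual scale of these data.

Normalization, imputation and batch correction are deliberately *not*
processing steps. Zeros are converted to missing values at ingestion:
a zero in these data means "not measured", not "absent", and letting
zeros survive into a log transform would manufacture infinities.

## The model

For peptide $j$, let $O_j$ be the set of cells where it is observed. The
model is

$$ Y_{O_j j} = X_{O_j S_j}\,\beta_{S_j j} + \varepsilon_{O_j j},
   \qquad \varepsilon \sim N(0, \sigma_j^2) $$

where $X$ is built from the cell descriptors: an imposed intercept,
centered numeric covariates, and sum-to-zero contrasts for categorical
descriptors (a descriptor with $a$ levels contributes $a-1$ columns;
levels are ordered lexicographically and the last level is $-1$
everywhere). Sum coding makes the intercept the peptide's baseline
intensity and makes group effects symmetric around it.

$S_j$ is the per-peptide retained parameter set: parameters whose design
column is not constant on $O_j$, plus the intercept, **minus** columns
that are jointly collinear on $O_j$. The last pruning step goes beyond
the plain "not constant" rule and matters in practice: a peptide observed
in two of three runs has two individually varying run indicators that sum
to the intercept; without pruning, the penalized solver resolves the
collinearity minimum-norm and silently moves half of the baseline into
the run effect, which then corrupts the batch-corrected reconstruction.
Pruning keeps the earliest columns (QR with pivoting), is deterministic,
and makes every retained parameter identifiable.

Coefficients are estimated per peptide by ridge-penalized least squares,

$$ \hat\beta = (X^\top X + \lambda I)^{-1} X^\top y, \qquad
   \lambda = 10^{-3} \text{ by default,} $$

where $\lambda$ is a numerical stabilizer for peptides whose $n/p$ ratio
(observations over retained parameters) is close to 1, not a shrinkage
device. Consistently with that reading, the residual degrees of freedom
are the OLS count $\nu = |O_j| - |S_j|$, without a ridge effective-df
correction. Peptides with $n/p \le 1$ can never be fitted and are always
skipped; the threshold is configurable upwards (e.g. 3) for stricter
filtering. This replaces arbitrary "maximum missingness" cut-offs with a
criterion tied to estimability.

Numeric covariates are centered once, on the mean over *all* cells, and
are not re-centered per peptide: this keeps the intercept's meaning
("baseline intensity of the peptide") comparable across peptides with
different observation patterns. The per-cell normalization factor — the
median of a cell's observed log2 intensities — can be requested as the
descriptor `median_intensity` and is computed on demand.

## Exploring the fit

**Analysis of variance** (`variance_analysis()`): for each variable $f$
with retained parameters $K_f$, $SSR^{(f)} = \lVert X_{O_j K_f}
\hat\beta_{K_f}\rVert^2$, and the share of variance is
$100\,SSR^{(f)} / (SSE + \sum_l SSR^{(l)})$. The intercept is a baseline,
not a variance source, and is excluded; dropped variables are reported
with share 0 so tables stay rectangular. `global_variance()` and
`protein_variance()` average the *percentages* (not the sums of squares)
across peptides, so every level of aggregation sums to 100.

**Differential abundance** (`build_contrast()`, `test_contrasts()`):
group differences are contrast rows $L$ on the sum-contrast encoding; the
statistic $T = L\hat\beta / \sqrt{L \hat\Sigma L^\top}$ uses the ridge
variance-covariance
$\hat\Sigma = (X^\top X + \lambda I)^{-1} X^\top X (X^\top X + \lambda
I)^{-1}\hat\sigma_j^2$ and is referred to $t_\nu$, two-sided. A contrast
that needs a parameter outside $S_j$ (peptide observed in only one of the
compared groups) is reported as non-estimable rather than dropped — the
information that a comparison *cannot* be made is part of the result.

Multiple testing (`adjust_pvalues()`) offers plain Benjamini-Hochberg and
a binned variant of independent hypothesis weighting: peptides are
stratified into quantile bins of their baseline (intercept) intensity,
and per-bin weights with mean 1 are learned on one data fold by
maximizing weighted-BH discoveries at the target level, then applied to
the other fold (2 folds, deterministic given the seed argument). The
rationale is that high-baseline peptides are less noisy and should spend
less of the error budget. This is a deliberate simplification of the
full convex-optimization IHW procedure; with fewer than `10 * n_bins`
tests it falls back to BH, and BH is always available for exact
reproducibility.

Protein-level results (`combine_to_protein()`) combine peptide p-values
by Fisher, Simes, Berger, Pearson, Holm-minimum, Stouffer or Wilkinson
(order 1). The protein log fold change is the estimate of the
*representative* peptide — the maximum-p peptide for Berger's
intersection-union test, the minimum-p peptide otherwise, with ties
broken by larger absolute estimate and then lexicographic id.

**Component analysis** (`apca()`): APCA+ decomposes, for a chosen
variable, the effect matrix plus the residuals, so that cellular
heterogeneity around that effect stays visible. Features are centered on
their observed entries (no unit-variance scaling — the data are already
on a common log scale); cells are score space, peptides are loading
space. `"unmodelled"` gives the pre-modeling view of the processed data,
`"residual"` hunts for structure the model missed. Protein-level
loadings are per-component medians over each protein's peptides — a
pragmatic aggregation that sacrifices orthogonality, stated in the
output's documentation.

**Missing-value PCA.** `nipals()` extracts components one at a time by
alternating regressions on the observed entries, with deflation — the
classic NIPALS scheme, which needs no imputation. Sequential extraction,
however, is not the optimal joint rank-$k$ fit when entries are missing:
on a rank-3 matrix with 20% of entries missing it leaves percent-level
reconstruction error — a property of the algorithm, not of the
implementation (the test suite demonstrates it on the unrefined path).
By default the sequential solution therefore seeds a joint
alternating-least-squares refinement over all $k$ components on the
observed entries, after which the factors are re-orthogonalized into
scores, unit-norm loadings and non-increasing eigenvalues. On complete
data the refinement converges to the truncated SVD (it merely polishes
the sequential solution); `refine_iter = 0` restores the textbook
behavior. Signs are fixed by
making each loading's largest-magnitude element positive, so outputs are
bit-reproducible.

**Batch correction** (`batch_corrected()`): the reconstruction keeps the
intercept, the effects you name (typically the biological ones), and the
residuals; technical effect matrices are dropped; the missingness
pattern is preserved. Keeping everything reproduces the observed data
exactly — a useful invariant that the tests assert.

## The simulator

`simulate_scp()` generates log2 peptide-by-cell data under exactly the
additive model the package fits: per-peptide baseline
$\sim N(8, 1.5^2)$ (median log2 intensities inside the usual QC window),
per-cell size factor $\sim N(0, 0.3^2)$, and per-peptide run, label and
cell-type effects drawn centered Gaussian per family and re-centered to
sum to zero across levels, so the truth aligns exactly with the
sum-contrast encoding and "true log fold change" is well-defined.
Default scales — run 1.0, label 0.3, cell type 0.5, residual 0.5 (log2
units) — emulate a batch-dominated multiplexed experiment in which
technical descriptors explain most of the variance and the biological
signal is modest. Missingness is MCAR (default rate 0.2) plus structural
run dropout (default 0.05 probability that a peptide is absent from a
whole run), the pattern that forces per-peptide model adaptation.
Intensity-dependent (MNAR) missingness is deliberately not simulated:
the modeling approach assumes MCAR, and the simulator probes exactly the
assumptions under which the method claims validity. Cells are assigned
to runs in contiguous blocks (as acquired), labels cycle within runs,
and cell types are randomized.

What passing tests on these data do show: correct recovery of
coefficients that are expressible in the design, calibrated t-based
inference under MCAR + run dropout, and effective removal of additive
run structure. What they do not show: robustness to MNAR missingness,
non-additive label-by-run interactions, or misspecified descriptors —
all named limitations of the linear approach.

`evaluate_recovery()` closes the loop: bias, RMSE and t-interval
coverage of the fitted coefficients against the generator's truth, per
effect family.

## Benchmarking batch correction

`benchmark_correction()` scores any corrected matrix by the protocol:
NIPALS PCA (20 PCs by default), k-means on the scores (seeded, 10
restarts, best inertia), then ARI, NMI and purity of the clustering
against the biological labels (separation; higher is better) and against
the technical labels, reported as $1 -$ metric (mixing; higher is
better). The average silhouette width is computed on the PC scores
directly with the known labels, Euclidean distance, singleton clusters
contributing 0. NMI uses the arithmetic-mean normalization of the two
entropies (recorded in the report's metadata, since several conventions
exist). ARI/NMI/purity/ASW are implemented in the package and
cross-checked in the tests against brute-force pair counting and against
`mclust` / `cluster`.

## Worked example

```{r example}
sim <- simulate_scp(
  n_cells = 150, n_peptides = 200, n_proteins = 50,
  n_runs = 4, n_cell_types = 3, run_scale = 2, seed = 42
)
ds <- sim$dataset

fit <- fit_model(ds, model_spec(
  size_factor = "normalization", run = "technical",
  label = "technical", cell_type = "biological"
))
glance(fit)

global_variance(variance_analysis(fit))

inf <- test_contrasts(
  fit, build_contrast(fit$design, "cell_type", "type1", "type2")
) |>
  adjust_pvalues(method = "bh")
summarise(inf,
  n = dplyr::n(), estimable = sum(estimable),
  significant = sum(adj_p_value <= 0.05, na.rm = TRUE)
)

corrected <- batch_corrected(fit, keep = "cell_type")
benchmark_correction(
  corrected, ds$cells$cell_type, ds$cells$run,
  n_pcs = 20, k = 3, seed = 1
)$metrics
```

The same analysis runs end to end from one configuration via
`run_pipeline()` (or the `inst/cli/scplm.R` wrapper), which writes every
result table plus a `manifest.json` that suffices to re-execute the
identical analysis.

## Numerical choices and problem sizes

- Constant-column detection uses an absolute variance threshold of
  1e-12; design rank is decided by QR with R's default tolerance.
- NIPALS: convergence at loading-change < 1e-9, at most 500 iterations
  per component, at most 100 refinement sweeps; initialization from the
  column with the largest observed variance (deterministic).
- The ridge solve uses the Cholesky-backed `solve()` on
  $X^\top X + \lambda I$; a numerically singular system records the
  peptide as skipped rather than failing the run.
- Degenerate inputs: an all-zero peptide yields zero coefficients, zero
  SSE, and a variance table that attributes 100% to the residual;
  a peptide observed once retains only the intercept and is skipped by
  the $n/p$ rule.
- The package's own validation (tests and the acceptance script) runs on
  simulated data sets of 100-200 cells and 40-2000 peptides, with 50
  replicates for coverage checks — sizes chosen so the whole suite
  completes in about a minute while keeping Monte-Carlo error well below
  the tolerances asserted.

## Known limitations

- Sources of variation must be independent; hierarchical designs
  (cells within patients) would need a mixed model, which this package
  does not provide.
- No interaction terms (e.g. label-by-run): they would overspecify the
  model at these sample sizes, and residual label-within-run structure
  can therefore survive correction.
- MNAR missingness is neither modeled nor simulated.
- Protein-level loadings and p-value combination are conveniences on top
  of peptide-level modeling, not joint protein-level inference.
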