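---
title: "Deconvolving single-molecule chromatin conformation ensembles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deconvolving single-molecule chromatin conformation ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromafactor)
```

## The problem

Chromatin tracing and single-cell Hi-C measure genome folding one molecule
at a time: for each cell we observe the 3D positions of `b` consecutive
genomic loci, summarized as a `b x b` pairwise distance matrix. Aggregating
thousands of cells recovers the familiar bulk contact map, but the
individual maps are extremely heterogeneous, and a trend visible in the
population median — a domain boundary, an enhancer–promoter contact — may be
carried by all cells weakly or by a small subpopulation strongly. This
package decomposes a stack of per-cell maps into a small set of recurring
structural *templates* and per-cell *weights*, then uses the weights to ask
which cells drive which trends and how they relate to matched transcription
readouts.

## Model

Let $X_i \in \mathbb{R}^{b \times b}_{\ge 0}$ be the (max-normalized)
distance map of cell $i$, flattened into a column of
$V \in \mathbb{R}^{b^2 \times n}$. Non-negative matrix factorization finds
$W \in \mathbb{R}^{b^2 \times k}_{\ge 0}$ and
$H \in \mathbb{R}^{k \times n}_{\ge 0}$ minimizing
$\tfrac12\lVert V - WH \rVert_F^2$, so that each cell is an additive
mixture of $k$ templates plus noise:
$X_i \approx \sum_k W_k H_{ki}$. Columns of $W$, reshaped to `b x b`, are
the templates; column $i$ of $H$ gives their weights in cell $i$, and
$\sum_k W_k H_{ki}$ is a denoised reconstruction of that cell.

### Solver

`fit_decomposition()` uses a deterministic NNDSVD initialization (the
"a" variant: zeros are filled with the data mean so no entry is frozen at
zero) followed by HALS coordinate descent, sweeping the columns of `W` and
rows of `H` in a fixed order. Defaults: tolerance `1e-4` on the relative
error change (checked every 10 iterations), at most 200 iterations, no
ridge penalty (`l2 = 0`; the penalty is exposed but a default strength of
zero is the only defensible choice absent a stated value). Because both
the initialization and the sweep order are deterministic, two fits of the
same data are bit-identical — important because every downstream file is
hashed for reproducibility.

Flattened NMF knows nothing about matrix symmetry, so fitted templates can
be (minutely) asymmetric even on symmetric data. Templates are symmetrized
as $(W_k + W_k^\top)/2$ after fitting and the relative discrepancy is
recorded in `asymmetry_norm`; on symmetric input it is at numerical-noise
level, and all track computations downstream assume symmetric maps.

`k = 20` is the conventional default for a single locus; the selection
framework below proposes a data-driven value.

## Choosing the number of components

`evaluate_k_grid()` scores each candidate `k` on five axes: Frobenius
reconstruction error; *stability* (mean correlation of matched components
across random restarts — matching by Hungarian assignment on template
correlations); *redundancy* (mean absolute pairwise template correlation);
variance explained; and computational cost. With matched transcription
labels a sixth axis — 5-fold cross-validated balanced random-forest
accuracy predicting the labels from `H` — measures biological signal.
`propose_k()` min–max normalizes each metric over the grid (orienting all
of them higher-is-better, constants contributing 0.5), averages them
unweighted, and proposes the arg-max, breaking ties toward the smaller
(more interpretable) model.

Two numerical choices matter here:

* **Deterministic cost proxy.** Wall-clock fit time is recorded in the
  report, but on a desk-scale grid its variation is scheduler noise, and
  min–max normalization would amplify that noise into a randomly-oriented
  vote. The efficiency axis therefore scores `fit_cost = k x iterations`,
  which captures the real per-iteration FLOP scaling and makes the proposal
  a pure function of data and seed.
* **Warm-started capacity curve.** Reconstruction error and variance
  explained should be monotone in `k`, but independently initialized fits
  stopped at a finite tolerance can cross by a few parts per million.
  Successive grid fits are therefore warm-started from the previous
  optimum with the added components initialized to contribute exactly
  nothing; since HALS descends monotonically, the `k+1` fit can never end
  worse than the `k` fit and the curve is non-decreasing by construction.

Stability deliberately uses random (not NNDSVD) initializations: restarts
from the same deterministic initialization would trivially report 1.

## Preprocessing

`read_coordinate_table()` ingests a TSV of per-cell, per-locus 3D
coordinates (nm) with optional per-gene binary transcription labels.
The QC and normalization chain mirrors standard imaging practice:

* **Missingness filter** — cells with *strictly more* than the threshold
  fraction of undetected loci are dropped (typical thresholds: 0.8 for a
  short locus, 0.25 for a multi-Mb one). Boundary-equal cells are
  retained.
* **Linear imputation** — each coordinate axis is interpolated linearly
  along the locus index between the nearest observed flanking loci;
  leading/trailing runs are filled with the nearest observed value
  (constant extrapolation — interpolation proper is undefined there).
  Observed coordinates are never modified.
* **Distances and normalization** — all-by-all Euclidean distances per
  cell, then division by the maximum distance. Both per-cell and global
  maxima are meaningful readings of "the maximum observed"; the package
  implements both and records the mode on the tensor. The default is
  per-cell, which puts every map on `[0, 1]` and makes the 0.05
  insulation threshold scale-free.

Bins and cells are 1-based throughout, following R convention.

## Linking structure to transcription

Two complementary routes:

* **Nonparametric testing.** Position-wise: a two-sided Mann–Whitney U
  test at every matrix position comparing transcribing vs non-transcribing
  cells, Benjamini–Hochberg corrected over all positions, significance at
  FDR < 0.05. Component-wise: the same test on each row of `H`, corrected
  over the `k` components, significance at FDR < 0.1. The U statistic uses
  midranks; p-values are exact (by enumeration) when both groups have at
  most 8 observations without ties, and otherwise use the normal
  approximation with tie and continuity corrections — toy examples stay
  exact while dataset-scale scans stay fast. Cells imaged in the same
  sample are not strictly independent; no clustering correction is
  applied, and results should be read with that caveat.
* **Balanced classification.** A random forest (100 trees, Gini impurity,
  `sqrt(d)` features per split) predicts transcription from the component
  weights after the majority class is downsampled to balance — chance is
  then exactly 0.5 and any excess accuracy is structural signal, which is
  the point of the analysis (identifying *which* templates matter, via
  impurity importances, rather than maximizing accuracy). A label
  permutation test (class proportions preserved, p =
  (#{null ≥ observed}+1)/(n_perm+1)) guards against optimistic splits.

## Template tracks and boundaries

For a template (or median map) `M`:

* **Insulation** — `insulation_profile()` averages the cross-block
  `window x window` rectangle touching each bin (truncated at the edges;
  the last bin is undefined). On *distance* maps a boundary separates two
  compact domains by long cross-domain distances, so boundaries are local
  **maxima**; `call_boundaries()` keeps interior strict maxima above 0.05
  (plateaus yield their leftmost bin). The profile is computed directly on
  the normalized-distance template, where the 0.05 threshold is
  scale-free.
* **Directionality index** — the classic signed chi-square statistic of
  upstream/downstream interaction bias. Its normalization divides by
  expected *contacts*, so normalized distance maps are first transformed
  to similarity `s = 1 - m`; windows truncate at the edges and `DI = 0`
  when the two sides balance exactly.
* **Peak colocalization** — called boundaries are matched against
  BED-derived protein peak tracks (strongest peak per protein per bin)
  within a bin tolerance, reporting per-protein counts and per-boundary
  co-binding combinations.

`embed_weights()` projects the columns of `H` to 2D with UMAP
(`n_neighbors = 5`, all else default, seeded and single-threaded so runs
reproduce); the backend and version are recorded on the result.

## Subpopulation extraction

Given the significant component set, `assign_contribution_groups()` scores
each cell (by default the mean weight over the selected components; an
`any_component` mode — top fraction in at least one component — is provided
for sensitivity analysis, since aggregating over several components is a
genuinely open choice) and selects the transcribing cells in the top
`q` fraction ("high contribution") and the non-transcribing cells in the
bottom `q` fraction ("low"), `ceiling(q * n_class)` per class up to ties;
cells exactly at the cut are included. Contrasts between the groups —
median maps, their difference, anchor–target (promoter–enhancer) mean
distances — quantify how much of the bulk trend the subpopulation carries.

## The synthetic generator

Every stage is validated against ground-truthed synthetic ensembles built
by `simulate_dataset()`: `b x b` non-negative symmetric maps composed as
additive mixtures of planted templates plus truncated-at-zero Gaussian
noise (re-symmetrized, zero diagonal), whole-locus dropout, and binary
labels coupled to chosen component weights through a logistic model whose
intercept is calibrated by root finding to prevalence 0.5 (matching the
balanced designs downstream).

Defaults and their rationale:

* **Motif library** — two-block boundary, stripe, and compartment
  checkerboard: the three structures real templates exhibit. Values are on
  the normalized-distance scale (background 0.1, elevated 0.9). Motifs
  correlated at ≥ 0.8 are rejected so the planted basis is well separated.
* **`weight_sparsity = 0.7`** — each cell activates ~70% of the planted
  components (stochastic rounding of `k * 0.7`, at least one). This is an
  identifiability condition, not a convenience: with every component
  active in every cell the additive mixture is not unique (background can
  be redistributed among templates without changing `WH`), and
  template-recovery validation would be ill-posed. It also mirrors real
  populations, where single cells resemble one or a few templates.
* **`noise_sd = 0.05`**, `dropout_frac = 0` — set for testability: 5% of
  the normalized distance range is enough to be non-trivial while leaving
  planted structure recoverable. No quantitative noise/dropout
  characterization of the real imaging data is available to emulate.
* **Dropout acts on whole loci** (row and column), as a missed probe does.
* **Coordinates** come from classical MDS of each map, exercising the
  full coordinate-table input path end to end.

What the generator does *not* emulate: polymer physics, microscopy point
spread and localization error, locus-dependent detection efficiency,
spatially correlated dropout. Passing tests demonstrate correctness of the
computations under the additive-mixture model, not robustness to every
artifact of real imaging data; in particular, consistently co-missing loci
in real data can produce templates that capture dropout structure.

## Problem sizes and numerical conventions

The validation suite runs at `b = 32`, `n = 500`, three planted templates
(grid `k = 2..8`, four random restarts for stability), with smaller
`b = 12..16` fixtures for the pipeline and unit tests — sizes chosen so the
whole suite completes in a few minutes on one core while leaving the
planted-structure recovery non-trivial. Other conventions: strict QC
inequality at the threshold; smallest-index tie-breaks (dominant
components, proposed `k`, boundary plateaus); `-1` sentinel for all-zero
weight columns in dominant-component labeling; floats persisted with 17
significant digits so model and tensor round trips are bit-identical;
SHA-256 stage hashing in the pipeline with wall-clock timings kept out of
the hashed outputs.

## Limitations

Templates are descriptive: a significant structure–transcription
association does not establish mechanism or direction, and snapshots of a
dynamic polymer cannot resolve temporal ordering. NMF solutions, while
deterministic here, are local optima; the stability metric is the guard
against over-reading any single factorization. The 0.05 insulation
threshold and window sizes are heuristics whose sensible range should be
explored per dataset.
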