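---
title: "Sub-region radiomics for binary tumour grading: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sub-region radiomics for binary tumour grading: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(subgrade)
```

## The problem

Clear cell renal cell carcinoma is graded on a four-tier nucleolar scale
that clinicians binarise into low (grades 1–2) and high (grades 3–4)
because management differs mainly across that boundary. The grade is
normally confirmed only after surgery; pre-operative biopsies sample a
small part of a spatially heterogeneous tumour and are often indeterminate.
`subgrade` implements a non-invasive alternative: quantitative texture
descriptors (radiomics) computed from contrast-enhanced CT, not on the
whole tumour only but on concentric **sub-regions** — volume-fraction cores
and hollow-rim peripheries — so the analysis can ask *where in the tumour*
the grade signal lives.

The package covers the full chain: synthetic CT phantoms and cohort tables,
mask decomposition, a standardised radiomics battery, leakage-safe feature
processing, an eleven-classifier model grid with internal and external
validation, and a diagnostic-comparison metrics suite (including the
paired comparison of biopsy grading against model predictions with
nephrectomy histopathology as the reference standard).

## Sub-region decomposition

A tumour is a 3D binary voxel mask with anisotropic spacing. Depth is the
exact Euclidean distance from each foreground voxel to the nearest
background voxel, computed by a separable lower-envelope distance
transform that honours the per-axis spacing (`boundary_distance()`).

The **core at fraction p** is the `round(p * |mask|)` deepest voxels —
i.e. p of the tumour *volume* taken from the centre outwards. "Percent of
the mask" is interpreted as a volume fraction rather than a fraction of
linear extent: it makes cores and peripheries exact set complements
(`periphery(p) = mask \ core(1 - p)`), gives the nesting
`core(0.25) ⊆ core(0.50) ⊆ core(0.75)`, and matches the intuition that a
"50% core" holds half the tumour. Ties at the cut depth are admitted in
lexicographic (z, y, x) order until the target count is met, so the
decomposition is deterministic across platforms. Masks with several
connected components are processed globally (the core may then fall in the
largest component only); this is flagged, not hidden. The seven analysis
regions per tumour are the full mask, cores at 25/50/75% and peripheries
at 25/50/75%.

## The radiomics battery

Features follow the standardised definitions used by the major extractors:

* **Discretisation**: fixed bin width of 20 HU anchored at the region
  minimum, so adding a constant to all intensities never changes texture
  features. No resampling, no outlier trimming, no extractor-side
  normalisation; a 5-voxel pad is honoured when a working sub-volume is
  cropped around the region.
* **Classes**: 19 first-order statistics, 24 GLCM, 16 GLRLM, 16 GLSZM,
  14 GLDM and 5 NGTDM texture features, plus 16 mesh/PCA shape features —
  110 per region. GLCM and GLRLM are computed per direction over the 13
  unique distance-1 3D offsets and averaged; GLSZM zones use
  26-connectivity; GLDM uses distance 1 and dependence tolerance 0 with
  dependence size defined as the number of dependent neighbours plus one;
  NGTDM uses the 26-neighbourhood.
* **Filter images**: square, square-root, logarithm and exponential
  intensity maps (with the conventional rescaling), gradient magnitude,
  Laplacian-of-Gaussian at sigmas of 1/2/3 mm, and a single-level
  stationary coiflet-1 wavelet decomposition into 8 sub-bands. Each
  enabled filter adds the 94 intensity/texture features recomputed on the
  filtered image; shape is computed once, from the mask alone. The default
  pipeline configuration runs the original battery only; the full filter
  bank multiplies compute roughly seventeen-fold and, on the synthetic
  phantoms, adds redundant copies of the same signal.
* **Degenerate cases** return mathematically defined limits rather than
  NaN: a constant region has variance 0, entropy 0, uniformity 1, GLCM
  contrast 0 and correlation 1; NGTDM coarseness is capped at 1e6.

Two shape choices deserve a note. Surface meshing uses marching
tetrahedra on the 0.5 iso-surface of the mask indicator **after smoothing
it with a 1-voxel Gaussian**: meshing the raw binary field overstates the
area of a digitised sphere by ~28% (staircase corrugation), while the
anti-aliased mesh reproduces analytic sphere areas within ~2% and
sphericity within 0.5%, at the cost of a ~4% under-estimate of mesh
volume (voxel-count volume is reported alongside). Maximum 3D and in-plane
2D diameters are exact maxima over voxel centres, computed after a
convex-hull prune (a voxel strictly between two same-line voxels can never
be a hull vertex).

## Leakage-safe processing and the classifier grid

All fitting operations accept the training partition only:

1. **z-scoring** with the training mean and population (n-denominator)
   standard deviation; a sample-sd switch exists because the convention is
   not universal. Constant features map to 0 and are flagged.
2. **Correlation filter**: greedy scan in canonical feature order; the
   later feature of any pair with |r| > 0.8 is dropped, so the surviving
   set is deterministic and all surviving pairs satisfy the threshold.
3. **Importance selection**: an XGBoost ranking model (gain importance,
   single thread, seeded); the top k = 30 features are kept by default.
4. **SMOTE** oversamples the training minority class to parity: each
   synthetic point is a uniform convex combination of a minority point and
   one of its k = 5 nearest minority neighbours.

The model zoo holds eleven classifiers with the published hyperparameter
table as defaults: rbf SVM (C 0.01, gamma 0.2), random forest (401 trees,
depth 3), XGBoost (401 rounds, eta 0.01, gamma 0.52), Gaussian naive
Bayes, a two-hidden-layer perceptron (401 and 201 relu units, adam, 5
epochs), an LSTM encoder with a trained logistic readout, logistic
regression capped at 4 IRLS iterations, regularised QDA (reg 0.05),
leaf-wise boosted trees (9 rounds, the LightGBM configuration), depth-wise
boosted trees (50 rounds, the CatBoost configuration) and discrete-SAMME
AdaBoost over weighted 401-tree forests (201 estimators, learning rate
0.01). Iteration caps that plainly under-train (LR, MLP) are honoured as
published; non-convergence is recorded on the fitted object, never fatal.
Every model exposes a score in [0, 1] and the label `1[score >= 0.5]`; for
the SVM the score is the sigmoid-calibrated decision value, which keeps
labels consistent with the SVM's own decision rule (Platt probabilities at
C = 0.01 sit arbitrarily close to 0.5). Boosted-tree slots run on the
xgboost backend; the perceptron, LSTM readout, QDA and AdaBoost are
implemented in the package.

`run_grid()` draws **one stratified 67/33 split per cohort** and reuses it
for every region and classifier of that cohort, refitting the processing
chain per region on training rows only; with 3 cohorts, 7 regions and 11
models this is the full 231-cell grid. `external_validate()` fits
everything on one cohort and only transforms and scores the other.
Summaries follow the study's conventions: the region average is the mean
test AUC over classifiers, and the classifier average is the mean of its
core-region average and periphery-region average.

## Evaluation

`diagnostic_metrics()` reports accuracy, sensitivity, specificity
(percentages with 95% Wald half-widths using metric-specific denominators
— all n for accuracy, positives for sensitivity, negatives for
specificity), AUC, MCC, F1, a McNemar p-value and a chi-squared
randomness p-value. The Wald rule and the **uncorrected** McNemar
statistic `(FN - FP)^2 / (FN + FP)` are the variants consistent with the
worked diagnostic-table examples the tests pin down. AUC is the
trapezoidal (rank-based) ROC area when scores exist and the balanced
accuracy `(SEN + SPE)/2` for label-only predictors such as biopsy. MCC
returns 0 (flagged) when a marginal factor vanishes. `biopsy_compare()`
maps an indeterminate biopsy to the opposite of the nephrectomy grade
before scoring, the conservative reading under which a non-contributory
biopsy always counts as an error.

Two chi-squared constructions are provided (2×2 independence, and
goodness-of-fit of predicted labels against 50/50) because the printed
chi-squared row of the reference diagnostic table is not reproducible from
the implied confusion matrices under either; that row is therefore not
asserted anywhere. The same applies to the printed sensitivity and AUC
half-widths, whose interval method is unstated.

## The phantom generator: what it emulates and what it does not

`generate_phantom()` builds an ellipsoidal tumour (semi-axes in mm,
anisotropic spacing, 5-voxel pad) in a uniform −50 HU background. The
intensity field is a Gaussian random field — white noise smoothed to a
stated correlation length, rescaled to a stated mean and sd — with one
triple for the inner core (the deepest half of the tumour volume by
default) and one for the outer shell, plus white acquisition noise
(sd 12 HU). Everything is a pure function of (configuration, seed), and
the mask never depends on the seed.

`generate_cohort()` adds the study-level structure: Bernoulli grade labels
at the configured prevalence (default 107/187), per-class truncated
normals for age and size matching the published per-class means and sds,
sex at the published per-class male fractions, and a tumour volume coupled
to size through an ellipsoid relation with lognormal scatter.

The default texture parameters encode a specific, deliberately structured
hypothesis — *the grade signal lives in the tumour core*:

* low-grade cores are N(45, 16) HU, high-grade cores N(63, 16) HU, with
  the same 3 mm correlation length — the class signal is a **core mean
  shift only**, so any region containing core voxels sees a linearly
  diluted effect;
* the shell mean sits at the class midpoint (54 HU) so that the
  core-shell intensity gap is symmetric across classes and mixture
  variance carries no class signal;
* shell means and sds vary widely between subjects (sd 15 and 4 HU,
  class-independent), emulating differences in vascularity and necrosis;
  this makes whole-tumour first-order features noisy;
* core means vary little between subjects (sd 2 HU), so core
  discrimination is limited by texture-sampling noise — which shrinks
  with region volume. This is the mechanism by which the 50% core
  (the full signal support) outperforms both the 25% core (same signal,
  half the voxels) and the 75% core or full mask (diluted signal plus
  shell noise);
* geometry (semi-axes 7–11 mm with ±15% anisotropy) is drawn
  independently of class, so shape features carry no signal.

Effect sizes were set by this signal-to-noise reasoning and checked on
desk-scale simulations before being frozen; the published study reports no
intensity distributions, so these are the package's own choices. What the
phantoms do **not** emulate: partial-volume blur at the tumour boundary,
contrast-enhancement gradients, scanner-specific artefacts, non-ellipsoidal
and infiltrative growth, and inter-scanner intensity shifts. Passing the
synthetic recovery experiment therefore shows the pipeline can localise a
sub-regional signal under controlled conditions; it does not certify
performance on clinical CT.

## Problem sizes and numerical choices

The test-suite experiments run at sizes chosen to exercise the full
pipeline comfortably on a single CPU: oracle comparisons on grids up to
24³ (distance transform) and 8³ (texture matrices, 50 random volumes); the
core-recovery experiment on 200-subject cohorts over 10 seeds; grid
cardinality on three 24-subject cohorts. The acceptance script repeats the
recovery experiment at the same sizes. Key numerical conventions:
population moments in first-order features and the z-scorer; banker's
rounding for core target counts (minimum 1 voxel); lexicographic
tie-breaks in the core cut; xgboost and ranger pinned to one thread with
explicit seeds; all stochastic stages seeded from a single master seed via
a deterministic sub-seed stream.

## Known limitations

* Feature values follow the standardised definitions but are not certified
  to be bit-identical to any specific extractor release; totals follow this
  package's own count formula (110 + 94 per filter image).
* The LSTM slot trains only its logistic readout over a seeded random
  recurrent encoding; it fills the eleventh grid cell deterministically
  and cheaply but is not a tuned sequence model.
* The LightGBM and CatBoost slots reproduce those models' published
  configurations on a single gradient-boosted-tree backend, not the
  original libraries' exact split-finding algorithms.
* Mesh volume is biased ~4% low by the anti-aliasing smooth; voxel-count
  volume is exact and reported alongside.
* The size-volume coupling reproduces the published size distributions
  exactly but the volume distribution only in order of magnitude; the
  printed volume means imply a stronger right skew than a lognormal
  scatter around an ellipsoid relation.

## A minimal run

```{r, eval = FALSE}
library(subgrade)
res <- run_end_to_end(run_config(n_per_cohort = 60, cohorts = c("A", "B"),
                                 seed = 42))
res$region_ranking      # regions ordered by mean test AUC per cohort
res$classifier_ranking  # classifiers by (core avg + periphery avg) / 2
```
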