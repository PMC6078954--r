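---
title: "Lesion-location-aware radiomics for glioma molecular subtyping: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lesion-location-aware radiomics for glioma molecular subtyping: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Lower-grade (WHO grade II/III) gliomas fall into three molecular
subtypes with very different prognosis and management: IDH-mutant
astrocytomas, IDH- and TERT-promoter co-mutated oligodendrogliomas, and
IDH-wildtype astrocytomas. Subtyping normally requires tissue. This
package implements a radiomics analysis that predicts the subtype from
conventional MRI (T1, T2, FLAIR, gadolinium-enhanced T1), with one
distinctive ingredient: *where* the lesion sits in the brain is encoded
as a numeric feature block — the occupancy ratio of the lesion over
labeled brain atlases — and fed into the model alongside texture and
shape.

Because no patient imaging is distributed with the package, every
stage is exercised on a seeded synthetic cohort generator
(`simulate_cohort()`) that reproduces the *statistical structure* the
analysis relies on, not the appearance of real MRI.

## Pipeline and models

### Gray-level normalization and derived channels

All channels are reduced to 256 gray levels (`normalize_channel()`).
T1, FLAIR and gadolinium T1 use the `clip999` rule: intensities above
the 99.9th percentile — predominantly high-signal noise — are capped at
that percentile (winsorized rather than removed, so the voxel grid
stays intact for downstream spatial operations), and the retained range
is mapped linearly onto 0..255 by `floor(255 (x - min)/(max - min))`
with the maximum at 255. T2 uses the full data range. The map is
monotone and invariant to positive affine rescaling of the input, which
is the point: it aligns intensity scales across scanners. The rounding
rule (floor, constant volume to 0) is a fixed numerical choice.

Two derived channels carry information the acquired channels encode
only implicitly:

* **T2Edge** (`prewitt_edge()`): the Euclidean norm of the three
  axis responses of a separable 3D Prewitt kernel on the normalized T2
  image, re-normalized to 0..255. The filter is applied in 3D —
  lesions are traced in 3D, so border sharpness is a 3D property —
  with replicate padding at the grid boundary, so locally constant
  regions (including the volume edge) respond zero.
* **Gdzscore** (`gd_zscore()`): the voxel-wise difference
  `gd - t1` standardized against its distribution over
  normal-appearing brain (brain minus lesion), using the population
  SD. A z-score map makes "enhancement" comparable across cases; a
  zero-SD reference yields an all-zero map by convention. The exact
  reference population is a declared package choice (brain excluding
  the lesion), as is the enhancement threshold z > 2 used for the
  enhancing-area feature.

### Registration and lesion mapping space

Cross-subject location analysis needs a common space.
`register_affine_mi()` provides an affine registration maximizing
mutual information (32-bin joint histogram) with 6, 9 or 12 degrees of
freedom, multi-resolution, with derivative-free Nelder-Mead
optimization and seeded jitter restarts. It is a self-contained
implementation of the standard MI-affine contract, validated on
synthetic phantoms with planted transforms (recovery within 0.5 voxel
and 1 degree in at least 90% of trials); it does not attempt to
reproduce any external tool numerically. Resampling
(`resample_to_atlas()`) is trilinear for intensities and
nearest-neighbor for masks, so masks stay binary; left-right flips
(`flip_lr()`) mirror about the voxel x midline of the atlas grid.
The synthetic generator produces volumes directly in atlas space, so
registration is exercised by phantom studies rather than inside the
default cohort path.

### The 109-feature vector

`feature_inventory()` fixes the default feature set:

| block | count |
|---|---|
| first-order histogram stats (mean, SD, skewness, excess kurtosis, median, p10, p90, entropy) for T1, T2, FLAIR, Gd, T2Edge | 40 |
| Gdzscore: the same first-order stats with 256-level entropy replaced by the enhancing-area fraction `Gdzscore_ara.of.Gd.` | 8 |
| shape: volume (mm^3) and sphericity | 2 |
| occupancy on the 10-label structural atlas (`MNI_str_loc.01..10`) | 10 |
| occupancy on the 49-label cortical atlas (`HrvdOxf_loc.01..49`) | 49 |

Histogram entropy is defined on the native 256-level histogram (no
re-binning; inputs are already 8-bit). It is dropped for the Gdzscore
channel because z-scores are continuous and a 256-level histogram of
them is not defined; the enhancing-area fraction takes its slot,
keeping eight statistics per channel and 109 features in total. SD,
skewness and kurtosis use population (n) normalization; zero-variance
regions return skewness/kurtosis 0 with a warning so tables stay
complete.

Sphericity is `pi^(1/3) (6V)^(2/3) / A`. No mesh library is used for
the surface area `A`; instead the package uses a coarea (smoothed
gradient) estimator: the mask indicator is mollified with a Gaussian
(sigma 0.7 voxels) and `A` is the integral of the gradient magnitude.
Sigma was calibrated once against analytic spheres of radii 5–12
voxels, where the estimator is accurate to about 2%. It is a smoothed
estimator: very small lesions (a few voxels across) can exceed
sphericity 1, and thin elongated shapes are smoothed toward higher
sphericity than the continuum value. Within one cohort the estimator
is used consistently, which is what the downstream screens and models
need.

Location is encoded by `occupancy_features()`: for each atlas label
(including 0, the white-matter/background label) the fraction of
lesion voxels carrying it. `loc.(k+1)` corresponds to original atlas
value `k`, so `MNI_str_loc.01` is the white-matter fraction and
`MNI_str_loc.04` the frontal-lobe fraction. Occupancy vectors sum to 1
whenever the atlas labels the whole grid — they are compositional
location coordinates, not statistics of intensity.

The package ships *toy* atlases (`make_toy_atlas()`): deterministic
geometric label maps with the same integer conventions as the real
segmentations (10 labels with a deep white-matter core and label 3
frontal; 49 cortical parcels over a white-matter core). The real,
copyrighted atlas volumes can be substituted by any user who has them;
everything downstream only needs an integer label volume plus a label
table.

### Voxel-wise lesion-frequency statistics

For each atlas voxel covered by at least one lesion, the 3x2 table
(three subtypes x lesion-positive/negative) is tested with a
two-tailed exact Fisher test (`fisher_3x2_p()`). The test enumerates
all tables with the observed margins and sums the probabilities of
tables no more probable than the observed one — the
probability-ordering two-tailed rule, stated explicitly because k x 2
two-tailed definitions vary. Because the per-voxel table is determined
by the three lesion-positive counts once group sizes are fixed,
`fisher_3x2_lookup()` precomputes the p-value for every count triple,
and maps and permutation replicates become array lookups; this is what
makes a 500-permutation analysis on a full grid fast.

Multiplicity is handled by cluster-based permutation correction
(`cluster_permutation_correct()`): suprathreshold voxels (p < 0.05)
are grouped into connected clusters (26-neighbor connectivity by
default; the choice is exposed), subtype labels are reassigned at
random across cases — preserving group sizes, the only exchangeable
unit here is the case — and the maximum suprathreshold cluster size is
recorded per permutation. An observed cluster is significant when its
permutation-corrected p-value, `(1 + #{null >= size})/(1 + B)`, is at
most alpha — the finite-sample form of "exceeds the null 95th
percentile". The add-one correction matters: thresholding on the naive
empirical quantile with strict exceedance inflates the family-wise
error rate noticeably at B around 100 (we measured ~0.095 at nominal
0.05 on null simulations), while the corrected rule keeps it near or
below nominal; the test suite verifies control within [0.01, 0.09].
Max cluster *size* (not mass) is the null statistic.
An optional flag unions each mask with its mirror image
first, for laterality-ignored mapping; the default analyzes masks as
drawn.

### Predictive modeling

`institution_balanced_split()` partitions the cohort randomly while
balancing institutions: each institution contributes its
largest-remainder share of the training total, so a 169-case cohort
always splits 111/58 at the default fraction. LASSO selection
(`fit_lasso_cv()`, glmnet) picks the penalty at `lambda.min` (minimum
10-fold cross-validated deviance; fold count is a package default, as
the deviance loss), then the model is refit without penalty on the
selected features (`refit_and_evaluate()`; logistic for the binary
IDH task, multinomial logit for the 3-subtype task) and evaluated on
training and validation sets separately. Standardization happens
inside the penalized fit on training data only. If nothing is
selected, the model predicts the training majority class — the honest
null behavior.

The atlas powering the location block differs by task: the binary IDH
task uses the 10-label structural occupancies (deep white matter
matters there), the 3-class task the 49-label cortical occupancies
(finer cortical detail separates the two IDH-mutant subtypes); the
two blocks are never used together since they are largely redundant.
`repeat_and_compare()` repeats the whole chain over fresh splits (5 by
default), runs a location-free arm on the same splits, and compares
the arms with an exact McNemar test on the pooled validation
predictions — the comparison test is a package choice, made explicit
because paired accuracy comparisons are otherwise ill-defined.

## What the synthetic generator emulates — and what it does not

`cohort_spec()` defaults encode the study conditions: 169 cases with
complete 4-channel MRI across 11 institutions; three subtypes in
roughly equal proportions; subtype-biased lesion locations (astrocytomas
frontotemporal, oligodendrogliomas frontal, wildtype white
matter/parietal — the location weights are qualitative choices, since
only relative preferences are known); subtype- and channel-specific
lesion intensity offsets; and contrast enhancement probabilities
(0.1, 0.1, 0.6) marking the wildtype group. Lesions are axis-aligned
ellipsoids with mild anisotropy (axis ratio at most 2) — the simplest
geometry with non-trivial shape features. Volumes are generated
directly in atlas space on a 40^3 grid at 2.5 mm spacing with lesion
radii 8–15 mm; a label-modulated baseline gives the "brain" enough
structure for intensity statistics to be meaningful.

Deliberately not modeled: MR physics (bias fields, coil profiles),
scanner-specific intensity non-stationarity, infiltrative lesion
geometry, partial-volume effects, DICOM. Consequently, green tests
show that the *statistical machinery* behaves as designed — exact
tests exact, error rates controlled, planted effects recovered, the
location block adding information when location carries the signal —
not that the pipeline reaches any particular accuracy on clinical
images. On the default synthetic cohort the subtype texture offsets
are strong, so classification accuracies are optimistic relative to
real data; the interesting quantity is the *difference* between the
location-on and location-off arms under planted location effects, and
the chance-level behavior (1/3 for three balanced classes) when no
signal is planted.

## Numerical choices and degenerate inputs

* Gray-level map: floor-based, maximum to 255, constant volume to 0.
* Percentile and quantile computations use R's default (type 7) rule.
* Zero-variance conventions: skewness/kurtosis 0, ANOVA p = 1,
  correlation 0 — each with a warning, so tables stay total without
  silently hiding degeneracy.
* Fisher enumeration compares table probabilities with a 1e-7 relative
  tolerance when accumulating the two-tailed sum, protecting
  probability-ordering ties against floating-point noise; agreement
  with R's exact implementation is at 1e-9 over all tables with
  total <= 12.
* Registration: 32 histogram bins at every pyramid level; Nelder-Mead
  with successive restarts at shrinking parameter scales (escaping
  collapsed simplices); translations are optimized in the voxel units
  of each pyramid level and rescaled between levels. Degenerate
  (constant) images are rejected — MI is undefined there.
* Masks are resampled nearest-neighbor only; binarity is asserted by
  construction.
* The pipeline derives per-stage seeds from one master seed by
  stage-name hashing (`derive_seed()`), so stages can be re-run
  independently and the whole run is reproducible byte-for-byte.

## Problem sizes used by the test suite

The suite exercises every property at sizes chosen for statistical
resolution: the family-wise error rate over 200 null replications of
100 permutations each on a 32^3 grid (15 cases per subtype, radius-8
spherical lesions — dense enough coverage that the max-cluster null is
non-degenerate); registration recovery over 20 planted rigid
transforms on 32^3 phantoms; chance-level behavior over 20 (tests) or
50 (acceptance script) repetitions of the full 3-class chain at
n = 169; and LASSO recovery of a planted 5-SD feature over 20 seeded
runs at n = 120 with 109 features.

## Known limitations

* The toy atlases are geometric stand-ins; occupancy features are
  meaningful relative to those label geometries only.
* The sphericity estimator is biased upward for lesions a few voxels
  across and for thin shapes (smoothing); it is consistent within a
  cohort, which is what screening and modeling use.
* The registration is a compact MI implementation intended for
  phantom-validated synthetic work, not a tuned clinical tool: no
  partial-volume interpolation in the histogram, no regularization of
  shear/scale beyond the parameterization.
* The generator plants effects through a small number of mechanisms
  (location weights, channel offsets, enhancement probability); real
  cohorts carry correlated nuisance structure (age, acquisition site
  effects on texture) that is not simulated, so institution balancing
  is exercised mechanically rather than stress-tested.
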