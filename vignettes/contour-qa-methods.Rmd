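---
title: "Knowledge-based contour QA: models, phantom, and design notes"
author: "ContourQA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Knowledge-based contour QA: models, phantom, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Radiotherapy treatment planning for head-and-neck cancer relies on dozens of
organ-at-risk (OAR) contours per patient. Contouring failures — a border
dilated by a few millimetres, a missing or extra volume, a stray single-slice
"ditzel" left by a misclick, a structure placed at the wrong location or under
the wrong label — propagate silently into dose optimization. ContourQA
implements a knowledge-based QA framework that learns, per OAR type, what
acceptable contours look like from a curated corpus, and flags contours that
deviate. It is a one-class approach: only acceptable contours are used for
training, and erroneous contours are detected as outliers.

## Models

Each contour is reduced to 20 single-contour features (`featureNames()`):
centroid relative to the brainstem centroid (the brainstem itself is
referenced to the pituitary), the components of the first two
principal-component eigenvectors of the voxel-center cloud, volume, the
ratios of the second and third covariance eigenvalues to the first, per-axis
extents, Wadell sphericity, and four CT intensity statistics. Geometry is
computed on voxel centers in physical millimetres so that anisotropic slice
spacing does not distort orientation.

Three per-OAR one-class models score these features:

* **z-score**: `max_j |x_j - mu_j| / sigma_j` over the training mean and
  standard deviation of each feature; the maximum across features is the
  output metric.
* **Mahalanobis distance (MD)**: `D(x) = (x - mu)' Sigma^{-1} (x - mu)`,
  the squared form. The covariance uses Ledoit–Wolf shrinkage toward the
  scaled identity (see *Numerical choices*).
* **Autoencoder (AE)**: a single hidden layer of 18 sigmoid units with
  linear outputs, trained on z-scored features with an L2 weight penalty of
  0.005 for at most 7000 epochs by full-batch quasi-Newton optimization
  (early stop when the relative loss change falls below 1e-9). The output
  metric is the mean squared reconstruction error (MSRE).

Eigenvector signs are arbitrary, so a representative eigenvector per OAR is
chosen from the training set as the member maximizing the summed absolute
dot product with all others, and every eigenvector is flipped to have a
non-negative dot product with it.

Before any model is fitted, training rows deviating from the per-feature
median by more than twelve (unscaled) median absolute deviations on any
feature are removed — one-class training is only as good as its training
set.

Two relational models complement the feature models:

* **CCR (contour-to-contour relationship)**: for configured pairs of OARs
  (rows = selected contour, columns = comparison contour, plus a body
  column), the minimum surface distance is fitted to a gamma distribution
  and the directional fractional overlap to a beta distribution. The
  acceptance interval is the central 99% of the fitted distribution,
  expanded by 2 mm (distance) or 0.02 (overlap) and clipped to the feature
  domain. A contour is CCR-flagged when any of its own (row) pairs falls
  outside its interval; both members of the pair are reported for review.
* **Connectedness**: the number of 26-connected parts must not exceed a
  per-OAR maximum — the observed value when all training counts agree, or
  the ceiling of the 99.95% quantile of a gamma fit otherwise. Some organs
  are legitimately multi-part (a two-lobed thyroid), which is why the
  threshold is learned rather than fixed at one.

The final verdict is the logical OR of the flags. The single-contour metric
thresholds are tuned on a validation set to maximize balanced accuracy (the
mean of sensitivity and specificity) of the OR-combined classifier, with
the CCR and connectedness flags held fixed; solo thresholds are tuned the
same way without the fixed flags, and the test set always reuses validation
thresholds. The CCR intervals and the parts thresholds are also adjusted on
the validation set so that no acceptable validation contour is flagged —
bounds violated by an acceptable value are widened to cover it plus a small
margin (0.5 mm / 0.005). Balanced accuracy is an appropriate objective at
roughly 10% error prevalence with a 9:1 cost ratio for missed errors; both
are exposed as knobs in `tuneThreshold()`'s callers for other settings.

## The phantom

The package carries its own synthetic data so the whole framework can be
trained, tuned and evaluated without patient data. `defaultRoster()` defines
19 head-and-neck-like OARs — ellipsoids (brain, eyes, lenses, glands),
tubes (cord, esophagus, larynx), a box-union mandible, a two-lobed thyroid —
on a 96x96x96 grid at 1.27 x 1.27 x 2 mm spacing, with the topology QA
cares about built in: the lenses are nested inside the eyes (overlap 1 by
construction), the cord abuts the brainstem (distance 0), the brainstem
partially overlaps the brain, and paired organs are mirrored in x.

Patient-to-patient variation emulates what drives feature variance in real
corpora: a global patient scale (±10%), per-organ scale (±12%), per-axis
aspect variation (±8% in-plane) with a wider longitudinal range (±15% —
observers disagree most on the first and last contoured slice), translation
jitter (sd 2.5 mm, clamped at 5 mm), a small 3D orientation jitter for every
organ (sd 5 degrees; anatomy is never exactly grid-aligned, and without it
eigenvector components have voxelization-only variance and any perturbation
scores hundreds of sigmas), and tube axis tilt (sd 2 degrees). The synthetic
CT paints tissue-class means with per-scan calibration shift (sd 6 HU),
per-organ composition jitter, spatially correlated texture, a scanner
point-spread-function blur (Gaussian, 0.8 voxels) that produces the
partial-volume mixing real contours sample at their boundaries, and detector
noise. Without the PSF and calibration terms, contour CT extremes (`ct_min`,
`ct_max`, `ct_std`) are single-voxel statistics with near-zero
between-patient variance, and every stray voxel lights them up — a
synthetic-data artifact, not a property of the method.

What the phantom does **not** model: real anatomical shape detail,
deformable inter-patient variation, dental artifacts, truncated fields of
view, or institutional naming conventions. Passing phantom tests shows the
pipeline is internally consistent and reproduces the qualitative behavior
of the framework; it does not certify performance on clinical data.

### Injected errors

`injectError()` implements the four clinical failure categories with known
ground truth; the image is never modified (an erroneous contour covers
tissue it should not, as in the clinic):

* **boundary**: isotropic dilation/erosion — moderate ±2 mm, major 4–6 mm;
* **volume**: attach or carve a convex blob, or truncate terminal slices —
  moderate 10–20%, major 30–50% of the organ volume;
* **non-adjacent slice**: moderate, a disconnected single-slice ditzel
  (1.8 mm disc) at ≥ 5 mm clearance, placed preferentially inside the
  organ's bounding box on soft tissue — the realistic stray-click that
  barely moves any feature and is exactly what the connectedness model
  exists for; major, jagged slice-to-slice misalignment;
* **position**: whole-mask translation — moderate 10–15 mm, major
  25–35 mm — or a mask swap.

These magnitudes are artifact-defined calibrations (chosen so that "major"
errors are unmistakable and "moderate" ones sit near the detection
boundary); the source corpus they emulate reports only the category
taxonomy, not magnitudes.

`phantomStudy()` runs the complete experiment: 100 structure sets split
80/10/10, erroneous variants appended to the validation and test subsets on
top of the intact acceptable sets (so acceptable contours keep acceptable
pair partners), with categories allocated by largest-remainder quota in the
proportions 74 : 99 : 14 : 40 (boundary : volume : slice : position), at
least four erroneous contours per paired OAR type and five per unpaired
type in each subset, and severities split evenly. Slice errors are only
assigned to organs spanning roughly a dozen slices or more, where
scroll-through misclicks arise. The problem sizes (100 sets, a 96^3 grid,
19 OARs) are the package's study conditions; `phantomConfig()` exposes all
of them.

## Numerical choices

* **Covariance shrinkage.** With ~80 training contours and 20 features the
  sample covariance underestimates its smallest eigenvalues severely
  (d/n = 0.25), so a plain or ridge-floored inverse inflates the
  Mahalanobis metric for any direction unseen in training and the MD model
  degenerates into "flag anything new". `fitMd()` therefore estimates the
  Ledoit–Wolf shrinkage intensity from the data (it vanishes as n grows)
  and keeps a 1e-6 ridge floor so the inverse exists even at n = d.
* **Gamma fits need positive support**: zero distances are clipped to
  0.01 mm before fitting; overlaps are clipped to [1e-4, 1 - 1e-4].
  Degenerate all-identical samples get point-mass bounds value ± expansion.
  If a maximum-likelihood fit fails to converge, empirical quantiles are
  used for that bound.
* **Bound expansion is applied before domain clipping**, so a touching pair
  (all distances 0) gets the interval [0, 2 mm].
* **Parts counting** uses 26-connectivity, matching the "separate blob"
  perception of a reviewer scrolling slices.
* **Sphericity** is Wadell's `pi^(1/3) (6V)^(2/3) / A`. The surface area A
  weights each exposed voxel face by the dot product between the face
  direction and the local surface normal estimated from a smoothed copy of
  the mask — summing `face_area * (n . e)` over the closed staircase
  surface reproduces the true area for locally planar patches (a
  divergence-theorem argument), avoiding both the ~30–70% staircase
  overestimate of raw face counting and the corner-rounding bias of meshing
  a smoothed field. A marching-tetrahedra mesher over scalar fields is kept
  as an independent cross-check.
* **Surface distance** is measured between boundary-voxel centers
  (sub-voxel precision is not attempted); intersecting masks have
  distance 0.
* **Extent convention**: per-axis difference of occupied voxel-center
  coordinates, so a single-voxel contour has zero extent.
* **z-score degenerate rule**: a zero-variance feature contributes 0 when
  the value equals the training mean and infinity otherwise.
* **Thresholds**: candidates are midpoints of sorted unique metric values
  plus ±infinity; ties prefer the higher threshold (specificity).
* **Missing CT**: contours without an attached image are excluded from
  training; at inference their CT features are imputed to the training mean
  (a neutral contribution), keeping the geometric screen available.
* **Determinism**: every stochastic step (generation, injection, AE
  initialization, subsampling) is seeded; identical seeds give
  byte-identical reports.

## Open design points, resolved

* The institutional OAR roster and the exact 42x43 CCR pair matrix of the
  source framework are not public; both ship as editable configuration
  (`defaultRoster()`, `ccrMatrix()`, CSV read/write).
* Whether thresholds are global per model type or per-OAR is ambiguous in
  the source description; a single global threshold per model type is
  implemented (metrics are normalized by training statistics, so they are
  comparable across OARs), with per-OAR overrides possible through the
  bundle slot.
* "Upper and lower 99th percentile boundaries" is read as the two-sided
  central 99% interval (quantiles 0.005/0.995); manual adjustment is
  available and the validation calibration step plays that role
  automatically.
* DICOM RT-Struct input is out of scope for this implementation (no DICOM
  reader in the dependency set); co-registered NIfTI label volumes and
  per-contour mask files are the supported input paths.

## Limitations

The phantom's organs are geometric primitives; its feature distributions
are narrower and cleaner than clinical ones, and the detection metrics
reported by `phantomStudy()` should be read as internal-consistency
results, not clinical performance. The AE is trained with a quasi-Newton
full-batch optimizer, so weights are reproducible but not identical to any
other tool's; acceptance of the AE is behavioral (reconstruction quality
and outlier ranking). CCR bounds for organ pairs that are far apart carry
wide intervals and little signal — the default matrix evaluates adjacent
and nested pairs only, plus the body column.
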