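---
title: "Standardized pixel-wise analysis of myocardial injury: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Standardized pixel-wise analysis of myocardial injury: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(myoatlas)
```

## The problem

Delayed-enhancement cardiac MRI of acute myocardial infarction is usually
summarized by a handful of global descriptors — infarct size, transmurality,
endocardial surface area. These discard most of the spatial information in the
segmented lesion maps: where around the circumference the infarct sits, how
deep it reaches at each location, whether a microvascular-obstruction (MVO)
core is present inside it. Comparing lesion *patterns* between patients, or
between treatment arms of a trial, requires first removing anatomical
differences between subjects: different ventricle sizes, slice counts, slice
coverage, in-plane orientations.

myoatlas implements a statistical-atlas approach to this problem. Each
subject's left-ventricular myocardium is parameterized by three normalized
coordinates; segmented lesion channels are transported through this coordinate
system onto one common semi-ellipsoid geometry; and group comparisons are then
performed at every myocardial location, alongside the classical global
descriptors and a low-dimensional embedding of the whole cohort.

## Normalized myocardial coordinates

For every myocardial pixel of every slice we compute:

* **radial** `r = d_endo / (d_endo + d_epi)`, where `d_endo` and `d_epi` are
  unsigned Euclidean distances to the endocardial and epicardial contours.
  `r` is 0 on the endocardium and 1 on the epicardium. The two-distance ratio
  is used because it is independent of how the contours are parameterized and
  is monotone across the wall; when polygon contours are stored with the study
  the distances are exact point-to-polyline distances, and after a bundle
  round trip (labels only) they fall back to Euclidean distance transforms of
  the cavity and exterior regions.
* **circumferential** `c`: the polar angle about the cavity center (the
  endocardial polygon centroid), measured anticlockwise in the displayed image
  plane (y up), zeroed on the ray through the LV-RV junction landmark, mapped
  to [0, 1). A chirality flag flips the direction for mirrored acquisitions.
  An angular parameterization (rather than arc length) keeps Bull's eye
  segments angle-regular and anchored at the junction.
* **long-axis** `z = (k - apex) / (base - apex)` for slice index `k`, with
  real-valued apex and mitral-level annotations that may lie outside the
  acquired stack when the annotator extrapolated them. Slices with `z`
  outside [0, 1] are excluded.

Fields are estimated on grids oversampled in-plane by a factor of 4 (default).
With contour-exact distances the pointwise coordinate accuracy is already at
polygon precision regardless of oversampling; what oversampling buys is a
denser sampling of the thin wall, which is what prevents artifacts in the
scattered-data interpolation step below. The tests therefore quantify the
oversampling benefit as the reconstruction error of the coordinate samples on
a 3-pixel-thick annulus (it roughly halves per doubling of the factor), not as
a pointwise field error.

Where a pair of outflow-tract landmarks is present on a slice, the angular
wedge between the two rays (the shorter interval; an explicit side flag is
required in the ambiguous 180° case) is removed from the analysis mask.

## The reference geometry and warping

The common geometry is a semi-ellipsoid with maximal endocardial/epicardial
radii of 30/50 px on 21 slices of 80×80 px (defaults). The taper toward the
apex is an ellipse quarter-arc, `radius(z) = R_base * sqrt(1 - ((1-z) *
a)^2)` with `a = 0.98`, chosen so the apical slice keeps a small nonzero
wall; only the basal radii, slice count and grid size are fixed by convention,
so the taper parameter is configurable. Note that with these conventional
radii the outermost part of the basal epicardial ring extends beyond the
80×80 grid and is cropped — the familiar "incomplete basal myocardium" of
polar displays — and the lattice resampler fills such radially incomplete
columns by interpolation along the radial bins.

Warping maps each reference myocardial pixel, through its own (r, c, z)
coordinates, into the subject's coordinate space and interpolates the
subject's channel values there. The interpolation is piecewise linear on the
myocardial coordinates, implemented slice-wise: each subject slice's scattered
(c, r) samples are bin-averaged onto a regular periodic grid (96 × 32 nodes by
default, empty nodes filled by neighbor averaging), queried bilinearly, and
the two slices bracketing the query's `z` are combined linearly. Every step
(averaging, bilinear and linear mixing) is a convex combination, so warped
values never leave the input range; a channel constant on the myocardium
warps to exactly that constant. We chose this regularized-grid scheme over a
simplicial (Delaunay) decomposition because it has the same piecewise-linear
character, is robust to the near-degenerate sample geometry of thin apical
walls, and needs no computational-geometry dependency.

Binary channels become soft values in [0, 1] on the reference ("partial
volume" of the lesion at that standardized location) and are *not*
re-thresholded; group averaging consumes the soft values. A `rebinarize`
switch (0.5 threshold) exists for sensitivity analysis.

**No extrapolation:** reference pixels whose `z` lies outside the subject's
acquired slice range are flagged missing, never imputed. Coverage can only
grow when the acquired range grows.

## The analysis lattice and per-location statistics

Patterns are resampled onto a 24 (circumferential) × 21 (slices) × 20
(radial) cell lattice by averaging the covered reference pixels in each cell.
From the lattice we compute, per (c, z) location: **location** (radial
maximum), **transmurality** (radial mean), **variability** (across-subject
standard deviation of per-subject transmurality — the package's
operationalization, since "variability" has no unique standard definition),
and the **p-value** of the two-sample Hotelling T² test comparing treatment
arms, with the per-subject radial profile (20 values) as the feature vector —
so the p-map matches the Bull's eye layout — and a univariate per-location
transmurality mode as a configuration switch.

The T² test uses the pooled covariance with a Moore–Penrose pseudo-inverse
(relative singular-value tolerance 1e-8) because near-binary lesion data are
often rank-deficient; the F transformation uses the effective dimension
q = rank, `F = (n - q - 1) / ((n - 2) q) · T²` on (q, n − q − 1) degrees of
freedom. For q = 1 this reduces exactly to the squared pooled-variance
two-sample t statistic and its two-sided p-value, which the tests assert at
1e-10. No multiple-testing correction is applied — the maps display raw
p-values, and the summary statistic (the percentage of myocardial locations
with p below 0.05) documents this explicitly.

Bull's eye grids are 21 rings (apex innermost) × 24 segments (segment 1 at
the junction, anticlockwise); p-values are displayed on a logarithmic color
scale.

## Global descriptors

Five descriptors per subject and geometry (native and standardized): infarct,
early-MVO and late-MVO area (% of myocardium), transmurality (%, averaged
over infarct-bearing columns only, i.e. excluding preserved myocardium, and
missing — not zero — when no infarct exists), and endocardial surface area
(%). All five are computed from the same (c, z, r) lattice with equal cell
weights in both geometries: native mode bins the subject's own coordinates,
standardized mode bins the warped pattern. Equal cell weighting (rather than
raw pixel counting) makes the two modes directly comparable and makes the
descriptors equal to their analytic values on idealized wedges (a wedge of
circumferential extent 0.25, depth 0.6 and half the slices has area
0.25 × 0.6 × 0.5 = 7.5%).

The endocardial surface estimator is the mean of the innermost radial-bin
value over columns. For binary native lattices this equals the fraction of
infarct-bearing endocardial columns; for soft warped lattices it is the
expected subtended fraction. A thresholded column count was rejected because
interpolation leak inflates it systematically in standardized geometry (the
soft estimator keeps native and standardized descriptors within 15% relative
on fully covered synthetic subjects; the thresholded count does not).
Columns are considered infarct-bearing when their transmurality exceeds 0.05,
a small floor that ignores interpolation leak at lesion borders.

## Realignment and embedding

For population-level pattern comparison across territories, every infarct
pattern is rotated along the circumference so that the average infarct center
of its territory (circular mean of the per-subject intensity-weighted phasor
centers) coincides with the average center of the LAD territory; LAD patterns
are left unrotated. Rotations are applied as the integer lattice shift
nearest to the circular difference, trading at most 1/48 of alignment error
for exact mass preservation. Subjects with zero infarct cannot be assigned a
center and are excluded from the embedding with a warning.

The embedding is exact t-SNE (authored in-package: per-point perplexity
search, early exaggeration 12 for 250 of 1000 iterations, momentum 0.5→0.8,
learning rate `max(50, n/48)`, PCA initialization scaled to sd 1e-4),
deterministic given the seed, with defaults of 2 components and perplexity 10
and at least `3 × perplexity` subjects required. Input vectors are the
flattened realigned lattices with missing cells imputed as 0 — absence of
lesion — under the Euclidean metric; both the representation and the metric
are package choices, documented here because no unique standard exists.
Stability across seeds can be quantified as the mean pairwise Procrustes
disparity over reruns.

## The synthetic cohort generator

Trial imaging data of this kind are not publicly redistributable, so the
package ships a generator whose defaults emulate the study conditions the
pipeline targets: two treatment arms of 65 and 58 subjects; four culprit
territories (LAD mid, LAD proximal, LCX, RCA) with mixture weights 0.20 /
0.16 / 0.14 / 0.50; stacks of about 17 ± 2 slices at 1.5625 mm in-plane and
5 mm slice spacing, with on average about one slice of the ventricle lying
outside the acquired stack (extrapolated apex/mitral annotations); and about
1/123 of subjects without any infarct. Anatomies are near-circular annuli
tapering toward the apex with smooth contour jitter, per-slice center drift
and junction-landmark jitter. Lesions are wedges in coordinate space:
circumferential interval × slice span × transmural depth, growing outward
from the endocardium, with cosine-tapered depth toward the wedge edges
(creating smooth transmurality gradients) and optional concentric MVO cores
nested inside the infarct by construction. Territory centers (0.17 / 0.46 /
0.79 in circumferential units, anterior/lateral/inferior relative to an
anterior junction) are a documented convention. Arm effects add transmural
depth and/or circumferential extent inside named segment and slice ranges.
Each subject draws from an independent random stream keyed by (master seed,
subject index), so cohorts are bitwise reproducible and extensible without
perturbing existing subjects.

What the generator does *not* emulate: image intensities (the pipeline
consumes segmentations, not images), papillary muscles and trabeculation,
non-annular pathology, true perfusion-territory geometry, inter-observer
segmentation variability beyond contour jitter. Passing tests on synthetic
cohorts therefore validate the geometry, statistics and plumbing of the
pipeline — not the clinical segmentation upstream of it.

## Numerical choices and degenerate inputs

* Rasterization: pixel-center-in-polygon with the even-odd rule; centers
  exactly on an edge count as inside (deterministic tie-break).
* Labels are one integer bitmask volume (myocardium / infarct / early MVO /
  late MVO) so nesting is cheap to check; nesting violations are counted in
  the validation report, then clipped.
* Slice indices are 1-based; apex/base annotations are real-valued on the
  same axis and may lie outside the stack.
* Contours touching (zero wall thickness) invalidate the affected pixels;
  slices with near-single-pixel myocardium are dropped with a warning; a
  myocardium-bearing slice without a junction landmark is an error.
* Circumferential periodicity is handled by periodic indexing of the (c, r)
  value grids, so there is no seam artifact at c = 0.
* Zero pooled covariance with a nonzero mean difference (perfect separation)
  is reported as p = 1e-300 rather than a spurious p = 1.
* Mann-Whitney comparisons use the normal approximation with tie correction;
  fully tied samples give p = 1.

## Problem sizes used in tests and the acceptance script

The statistical simulations (null calibration over ≥2000 location-replicates,
regional effect recovery at n = 60 + 60) run on a compact anatomy — 48 px
grids, ~10 slices, oversampling 2 — which exercises the identical code paths
at lower resolution; the fidelity checks (coordinate accuracy, warp round
trips, native-vs-standardized agreement) run at the default 64 px / ~17-slice
/ oversample-4 conditions. These sizes are the package's chosen test design:
large enough for the binomial tolerances asserted, small enough to keep the
suite convenient to run routinely.

## Known limitations

* The coordinate system is per-slice (2D + stacked z); no trans-slice
  smoothing or 3D Laplace/prolate-spheroidal parameterization.
* Linear z interpolation between slices blurs lesion boundaries by up to half
  a slice spacing; descriptors in standardized geometry inherit a
  corresponding small bias relative to native geometry.
* The CVI42 workspace parser targets the hash/list layout and contour element
  names of v.5.x exports; the role map is the documented extension point for
  other versions.
* Raw (uncorrected) p-value maps are displayed by design; cluster-based or
  FDR-controlled inference is out of scope.
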