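---
title: "Renal CT morphometry: models, parameters and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Renal CT morphometry: models, parameters and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(renalmorph)
```

## The measurement problem

Kidney length, width, thickness and volume are everyday clinical
descriptors: they feed donor eligibility assessments, transplant matching,
and longitudinal follow-up of renal disease. On CT they are traditionally
obtained either by full manual delineation (accurate, slow, observer-
dependent) or by the ellipsoid shortcut
$V = \frac{\pi}{6}\, L \cdot W \cdot T$, which is fast but biased because
kidneys are bean-shaped, not ellipsoidal.

`renalmorph` implements the segmentation-to-measurement chain that sits
between a voxelwise kidney segmentation (from any source: a neural network,
an atlas method, a human) and the clinical numbers, together with the
agreement statistics used to compare automated against manual
measurements, and a seeded phantom generator that provides analytic ground
truth for validating every stage.

## Coordinate contract

All volumes are handled as `scalar_grid` / `label_grid` objects: a 3-D
lattice plus spacing (mm), origin (mm), and an orthonormal direction
matrix. On load (`read_volume()`), images are reoriented to RAS+
(+x patient right, +y anterior, +z superior); voxel indices are 0-based
and refer to voxel centers, so voxel $(i,j,k)$ sits at
$\mathbf{o} + D\,(\mathbf{s} \odot (i,j,k))$. A fixed frame is what makes
"length = inferior–superior" a meaningful, automatic label later in the
chain. Label maps use the fixed coding 0 = background, 1 = right kidney,
2 = left kidney. NIfTI headers store affines in float32, so geometry
round-trips to about $10^{-5}$ relative precision — spacing survives to
1e-6 mm, world origins at |100| mm to a few times 1e-6 mm.

## Processing model

**Windowing.** CT intensities are clamped to a protocol window and
min-max normalized to [0, 1]: 200/300 HU (level/width) for
contrast-enhanced (CE) protocols, 65/170 HU for noncontrast (NC). The
windows bracket the kidney parenchyma HU distributions of the two
protocols (medians ~171 HU CE, ~28 HU NC).

**Resampling.** NC images are resampled to 1.5 mm isotropic spacing for
inference (their 5 mm slices are too anisotropic for 3-D patches); CE
images run at native resolution. Label maps are resampled by trilinear
interpolation of per-class indicator functions followed by argmax (ties
toward background), the same dialect used when masks are later upsampled.

**Sliding-window inference.** A pluggable `predictor` maps a 96³ patch of
normalized intensities to per-class scores. Patches tile the volume with
overlap 0.5 (stride = half patch, last patch edge-aligned); overlapping
scores are averaged arithmetically with uniform weights. The predictor
contract passes the patch origin and image shape alongside the patch so
position-aware backends can tell right from left at the midsagittal
plane. Whether overlapping predictions should be averaged as logits or as
probabilities is a genuine dialect ambiguity; the harness averages
whatever scores the backend emits, and the two dialects can disagree at
argmax boundaries.

**Post-processing.** Argmax over averaged scores (ties to the lower class
index), then per-kidney-class largest connected component. Connectivity is
26-neighborhood — the permissive 3-D standard; it is exposed nowhere else
because the choice only matters for pathological masks. For NC, the
processed mask is upsampled back to native resolution by trilinear
interpolation of the indicator and binarized at a threshold; the threshold
can be fixed (0.5) or selected on validation cases (`select_threshold()`)
by maximizing mean Dice over a 0.05-step grid, ties to the lowest value.

A numerical note on that threshold: trilinear interpolation of blocky
binary data under-shoots 0.5 on diagonally oriented surface patches, so a
0.5 threshold mildly erodes strongly curved objects. On a digitized
radius-20-voxel sphere the full 1.5 mm down/up round trip loses about 4–5%
of volume at T = 0.5, while a validated threshold near 0.35 recovers it to
~2% (at radius 30 the loss at T = 0.5 is already below 1%). This is
exactly why threshold selection is part of the pipeline rather than a
hard-coded constant.

**Reference backend.** To run the pipeline end-to-end without trained
weights, `reference_hu_predictor()` provides an intensity-model backend:
kidney score $\exp(-s\,(v - 0.5)^2)$ on the window-normalized, lightly
box-smoothed intensity $v$, background score its complement, kidney mass
assigned right/left by the midsagittal plane. The decision level — the
$v$ at which the kidney score crosses 0.5 — is the meaningful parameter:
background tissue clamps to $v = 0$ under both windows while kidney
parenchyma sits near 0.40 (CE) or 0.28 (NC), so the default 0.17
approximates half the kidney's normalized density under either protocol
and splits boundary partial-volume voxels without systematic erosion or
dilation. This backend is a transparent physical model, useful as a
pipeline exerciser and baseline; it is not a learned segmenter.

## Morphometry

Volume is voxel counting at the original spacing:
$V = N \cdot \prod s / 1000$ mL. Axes need more care:

1. the kidney mask is interpolated to 1 mm isotropic spacing (indicator
   trilinear, 0.5 threshold);
2. `principal_frame()` runs PCA on the world coordinates of the
   foreground voxel centers (the unweighted point cloud);
3. `obb_extents()` measures the span of point projections along each
   principal axis — the minimal bounding box oriented along the PCA axes;
4. `label_axes()` matches principal axes to patient axes
   (superior–inferior, medial–lateral, ventral–dorsal) by maximizing the
   total |cosine| over all six one-to-one assignments, ties preferring the
   largest component for superior–inferior. Length, width and thickness
   are the extents of the S–I, L–M and A–P assigned axes respectively.
   The assignment is stable for tilts below 45°, which covers anatomical
   kidney orientations comfortably.

Two design points deserve explanation:

*Extent compensation.* Voxel-center spans under-measure a slab-like
structure by exactly one voxel (a w-voxel slab spans w−1 mm between
centers). For smooth convex anatomy, however, the extreme voxel centers of
a digitized body lie within a small fraction of a voxel of the true
surface, and adding a fixed +1 voxel to every span inflates each axis by
~1 mm — enough to push the ellipsoid-model volume ~4–5% above the voxel
volume for an exactly ellipsoidal object, where the two must agree
(π/6 · 2a · 2b · 2c = 4π/3 · abc). `obb_extents()` therefore defaults to
the uncompensated point-cloud span (what 3-D geometry toolkits report for
an oriented bounding box) and exposes `compensation_voxels` for slab-like
use cases. With the default, ellipsoid phantoms reproduce the π/6 identity
to within ~1.3% and axes to well under 1 mm.

*Frame handedness.* Eigenvectors have arbitrary sign. The first two axes
are flipped to a positive dot product with their dominant patient axis
(making reports reproducible); the third is their cross product, which
guarantees a right-handed frame. Extents use unsigned projections, so sign
conventions never affect measurements; the convention only matters for
serialized frames.

The ellipsoid model `ellipsoid_volume(length, width, thickness)` is exact
for ellipsoids and positively biased for bean shapes, because bending
enlarges the oriented bounding box while preserving volume. On typical
donor-cohort CE median axes (113.96, 66.28, 49.18 mm) it gives 194.5 mL
against a median measured volume near 140 mL — the overestimation that motivates
segmentation-based volumetry in the first place.

## Agreement statistics

- **DSC** $= 2|A \cap B| / (|A| + |B|)$. Two empty masks are defined to
  agree (DSC 1, flagged); one empty gives 0. These conventions make
  absent-kidney cases deterministic.
- **Percentage volume error** $= |V_{man} - V_{pred}|/V_{man} \times 100$;
  **absolute axis error** $= |x_{man} - x_{pred}|$.
- **ICC(3,1)** — single-rater, consistency, two-way mixed:
  $(MS_S - MS_E)/(MS_S + (k-1) MS_E)$ with the exact F-based 95% CI and
  p-value from $F = MS_S/MS_E$; bands poor/moderate/good/excellent at
  0.50/0.75/0.90. Consistency means a constant per-rater offset does not
  reduce the ICC — appropriate when systematic calibration differences
  between an automated and a manual reader should not count as
  disagreement.
- **Bland–Altman**: bias = mean(predicted − manual), limits of agreement
  bias ± 1.96 sd (sample sd). No multiple-testing correction is applied;
  p-values are reported raw.
- `evaluate_cohort()` assembles these into the standard report (DSC,
  MPVE, MAE per axis, ICC per parameter, Bland–Altman for volume);
  cohort means are unweighted means over kidneys. The DSC confidence
  interval is normal-theory (labeled as such in the output) — a bootstrap
  variant would be a reasonable alternative but the choice is
  inconsequential at the cohort sizes involved.

## The phantom generator and what it does (and does not) show

`phantom_spec()`/`make_mask()` rasterize ellipsoids, optionally bent into
beans by the quadratic shear $u_1 \mapsto u_1 - \beta u_3^2$. The shear
has unit Jacobian, so bean volume stays analytic (it equals the ellipsoid
volume); a 0.25 mm reference voxelization confirms this to <0.5% and
supplies the bean's local-frame extents. Semi-axes are given pre-rotation
along the patient axes (x = width, y = thickness, z = length).

`make_cohort()` draws two-kidney cases with length semi-axes 46–55 mm,
width 28–33 mm, thickness 21–25 mm (volumes ~113–190 mL, spanning the
interquartile range reported for healthy donors), rotations uniform ±25°
per axis, CE spacing 0.86 × 0.86 × 3 mm or NC 0.69 × 0.69 × 5 mm.
`make_ct()` paints kidney voxels at the protocol median density (171/28
HU), background at −50 HU (a fat/soft-tissue compromise; configurable),
with Gaussian noise of sd 10 HU — typical parenchymal noise for abdominal
CT. `perturb_mask()` simulates an imperfect second rater by adding a
smooth random field (correlation length ~12 mm) to the signed distance
function and rebinarizing; the amplitude is calibrated by bisection to a
target Dice (default 0.95) within ±0.02, and the result is kept a single
26-connected component.

One geometric subtlety: for the quadratic shear, the oriented bounding box
only widens once $2\beta c^2$ exceeds the width semi-axis $a$; below that
threshold the shape bends but its box — and hence the ellipsoid-model
estimate — is unchanged. Kidney-sized phantoms therefore show formula bias
only for $\beta \gtrsim 0.006$/mm, and the direction-of-bias battery uses
a slender bean family (semi-axes ~4–5 × 12–16 × 32–33 mm) for which the
whole bend range 0.005–0.015/mm is in the biased regime.

What passing phantoms shows: the geometry chain (PCA, OBB, labeling,
volumetry, resampling, agreement statistics) is correct to stated
tolerances, and the pipeline plumbing composes. What it does not show:
performance on real CT — phantoms have uniform parenchyma, no
perinephric structures of similar density, no renal sinus fat to exclude,
no pathology, and hard boundaries. Segmentation quality on real data is
the job of a trained model evaluated on clinical cohorts; this package's
claim is that once a segmentation exists, the numbers derived from it are
right.

## Problem sizes and determinism

The validation battery uses 50 rotated ellipsoid phantoms at 1 mm spacing
(≈120³ voxel lattices), 30 bean phantoms, 1000-table/1000-pair oracle
sweeps for ICC and DSC, and a 16-case two-kidney CE cohort run end-to-end
— sizes at which every stage's error is measurable while a full run
completes in minutes on one core. All stochastic stages (phantom draws,
CT noise, rater perturbation, augmentation) are seeded; identical seeds
reproduce bit-identical volumes, masks and reports.

## Known limitations

- The reference backend is an intensity model; it cannot separate
  touching isodense organs and is not a substitute for a trained
  segmenter on clinical data.
- Cortex/medulla sub-segmentation is out of scope.
- NRRD/MetaImage readers are not provided; NIfTI is the interchange
  format.
- `largest_component()` keeps exactly one component per kidney class;
  duplicated kidneys or severely fragmented masks need upstream handling.
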