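# renalmorph

Quantitative renal measurements from 3-D CT segmentations.

Kidney volume and the three renal axes — length (inferior–superior),
width (medial–lateral) and thickness (ventral–dorsal) — are routine
clinical descriptors used to assess renal function and donor eligibility.
`renalmorph` implements the full chain from a voxelwise kidney
segmentation to those numbers, plus the statistics used to compare
automated against manual measurements:

- **Volume I/O** — NIfTI read/write with a strict geometry contract
  (canonical RAS+ orientation, voxel-center affine, fixed label coding
  0/1/2 = background/right kidney/left kidney).
- **Preprocessing** — protocol windowing (CE 200/300 HU, NC 65/170 HU)
  with min-max normalization, isotropic trilinear resampling (NC images
  to 1.5 mm), one-hot encoding, and seeded training-time augmentation
  (patch extraction, flips, intensity shift, Gaussian noise).
- **Inference harness** — sliding-window prediction (96³ patches,
  overlap 0.5, uniform score averaging) around a pluggable per-patch
  predictor, argmax, per-kidney largest 26-connected component, and
  threshold-validated trilinear upsampling back to native resolution. A
  non-learned HU-model reference backend runs the pipeline end-to-end
  without network weights.
- **Morphometry** — voxel volumetry at native spacing; kidney axes from
  PCA of the 1 mm-resampled mask's point cloud, the minimal bounding box
  oriented along those axes, and anatomical axis labeling; the ellipsoid
  model `V = π/6 · L · W · T` (exact for ellipsoids, positively biased
  for bean shapes).
- **Evaluation** — Dice similarity coefficient, percentage volume error,
  absolute axis errors, ICC(3,1) (single-rater, consistency, two-way
  mixed, exact F confidence intervals, 0.50/0.75/0.90 interpretation
  bands), Bland–Altman limits of agreement, and a cohort report
  assembling all of them.
- **Phantoms** — a seeded generator of ellipsoid and bean kidney
  phantoms with analytic ground truth, CT-like intensity volumes, and
  rater perturbations calibrated to a target Dice: the test substrate for
  every other module.

## Worked example

Segment and measure a synthetic contrast-enhanced kidney:

```r
library(renalmorph)

spec <- phantom_spec("ellipsoid", semi_axes = c(30, 20, 50),
                     rotation = c(20, -10, 15), center = c(50, 0, 0),
                     side = "right")
mm  <- make_mask(spec, c(180, 100, 130))          # label map + truth
ct  <- make_ct(mm$mask, protocol = "ce", noise_sd = 10, seed = 7)
res <- run_pipeline(ct, run_config("ce"))
res$measurements
#>    side present volume_ml length_mm width_mm thickness_mm ellipsoid_volume_ml
#> 1 right    TRUE     127.8     100.3    60.38        40.33               127.9
#> 2  left   FALSE        NA        NA       NA           NA                  NA

dice(res$labels$data == 1, mm$mask$data == 1)
#> [1] 0.9907
```

The phantom's analytic truth is 125.66 mL with axes 100 × 60 × 40 mm: the
pipeline recovers the volume within ~2%, each axis within ~0.4 mm, and the
ellipsoid-model estimate agrees with the voxel volume because the shape
really is an ellipsoid. The absent left kidney is reported as absent, not
as zeros. On bean-shaped phantoms the ellipsoid model overestimates — the
direction of its well-known clinical bias. For the widely used CE median
axes 113.96 × 66.28 × 49.18 mm the formula gives

```r
ellipsoid_volume(113.96, 66.28, 49.18)
#> [1] 194.5011
```

well above the typical measured median volume near 140 mL.

A thin command-line front end (`inst/cli/renalmorph`) exposes `segment`,
`measure`, `evaluate` and `phantom` subcommands over the same functions.

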