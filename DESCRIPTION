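Package: renalmorph
Title: Renal CT Morphometry from Segmentation Masks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Toolkit for deriving quantitative renal measurements from
    3-D CT segmentations: intensity windowing and isotropic resampling,
    sliding-window patch inference with pluggable per-patch predictors,
    connected-component post-processing, PCA/oriented-bounding-box kidney
    axes (length, width, thickness), voxel and ellipsoid-model volumetry,
    and an agreement-statistics battery (Dice similarity coefficient,
    volume and axis errors, intraclass correlation, Bland-Altman).
    Includes a seeded synthetic kidney phantom generator with analytic
    ground truth for validating the full pipeline.
License: MIT
Encoding: UTF-8
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
NeedsCompilation: yes
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
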