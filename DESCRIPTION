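Package: aroiseg
Title: Semi-Automated Volumetric Lung Nodule Segmentation with Adaptive
    ROI Propagation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Two-stage semi-automated segmentation of pulmonary nodules in
    chest CT. From a single user-supplied square region of interest (ROI) on
    one axial slice, an adaptive-ROI algorithm propagates the ROI across
    slices -- recentering it on the previous prediction and resizing it so
    the nodule-to-ROI area ratio stays below a threshold -- to build an
    initial axial segmentation and extract a volume of interest (VOI). The
    VOI is then re-segmented patch-wise along the coronal and sagittal axes
    and the three masks are fused by voxel-majority consensus. Includes deep
    residual U-Net segmenters (built and trained in pure R with a dice
    loss), DICOM/NIfTI volume I/O with slice-thickness normalisation and
    window-level intensity scaling, Dice/sensitivity/PPV/Hausdorff
    evaluation, and a parametric nodule-phantom generator with exact ground
    truth for fully self-contained testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    EBImage,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
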