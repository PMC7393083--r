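# aroiseg

Semi-automated volumetric segmentation of pulmonary nodules in chest CT,
built around an **adaptive-ROI (A-ROI) slice-propagation algorithm** and
**multi-view residual U-Net fusion**.

Accurate nodule volumetry matters for lung-cancer screening: malignancy risk
is assessed from a nodule's size and growth, which requires a reliable 3-D
segmentation. Fully manual contouring is slow; fully automatic methods need a
radiologist-drawn 3-D volume of interest (VOI) or use one fixed 2-D window
for every slice, which either demands extra interaction or drags non-nodule
structures into the model's input. `aroiseg` implements a middle road: the
user draws **one square 2-D region of interest (ROI) on one axial slice**,
and the package does the rest.

## Method

**Stage I — adaptive-ROI axial propagation.** The seed ROI is segmented by a
2-D segmenter; the prediction then steers two independent sweeps towards
higher and lower slices. Before each step the ROI is

* *recentred*: with mask margins D_L, D_R, D_T, D_B inside the ROI, the
  window shifts by `round((D_L - D_R)/2)` in x (and analogously in y), so it
  stays concentric with the nodule as it drifts between slices;
* *resized*: the ROI stays square with side `ceil(sqrt(A_N / R_T))`, which
  keeps the nodule-to-ROI area ratio bounded, `A_N / A_ROI <= R_T`. The
  threshold `R_T` (default **0.6**) controls how much context the model
  sees; smaller values give looser windows.

A sweep stops at the first empty prediction (configurable), i.e. immediately
after the nodule ends. The union of per-slice masks defines the VOI.

**Stage II — multi-view segmentation and consensus.** The VOI is re-sliced
along the coronal and sagittal axes; each patch is resized to 128x64 (the
in-plane axis maps to 128, the coarser z axis to 64), segmented, and mapped
back. The axial, coronal and sagittal masks are fused by voxel majority:
voxel k enters the final mask iff its vote count g satisfies
`g >= M * C_R`, with `M = 3` sources and consensus ratio `C_R = 0.5` — a
2-of-3 rule. The same operator with four sources implements the 2-of-4
"50% consensus" used to build reference masks from four raters' annotations.

**Segmenters.** Any function mapping a 2-D patch to a same-shaped binary
mask can drive the pipeline (the "segmenter contract"). The package ships

* deep residual U-Nets built and trained in pure R (BLAS-backed
  convolutions): a 9-level, 19-convolution network at 128x128x1 with a
  1024-channel bridge at 8x8 for the axial view, and a 7-level,
  15-convolution network at 128x64x1 with a 512-channel bridge at 16x8 for
  the coronal/sagittal views, trained with the soft dice loss
  `1 - 2|p.t| / (|p| + |t|)` under SGD;
* a ground-truth **oracle segmenter** (optionally corrupted by seeded
  erosion/dilation or pixel flips) that isolates the geometric pipeline from
  learning in tests and sensitivity studies.

Pre- and post-processing follow standard CT practice: DICOM series / NIfTI
input, slice thickness normalised to the in-plane pixel spacing (linear in
z for intensities, nearest-neighbour for masks), window-level intensity
scaling `(I - Min)/(Max - Min)` with clipping to `[Min, Max]`,
`Min/Max = WC -+ WW/2`. Evaluation: Dice coefficient, sensitivity, positive
predictive value, and the symmetric Hausdorff distance in millimetres.

## Worked example

```r
library(aroiseg)

# a lobulated nodule phantom on an anisotropic CT grid, with ground truth
ph <- generate_phantom(phantom_spec(seed = 3, lobulation = 0))
ph$volume
#> <ct_volume> 24 x 96 x 96 voxels (z,y,x), spacing 2.5 x 0.66 x 0.66 mm
#>   window: WC -600, WW 1500
#>   intensity range: [-821.7, -149.7]

# preprocess: isotropic z, intensities in [0, 1]
vol   <- normalize_intensity(resample_z_to_pixel_spacing(ph$volume))
truth <- resample_z_mask(ph$mask)

# seed ROI on the nodule's middle slice, oracle segmenter standing in for
# a trained model
seed <- square_roi(slice = 43, x1 = 33, y1 = 33, side = 30)
res <- segment_nodule(vol, seed, oracle_segmenter(truth),
                      pipeline_config(preprocess = FALSE), reference = truth)
res
#> <nodule_segmentation> status: ok
#> <voi_box> z [31,57), y [31,65), x [31,65)
#>   final mask: 11768 voxels (3.38e+03 mm^3)
#>   axial     DSC 1.0000
#>   coronal   DSC 1.0000
#>   sagittal  DSC 1.0000
#>   consensus DSC 1.0000
```

The per-stage DSC values compare each view's mask (and the fused result)
against the reference; with the exact oracle the pipeline's geometry loses
nothing, so all four are 1. With a noisy oracle (one-voxel erosions and
dilations at rate 0.3) the three views degrade to mean DSC ~0.96 while the
consensus recovers to ~0.99 — the fusion's purpose. Training a scaled-down
residual U-Net on 200 synthetic blob patches reaches held-out DSC ~0.98
within a few epochs (see the tests).

A thin CLI over these functions is installed at `inst/cli/aroiseg.R`
(subcommands `simulate`, `segment`, `evaluate`, `consensus`, `rt-sweep`,
`train`).

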