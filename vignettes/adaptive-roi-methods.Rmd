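---
title: "Adaptive-ROI nodule segmentation: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive-ROI nodule segmentation: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(aroiseg)
```

This vignette is the package's own account of the method it implements: the
two-stage segmentation procedure, the parameters that matter and their
defaults, what the synthetic data emulates (and does not), and the numerical
and design choices made where the procedure's description left room.

## The procedure

The pipeline turns a single user-drawn square ROI on one axial CT slice into
a volumetric nodule segmentation in two stages.

**Stage I.** The seed ROI is segmented by a 2-D segmenter. Its prediction
steers two independent slice sweeps (up and down the z axis). At each step
the previous slice's prediction is used twice:

1. *Recentre.* With margins $D_L, D_R, D_T, D_B$ between the predicted mask
   and the ROI edges, the window translates by
   $\mathrm{round}\!\big((D_L - D_R)/2\big)$ in $x$ and
   $\mathrm{round}\!\big((D_T - D_B)/2\big)$ in $y$. After this the margins
   differ by at most one voxel per axis — the ROI tracks the nodule's
   in-plane drift between slices.
2. *Resize.* The window stays square with side
   $\lceil\sqrt{A_N / R_T}\rceil$, where $A_N$ is the predicted nodule
   area, enforcing $A_N / A_{ROI} \le R_T$ whenever image bounds and the
   minimum side do not interfere.

The sweep ends at the volume boundary or after `stop_on_empty` consecutive
empty predictions. The union of the per-slice masks is the axial estimate,
whose padded bounding box is the VOI.

**Stage II.** The VOI is re-sliced along the coronal and sagittal axes. Each
patch is resized to $128 \times 64$ — in-plane axis to 128, z axis to 64,
reflecting that z is the coarser axis before slice-thickness normalisation —
segmented, resized back (nearest-neighbour, to stay binary), and
re-stacked. The final mask is the voxel-majority consensus of the axial,
coronal and sagittal masks: voxel $k$ is kept iff its vote count satisfies
$g_k \ge M \cdot C_R$ with $M = 3$, $C_R = 0.5$. The inclusive inequality
makes the same operator a 2-of-4 rule for four-rater reference masks.

## Parameters

| parameter | default | units | role |
|---|---|---|---|
| `ratio_threshold` ($R_T$) | 0.6 | — | upper bound on nodule/ROI area; smaller = looser window. Should scale inversely with slice thickness, since thicker slices allow larger inter-slice drift. |
| `resize_mode` | `"always"` | — | whether the ROI may also shrink (see below) |
| `min_side` | 8 | voxels | floor on the ROI side; prevents tiny windows being upscaled to the network resolution, where interpolation destroys the boundary |
| `stop_on_empty` | 1 | slices | consecutive empty predictions ending a sweep |
| `voi_pad` | 2 | voxels | VOI margin around the stage-I bounding box |
| `consensus_ratio` ($C_R$) | 0.5 | — | minimum vote fraction for the fused mask |
| `binarize_threshold` | 0.5 | — | sigmoid cut for model segmenters |
| learning rate / batch / epochs | 1e-4 / 8 / 700 | — | reference training protocol for the full-size networks (SGD, dice loss) |

The shipped network specifications are fixed by construction: the axial
network has 9 levels and 19 main-path convolutions at $128\times128\times1$
with a $8\times8\times1024$ bridge; the coronal/sagittal network 7 levels
and 15 convolutions at $128\times64\times1$ with a $16\times8\times512$
bridge. `resunet_audit()` walks a real forward pass and reproduces these
tables row by row; the acceptance suite asserts exact equality.

## Synthetic data: what it does and does not show

`generate_phantom()` emulates the features of thoracic CT that exercise the
pipeline's geometry: anisotropic grids (default 2.5 mm slices over 0.66 mm
pixels), blob-like nodules spanning several slices with adjustable size,
lobulation (a smooth low-order angular perturbation of an ellipsoid's
radius) and contrast, optional attached tubes (the juxta-vascular case),
in-plane smoothing and additive Gaussian noise — with exact ground truth.
`make_blob_patches()` provides the analogous 2-D training data.

Phantoms are *not* a physical CT simulation: no reconstruction physics, no
textured parenchyma, no fuzzy infiltrative boundaries, no neighbouring
structures that mimic nodule intensity. Tests passing on phantoms therefore
validate the geometric algorithm, the fusion rule, the metrics and the
learning machinery — they do not certify clinical-grade accuracy on real
scans, which depends on training data the package deliberately does not
ship. The sensitivity sweep (`rt_sweep()`) likewise reproduces the *shape*
of the threshold-performance relationship on phantoms, not its values on
clinical data.

Study sizes used in the shipped tests (chosen to keep a laptop-class run
comfortable while leaving the conclusions stable): 500 randomized slice
sequences for the ROI invariants, 20 phantoms for end-to-end recovery, 200
blob patches (160/40 split) with a `c(8, 16, 32)`-filter network for the
training check, 100 random mask pairs against the brute-force metric
oracles.

## Numerical and design choices

* **Ratio inequality direction.** The enforced invariant is
  $A_N / A_{ROI} \le R_T$: the ROI is enlarged when the ratio *exceeds* the
  threshold, and the threshold bounds the nodule's share of the window.
* **Shrinking ROIs.** The enlargement trigger alone would never shrink a
  window, yet a window fitted to the nodule's widest slice is far too loose
  near its tips, exactly where segmentation is hardest. Default
  `resize_mode = "always"` therefore tracks
  $\lceil\sqrt{A_N/R_T}\rceil$ in both directions; `"grow_only"` restores
  the literal enlarge-only behaviour.
* **Recentre before resize.** The two updates commute only approximately;
  the order recentre → resize is fixed so the resize expands around the
  already-centred window.
* **Rounding.** Translation shifts round half away from zero; sides round
  up (`ceiling`); when a resize changes parity, the extra voxel goes to the
  high-index side. Clamping at image borders translates the window rather
  than shrinking it, so squareness survives.
* **Windowing.** Intensities are clipped to $[WC - WW/2,\, WC + WW/2]$
  before the affine map — without clipping the output would leave $[0,1]$.
  Missing window tags fall back to a lung window (WC $-600$, WW $1500$),
  logged.
* **Interpolation.** Intensities: linear along z (slice-thickness
  normalisation) and bilinear in-plane (patch resizing). Masks: always
  nearest-neighbour, preserving binarity. Whether reference masks should
  instead be re-derived on the resampled grid is not determined by the
  procedure's description; nearest-neighbour resampling is used and flagged
  here.
* **Dice denominators.** Both the loss and the evaluation metric use
  $|P| + |T|$ in the denominator (not the union), keeping the coefficient
  in $[0,1]$ with value 1 at identity. The loss adds $\varepsilon = 10^{-7}$
  against 0/0 on empty masks. Conventions for degenerate metric inputs:
  both masks empty gives DSC = SEN = PPV = 1 (perfect agreement on
  absence); the Hausdorff distance is reported as missing (`NA`), never 0,
  when a mask is empty.
* **Hausdorff point sets.** Distances are defined over all foreground voxel
  centres (scaled to mm), not extracted surfaces. The implementation
  reduces both sets exactly — points of $A$ inside $B$ contribute 0, and
  nearest points of $B$ lie on its 6-connected surface — and is tested for
  equality against a literal double loop.
* **Residual units.** Pre-activation order (BN → ReLU → conv) with two
  $3\times3$ blocks per unit; downsampling by stride 2 on the unit's first
  convolution; decoder units preceded by nearest-neighbour 2x upsampling
  and concatenation with the matching encoder map. Where a unit changes
  shape, the identity path is a stride-matched $1\times1$ projection —
  standard residual practice; these projections sit on the shortcut and are
  not counted among the main-path convolutions. The binarisation threshold
  (0.5), He initialisation and BN momentum (0.1) are defaults the
  procedure's description does not pin down; all are configurable.
* **Training engine.** No deep-learning framework is attached: the networks
  are small and fully specified, so the package carries a compact
  convolution engine (forward and hand-derived backward passes over
  BLAS-backed matrix products) with plain SGD plus optional momentum.
  Gradients are verified against numerical differentiation in the tests.
  Training is bit-reproducible for a fixed seed.
* **Seed ROI.** Used exactly as drawn for the first segmentation — it is
  the user's statement of where the nodule is, and is not recentred first.
* **Non-nodule training ROIs** are placed at the nearest nodule slice's
  tight window, at z offsets just beyond both ends of the nodule, teaching
  a model to emit empty masks where the sweep should stop. The margin
  sampler's "maximum diameter" is read as the in-slice bounding-box long
  side.
* **Consensus sources.** The fusion takes the stage-I axial mask cropped to
  the VOI (not a re-segmentation of axial VOI slices), plus the two stage-II
  view masks.

## Limitations

* Propagation assumes one nodule per seed; attached structures of similar
  intensity can drag the window (mitigated but not solved by `min_side`
  and the ratio bound — the known failure mode of juxta-vascular and
  ground-glass nodules).
* Nodules whose axial footprint is tiny relative to the network resolution
  suffer from the upscaling distortion; the configuration hook for
  alternative rescaling resolutions exists (`axial_target`/`side_target`),
  but no multi-resolution model bank ships.
* The pure-R training engine is appropriate for the scaled-down networks
  used in tests and experimentation; training the full-size networks on a
  clinical corpus calls for a GPU framework, for which the architecture
  specification and checkpoints-as-RDS interface are the exchange points.
* Pipeline determinism holds exactly on oracle paths; trained-model paths
  are deterministic given fixed weights, but weights depend on the training
  seed and BLAS reduction order only to float tolerance.
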