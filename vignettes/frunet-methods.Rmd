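---
title: "Synthesizing 7T-like brain MRI from 3T: model, losses, and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Synthesizing 7T-like brain MRI from 3T: model, losses, and evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Paired 3T/7T T1-weighted datasets are tiny — typically around ten subjects —
because 7T scanners are rare. `frunet` treats 3T→7T synthesis as volumetric
image-to-image translation under small-data constraints: a patch-based 3D
network keeps memory bounded and multiplies the effective sample count
(a whole-head 256×304×308 volume yields 567 overlapping 64³ patches at
stride 32), while unpaired 7T volumes can be folded in through a
semi-supervised consistency objective. Because conventional similarity
metrics say little about anatomy, the package pairs the synthesizer with
segmentation-derived fidelity metrics computed from multi-class label
volumes.

## Data model and conventions

Volumes are 3D arrays in a canonical (sagittal, coronal, transverse) axis
order with voxel spacing in mm; NIfTI files in other orientations are
reoriented at load and the original orientation recorded in the volume's
metadata. Intensities are min-max normalized **per volume** to [0, 1] before
patch extraction — patches inherit the volume's scale, preserving
within-subject intensity relationships. Unpaired 7T volumes are normalized
by the same per-volume rule (an assumption; nothing in the pipeline depends
on it beyond keeping all network inputs on one scale). Voxel coordinates are
0-based and patch intervals half-open.

Patch starts along an axis are `0, s, 2s, …` while they fit, plus one final
end-aligned start when the last regular patch stops short of the boundary.
This is the unique simple policy consistent with 567 = 7×9×9 patches on a
256×304×308 volume at 64/32; the tail patch simply overlaps its neighbour
more. At reassembly each voxel is the arithmetic mean of all patches
covering it, which makes reassembly an exact inverse of extraction and
independent of patch order. Blending is behind a config enum so tapered
windows could be added without contract changes.

## Architecture

`build_model()` constructs the FR-U-Net: four levels, channel widths
doubling from `base_channels` (32 at full scale; tests use 4 or 2 with the
same topology). Encoder levels apply two 3×3×3 convolutions, each followed
by PReLU and layer normalization, then 2×2×2 max pooling. Decoder stages
upsample by a kernel-2/stride-2 transposed convolution, concatenate the
matching encoder skip, refine with a residual block and a multi-scale fusion
block (1³/3³/5³ branches, concatenation, 1×1×1 reduction), and a 1×1×1
convolution + sigmoid produces the output, so predictions always lie in
(0, 1).

Choices the published description leaves open, resolved here once:

* **Convolutions per encoder level**: 2, the U-Net convention.
* **Normalization placement**: convolution → PReLU → layer normalization,
  applied after every convolution. Layer normalization is per sample over
  all channels and voxels with a per-channel affine, so there is no
  cross-sample state and batched inference equals per-sample inference
  bitwise.
* **Residual block with width change**: a 1×1×1 projection on the skip path.
* **Fusion widths**: each branch outputs the stage width; the 3×width
  concatenation is reduced back by a 1×1×1 convolution.
* **Initialization**: fan-in-scaled Gaussian under an explicit seed; PReLU
  slopes start at 0.25. Identical seeds give identical models.
* **Transposed-convolution kernel**: 2×2×2 (stride 2), the non-overlapping
  choice, so upsampling introduces no checkerboard coupling.

`use_residual`/`use_msf` toggles expose the ablation variants without
separate model classes.

## Objectives

With λ the hybrid SSIM weight (default 0.7):

* `mse_loss` — mean squared voxel difference over the batch.
* `ssim` — the standard structural-similarity form with stabilizers
  C1 = (k1·L)², C2 = (k2·L)², using the universal defaults k1 = 0.01,
  k2 = 0.03 and data range L = 1 for normalized volumes. Two window
  policies: `global` (one moment set per sample; admits closed-form tests)
  and `local` (default; uniform 7³ window, mean of the local SSIM map).
  Local windows are edge-truncated — border windows average only in-bounds
  voxels — and moments are population moments. A 2D 7×7 version of the same
  code scores image slices.
* `hybrid_loss = MSE + λ·(1 − mean SSIM)` for paired patches.
* `consistency_loss = mean|x−f(x)| + α·(1 − mean SSIM(x, f(x)))` for
  unpaired 7T patches; the L1 term is the voxelwise *mean*, keeping the two
  objectives on one scale.
* `total_loss = supervised + λ_semi · consistency`.

α and λ_semi have no published reference values; they default to 0.7
(mirroring λ) and 1.0, are mandatory fields of `loss_weights()`, and are
recorded in every run manifest. All losses vanish exactly at their identity
fixed points, which the test suite asserts alongside finite-difference
gradient checks of every operator.

## Training

Reference full-scale settings (kept as `train_config()` defaults): Adam at
learning rate 2×10⁻⁵, batch size 8, up to 100 epochs, early-stopping
patience 10. The validation split for early stopping is not defined by the
reference protocol inside the nine training subjects; here a seeded 10% of
the training patches is held out, the monitored quantity is the supervised
hybrid loss only (also in semi-supervised runs), improvement is strict
(min-delta 0), and the best-validation weights are returned. Semi-supervised
steps draw one paired and one unpaired batch (1:1), so steps per epoch are
`min(⌊paired/batch⌋, ⌊unpaired/batch⌋)`. Paired and unpaired shuffles come
from independent pre-generated seeded streams, which makes the λ_semi = 0
trajectory bitwise identical to supervised training — a property the
acceptance suite checks.

Leave-one-subject-out folds (`make_folds`) are deterministic in input
order; each subject is the test volume exactly once.

## The phantom generators

`make_phantom_7t` builds a geometric stand-in for a T1w head: an ellipsoid
with nested intensity shells (dark CSF-like rim 0.25, grey-matter band
0.55, bright white-matter core 0.85 on the [0,1] scale), a mild linear
intensity gradient as a bias-field stand-in, and seeded sinusoidal texture
(default 0.15 cycles/voxel, amplitude 0.08) inside the brain standing in
for the fine detail that distinguishes ultra-high-field scans.
`degrade_to_3t` produces the paired "3T": Gaussian blur (1.2 mm), gamma
contrast compression (0.7), additive Gaussian noise (sd 0.05), clipped to
[0, 1]. These defaults were chosen once as a visible-but-learnable
degradation — strong enough that every metric separates the pair (phantom
SSIM(3T, 7T) ≈ 0.3), smooth enough that a small network can invert it.
Everything is bitwise reproducible from the seeds recorded in the dataset
manifest.

What the phantoms deliberately are **not**: anatomically realistic. There is
no MRI physics (no B0/B1 inhomogeneity, no sequence signal equations), no
inter-subject anatomical variability beyond the seeded texture, and the
3T↔7T relationship is a known smooth forward model rather than a contrast
mechanism. Passing tests on phantoms therefore demonstrates that the
machinery — patching, optimization, metrics, bookkeeping — is correct and
that the network can learn a deblurring/denoising contrast map; it does not
certify synthesis quality on real brains.

Label phantoms (`make_label_phantom`) provide nested CSF/GM/WM shells plus
two left/right sphere pairs: a "hippocampus-like" pair with a configurable
volumetric asymmetry (default +15% right) and a symmetric "thalamus-like"
pair. Exact voxel counts are recorded in a generation ledger, so volumetry,
Dice, HD95, and asymmetry recovery can be asserted exactly.

## Evaluation metrics

Image quality is reported per slice orientation (axis 1 sagittal, axis 2
coronal, axis 3 transverse), as mean ± sd over 2D slices: PSNR
(`10·log10(M²/MSE)` with M the maximum over both images, literally; a
fixed-range mode is available for comparability), NMSE
(`Σ(f−y)²/Σy²`), and slice-wise SSIM. Slices where a metric is undefined —
identical slices for PSNR, all-zero ground truth for NMSE — are excluded
and counted rather than scored 0. Method comparisons use classical paired
t-tests on slice-wise values.

Segmentation consistency operates on co-registered integer label volumes.
HD95 uses boundary voxels (6-connectivity erosion difference) scaled to mm
by the voxel spacing; the robust distance is the maximum of the two
directed 95th percentiles. Labels present in only one volume score Dice 0
with a flag instead of being dropped, keeping family means honest. Two
empty masks give NA, not 1. Volumetry converts voxel counts to cm³ and
percentages of the intracranial cavity; percent differences between field
strengths default to the form `100·(7T−3T)/3T`, the form consistent with
published comparison tables (the alternative denominator is available
behind a flag). The asymmetry index has no standard published formula, so
the default `100·(R−L)/((L+R)/2)` is labelled on every output.

## Numerical engine and problem sizes

No deep-learning framework is involved: the network is differentiated by a
small reverse-mode tape in R whose heavy operators (3D convolution via
im2col + BLAS GEMM, transposed convolution, pooling, box filtering) are
RcppArmadillo kernels, all finite-difference-checked. Double precision
throughout; determinism comes from seeded R RNG streams and single-threaded
deterministic kernels.

The shipped tests and the acceptance script use desk-scale problem sizes
chosen so the full pipeline exercises every contract on one CPU: phantom
subjects of 96×112×112 voxels, 32³ patches at stride 16, a width-4 FR-U-Net,
batch 2, 200 optimizer steps with learning rate 10⁻³ (appropriate for a
200-step budget; the 2×10⁻⁵ default belongs to full-scale 100-epoch runs).
Under these conditions the validation hybrid loss falls by roughly 74% and
held-out-subject SSIM against the 7T phantom rises from ≈0.30 (3T input) to
≈0.77 (synthesis) — the quantities `scripts/acceptance.R` recomputes.

## Known limitations

* Training at full scale (64³ patches, width 32, batch 8) is far beyond a
  single-CPU R session; the implementation is faithful but intended for
  reduced-scale experimentation and method evaluation.
* Registration, bias-field correction, and skull stripping are out of
  scope; inputs are assumed co-registered (the pipeline performs none).
* The segmentation network itself is not included — the package consumes
  label volumes produced elsewhere plus a user-supplied region table.
* Published cross-field volumetric comparison tables round their inputs;
  asymmetry percent errors recomputed from 4-decimal indices can differ
  from printed values in the third decimal, which the tests acknowledge by
  asserting those cells at the precision the rounded inputs support.
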