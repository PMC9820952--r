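---
title: "Methods: deep-supervised residual U-block segmentation of the masseter muscle"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: deep-supervised residual U-block segmentation of the masseter muscle}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

The masseter muscle (MM) is a bilateral masticatory muscle whose volume and
shape matter for orthodontic and orthognathic planning. Cone-beam CT (CBCT)
is the routine dental 3D modality, but its soft-tissue contrast is poor: the
Hounsfield-unit (HU) distribution of the muscle overlaps heavily with its
surroundings and is far noisier than in conventional CT, which makes manual
delineation slow and observer-dependent. `masseg` implements an automatic
3D segmentation pipeline for this setting — one model that segments the left
and right masseter on both CBCT and CT — together with the evaluation and
agreement statistics used to judge such a model, and a synthetic paired
CBCT/CT phantom generator so every stage can be exercised and tested without
clinical data.

Classes are coded 0 = background, 1 = left MM, 2 = right MM. All volumes are
canonicalised to the RAS frame on read; "left" is the structure on the
subject's anatomical left (+x). Because left and right are distinct classes,
no mirroring is used anywhere in the pipeline (in particular, augmentation
never reflects).

## Network

The model is a two-level U-shape: a four-stage encoder–decoder whose
building blocks are themselves small U-shaped networks, the residual U-block
(RSU). An RSU of depth $d$ applies an input transform (3×3×3 convolution,
instance normalisation, LeakyReLU), then a nested encoder–decoder over $d$
2×-pooled scales with a dilation-2 bottom convolution, and adds the input
transform residually to the nested branch's output; a dilated variant
replaces pooling with growing dilation (1, 2, 4, …) for grids too small to
pool. Stage resolution halves after every encoder stage and doubles before
every decoder stage; decoder stages consume the concatenation of the
upsampled deeper features and the same-scale encoder features.

Deep supervision: a 1-voxel convolution head produces raw class scores at
every decoder scale; a fused head combines all upsampled side outputs into
the full-resolution prediction. The loss is applied at every scale against
a nearest-neighbour down-sampled ground truth (nearest-neighbour selection
preserves the label alphabet), each scale with weight 1, plus the fused
output.

Choices the architecture leaves open, and what this package uses:

- normalisation: instance norm (batch size is 2, so batch statistics would
  be unreliable);
- LeakyReLU negative slope 0.01;
- down-sampling by 2×2×2 max pooling, up-sampling by trilinear
  interpolation (half-pixel centre alignment);
- default widths 16/32/64/128 with RSU depths 5/4/3/2 and a dilated deepest
  stage; mid (internal) channels are half the stage width, minimum 4.

## Training

The objective is an equally weighted sum of soft Dice loss (over foreground
classes, $\varepsilon = 10^{-5}$) and cross-entropy, optimised by momentum
SGD (momentum 0.9, no weight decay). The reference schedule is 20,000
iterations at batch 2: learning rate rising linearly from 0 to 0.001 over
the first 300 iterations, then decaying to 0 along a cosine. `lr_at()` is
that schedule in closed form: continuous, maximal exactly at the end of the
warm-up, `base_lr/2` at the midpoint of the decay span.

Training samples are patches (default 48³) cut from the preprocessed
volumes; half of the patches are centred on a muscle voxel so foreground is
never starved. Each patch is augmented by one random rigid-plus-zoom
transform — rotations up to ±15° per axis and an isotropic resize in
[0.85, 1.15], trilinear for intensities and nearest-neighbour for labels.
The linear part of every sampled transform has positive determinant:
reflections are structurally impossible, preserving left/right chirality.
CBCT and CT renderings of the same cases are mixed in one batch stream —
after clipping and normalisation their muscle intensity distributions
overlap, which is the premise for training a single cross-modality model.

A run is bitwise reproducible from (cases, configurations, seed): all
randomness flows from one seed, and the compiled kernels are deterministic.

## Preprocessing

Intensities are clipped to [−325, 400] HU — the 0.5/99.5 % quantiles of the
foreground voxels of the training corpus, the nnU-Net-style rule; the
quantile computation itself (`foreground_quantile_bounds()`, linear
interpolation between order statistics) is exposed so the bounds can be
recomputed on a new dataset, while the fixed window is the default
(`preprocess_config()`). After clipping, volumes are z-scored by the pooled
foreground mean/SD. For mixed-modality training at different native
resolutions (CBCT 0.3 mm isotropic, CT 0.4×0.4×1 mm) both modalities are
resampled to a common grid, 0.5 mm isotropic by default.

## Inference

Sliding-window prediction with 50 % overlap; per-voxel class probabilities
(softmax of the fused head) are averaged uniformly over windows, and the
label is the argmax with ties broken towards the lower class index. The
output grid equals the input grid. Optional post-processing
(`largest_components_filter()`, 26-connectivity) is off by default: the
evaluation convention scores raw model output.

## Evaluation metrics

- DSC per class; the "Mean" DSC is the unweighted mean over {background,
  left, right}. With a single foreground structure this reduces to the
  classic two-class form (DSC_Seg + DSC_Back)/2; with both structures the
  three-class mean is the operative definition (it reproduces the Mean
  columns of the clinical tables this convention was taken from). Both-empty
  structures score 1, exactly-one-empty scores 0.
- Average Hausdorff distance (aHD): the directed aHD from A to M is the mean
  distance from each voxel of A to the nearest voxel of M, in physical mm;
  the reported value is symmetrised (mean of the two directions) with the
  directed values exposed, and the per-case "Mean" aHD is the side mean
  (left + right)/2. Implemented with an exact Euclidean distance transform
  (anisotropic spacing enters as per-axis weights), verified against a
  brute-force oracle; aHD is undefined (an error) for empty structures.
- Revision fraction: per structure, 100 × |voxels labelled c in exactly one
  of original/revised| / |revised = c|, averaged over the two sides; if the
  revised structure is empty but the original is not, the denominator falls
  back to the original and the value is flagged.
- Aggregates are mean, SD and the t-based 95 % CI of the mean. The side-mean
  aHD aggregates as the mean over cases of the per-case side mean, which
  equals the mean of the two per-side means.

## Agreement statistics

`bland_altman()` reports the mean difference, SD (n−1), limits of agreement
mean ± 1.96 SD, and the fraction of pairs outside the limits;
`paired_t()` is the exact paired t-test (two-sided p from the t distribution
with n−1 df). The 1.96 multiplier is used for the limits because the
published agreement intervals for this model family reproduce mean ± 1.96 SD
for the internally consistent rows. The t-based CI is reserved for CIs of
means (`summarize_series()`).

## Synthetic paired phantoms

`phantom_spec()`/`generate_case()` emulate the geometry of the clinical
problem: two mirrored muscle-like ellipsoids (default semi-axes 4×6×10 mm)
whose transverse girth tapers towards the superior tip — the region where
automatic masseter segmentations are known to under-segment — beside a
central bone plate, in a fat-like background with an air rim. The same
geometry is rendered as a pseudo-CT and a pseudo-CBCT: identical
per-compartment mean HU (muscle 60, fat −100, bone 900, air −1000) but
larger noise SDs in the CBCT rendering (muscle 60 HU vs 15 HU in CT); a
Gaussian PSF (FWHM 1.2 mm) smooths both anatomy and noise, with the noise
rescaled so its marginal SD matches the configured value. Only the ordering
(CBCT variance > CT variance, similar centres) is anchored in published
observations; the magnitudes are configuration. Per-side jitter (0.5 mm SD)
breaks exact mirror symmetry unless disabled.

What the phantoms do *not* model: CBCT scatter, beam hardening, metal
artifacts, anatomical texture, inter-subject anatomy, or registration error
(cases are generated pre-aligned, standing in for the clinical CBCT-to-CT
superimposition step, which is out of scope). Passing the end-to-end test
therefore shows the pipeline is implemented correctly and can learn a
cross-modality segmentation under controlled noise — not that it reaches
clinical accuracy on patients.

`simulate_observer()` warps the truth by a smooth random displacement field
(unit-RMS Gaussian field scaled to a magnitude in mm) so interobserver-style
paired statistics have inputs; DSC against truth decreases monotonically in
the magnitude.

## Desk-scale experiment

The package's self-contained accuracy experiment (run by
`scripts/acceptance.R` and the acceptance test): 12 phantom cases on a 64³
grid at 0.5 mm (protocol seed 7), 8 train / 4 test; a tiny four-stage
network (channels 8/16/32/64, mid 4/8/16/32, RSU depths 1/1/1/1, dilated
bottleneck) trained for 500 iterations at batch 2 on mixed CBCT/CT 48³
patches; sliding-window prediction on the held-out cases of both
modalities. At this scale the reference learning rate (0.001 over 20,000
iterations) is far too conservative; the desk-scale schedule keeps the same
shape with base_lr 0.01 and warm-up 50. Problem sizes were chosen so the
whole experiment runs in minutes on one CPU core.

## Numerical notes

- Convolutions run in single precision (padded channel-major layout; taps
  as pointer-offset GEMMs or register-blocked direct kernels); parameters,
  gradients and everything outside the convolution operands stay double.
  Gradient correctness is established per operator (exact adjoint
  identities for the linear ops, finite differences for norm/activation and
  losses) plus a whole-network directional-derivative check whose tolerance
  reflects the single-precision forward arithmetic.
- Quantiles use linear interpolation between order statistics (R type 7).
- Odd grid sizes inside RSUs pool with ceiling semantics and upsample back
  to the recorded encoder dims, so any input divisible by
  `2^(num_stages−1)` is valid.
- Degenerate inputs: empty structures (DSC conventions above, aHD errors),
  zero-variance paired differences (`paired_t()` errors, `bland_altman()`
  reports NA for t), single-case aggregates are flagged rather than given
  an SD.
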