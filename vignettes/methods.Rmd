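---
title: "Adversarial 3D dose prediction: model, losses and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adversarial 3D dose prediction: model, losses and evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fusedose)
```

## The problem

Volumetric modulated arc therapy (VMAT) planning for pelvic tumours is an
iterative optimization that takes experienced physicists hours per patient.
Because plans for a given site and prescription are highly stereotyped, the
3D dose distribution can be predicted voxel-by-voxel from the CT image and
the delineated target: that prediction then serves as a planning aid, a
quality-assurance reference, or the starting point of automated planning.

`fusedose` implements such a predictor as a conditional generative
adversarial network (cGAN). A generator maps a multichannel conditioning
volume X (CT, target and organ masks) to a dose map G(X); a fully
convolutional patch discriminator D receives the conditioning stack
concatenated with either the clinical dose (label 1) or the generated dose
(label 0) and emits a 3D map of patch logits. Training alternates the two.

## Conditioning schemes

Three input compositions are supported, mirroring the question of how much
delineation effort the model needs:

* **Scheme A** (8 channels): dose, CT, PTV, body, femur-head-R,
  femur-head-L, rectum, bladder;
* **Scheme B** (3 channels): dose, CT, PTV — no organ-at-risk contours;
* **Scheme C** (2 channels): dose, CT only.

The dose channel exists only during training; at inference the generator
receives 7 / 2 / 1 channels respectively.

## Preprocessing

CT is truncated to [-600, 1000] HU (air cut-off to bone, the informative
pelvic window). Each structure mask is label-encoded onto the same scale:
background -600, body -400, femur-head-R -200, femur-head-L 200, rectum
600, bladder 800, PTV 1000. Volumes are resampled to isotropic 3.5 mm
voxels (trilinear for CT/dose, nearest-neighbour for masks, half-pixel
centre convention) and cropped/padded to 128^3 about the body centroid
(PTV centroid as fallback; pad value -600 for CT/labels, 0 for dose). All
channels are mapped affinely onto [-1, 1]: CT and labels from
[-600, 1000]; dose from [0, 1.2 x prescription], a range chosen so that
every clinically plausible maximum (<= 1.17 x Rx in this setting) is
representable with headroom under the generator's tanh output. Stored dose
grids that come as integers with a dose-grid scale factor are converted to
cGy by multiplication.

The axis convention is fixed as (transverse slice, row, column); the
adjacent-voxel-difference loss and the augmentation rotations refer to it.

## Generator: full-scale feature fusion

The generator is an encoder-decoder over five spatial scales in which
*every* decoder step sees features from *all* scales (UNet3+-style
full-scale skip connections), rather than only its mirror encoder level:

* a stem of three 3^3 convolutions producing 32 feature maps at full
  resolution (three small kernels rather than one 7^3: deeper nonlinearity,
  fewer parameters);
* four downsampling steps implemented as strided 3^3 convolutions (no
  max-pooling, so location/intensity information is learned rather than
  discarded) with encoder widths 64, 128, 256, 512; the recorded block plan
  places two refinement convolutions at the 64-map scale and lets the
  strided convolutions alone carry the deeper scales, leaving the heavy
  lifting at depth to the fusion pathway;
* each decoder step (scales 4 down to 1) gathers one 32-channel branch from
  every encoder scale at or above it and every decoder scale below it
  (average-pooling to go down, trilinear interpolation to go up, then a
  3^3 convolution); the five branches concatenate to 5 x 32 = 160 fused
  maps, merged by a 3^3 fusion convolution. Interpolation upsampling (not
  transposed convolution) avoids checkerboard artifacts in the dose maps;
* a final 3^3 convolution with tanh yields the normalized dose.

Batch normalization + ReLU follow every convolution except the output.
This plan totals 11,076,961 trainable parameters (11.077 M) for the
scheme-A input configuration. The exact block plan is recorded in
`inst/config/architecture.json` and read by `generator_spec()`; a
`width_mult` argument scales every width for desk-scale work.

## Discriminator: 3D patch classifier

The discriminator judges overlapping 3D patches rather than whole volumes:
five 4^3 convolutions with strides (2, 2, 2, 1, 1), LeakyReLU (slope 0.2)
activations and batch normalization on the middle three layers, ending in a
1-channel logit map. Each logit has a receptive field of

RF = 1 + sum_i (k_i - 1) prod_{j<i} s_j = 1 + 3(1 + 2 + 4 + 8 + 8) = 70

voxels per axis. The channel ladder (96, 192, 420, 840, 1) is the recorded
plan reproducing 29,025,721 trainable parameters (29.026 M) at the 8-channel
scheme-A input; convolutions followed by batch norm carry no bias. The
kernel edge 4 is the unique choice that, with these strides, yields the
70^3 receptive field.

## Losses

With sigma the logistic function and M the patch-logit map:

* discriminator: `L_D_GT = -mean log sigma(D(X|GT))`,
  `L_D_Pre = -mean log(1 - sigma(D(X|Pre)))`, `L_D = (L_D_GT + L_D_Pre)/2`;
* generator adversarial term (non-saturating):
  `L_cGAN = -mean log sigma(D(X|G(X)))`;
* adjacent-voxel-difference (AVD) term: for each of the three axes the
  difference of consecutive-slice differences between clinical and
  predicted dose is squared and accumulated — it penalizes mismatched dose
  *gradients*, preserving edges and suppressing blur;
* L1 term: mean absolute voxel difference.

Total: `L_G = lambda_cGAN L_cGAN + lambda_AVD L_AVD + lambda_L1 L_L1`.

All BCE terms use the softplus identity and are exact for arbitrarily large
logits. AVD and L1 are reduced to *means* by default (sums are available
via `reduction = "sum"`): mean reduction keeps the lambdas comparable when
the spatial size changes between the 96^3 training crops and full 128^3
inference. The weights default to (1, 10, 100) — the pix2pix-style
L1-dominant setting; they are not prescribed by the source protocol and are
exposed in the configuration.

## Training protocol

Adam with beta1 = 0.5, beta2 = 0.999; learning rate 0.002 for epochs
0-200, then linearly decayed to 0 at epoch 500; batch size 4; Kaiming
initialization everywhere. Augmentation draws a random 96^3 crop and a
random rotation by 90/180/270 degrees in the transverse plane, identical
across channels. Discriminator and generator are updated by turns — here
resolved as one discriminator step then one generator step per batch, with
the generated dose detached for the discriminator step. Every epoch is
checkpointed and a per-epoch loss log (all seven loss terms) is written as
CSV. Case splitting holds out 20 test cases and cycles the rest into seven
6:1 train:validation folds. Model selection among checkpoints uses the
lowest validation body MAE (the protocol records all epochs without naming
a criterion; body MAE is its headline comparison metric).

## Synthetic phantoms

The package replaces the clinical cohort with seeded synthetic pelvic
phantoms: a soft-tissue body ellipsoid (30 HU + 20 HU Gaussian noise) in
air (-600 HU), bone-level (700 HU) femoral-head spheres laterally, a
central PTV ellipsoid, an anterior bladder and a posterior rectum, with
geometry scaled to the grid's physical extent. The reference dose is
`Rx exp(-d / 25 mm)` with d the Euclidean distance (separable exact
distance transform, anisotropic spacing) to the PTV, plus 0.5 % Rx noise,
clipped at zero — prescription coverage inside the PTV and smooth falloff
outside, which gives DVHs with realistic shoulders, nontrivial isodose
surfaces for Dice/conformity work, and the bladder/rectum-nearer-than-femur
dose ordering of pelvic plans.

What the phantoms do **not** emulate: multi-arc beam structure and
entrance/exit dose streaks, heterogeneity corrections, inter-patient
anatomical variability, delineation noise, or dose shaping by optimization
constraints. Tests passing on phantoms therefore validate the machinery
(shapes, losses, optimization, metrics) — not clinical accuracy.

## Evaluation suite

All metrics compare a predicted dose to the clinical/reference dose:

* **MAE**, reported relative to the prescription (x100 %): the plain
  voxel-sum formula carries no normalization yet results are quoted in
  percent, so the package divides the masked mean absolute error by Rx —
  consistent with "relative to the prescribed dose" in the source
  discussion;
* **DVH** (cumulative, default 10 cGy bins) and queries `Dp` (rank
  `ceiling(p m / 100)` of the descending-sorted doses) and `Vd`;
* **HI** = (D2 - D98)/D50; **CI** = V_TP^2 / (V_T V_P) of the prescription
  isodose (the printed Dice-style denominator with the same term twice is
  treated as a typo; CI uses the standard definition);
* **isodose DSC** at levels 10-100 % of Rx; when both isodose volumes are
  empty the 0/0 is reported as 1 with a warning;
* **3D gamma** at 3 %/3 mm with a 10 % dose threshold: global normalization
  to Rx, exhaustive neighbourhood search within 3 x DTA, evaluated dose
  interpolated trilinearly at DTA/10 steps, offsets visited in order of
  increasing radius so the search terminates as soon as the distance term
  alone exceeds the best gamma;
* **difference histograms** (bias and sd) and **paired t-tests**
  (two-sided, significance 0.05; zero-variance differences are flagged
  degenerate instead of emitting a p-value).

`evaluate_case()` assembles everything into tibbles with `tidy()`/
`glance()` methods and `autoplot()` figures.

## Numerical choices and degenerate inputs

* Reverse-mode differentiation is implemented on a linear tape with
  analytically derived backward passes for convolution (vol2col + GEMM,
  tiled to bound memory), batch norm (batch statistics, population
  variance), pooling, trilinear resize and the losses; gradients agree with
  central differences to ~1e-6 relative at smooth points (finite-difference
  checks at step 1e-5 can straddle ReLU kinks in deep nets — an artifact of
  the check, not the gradients).
* Resampling uses the half-pixel convention; nearest mode guarantees masks
  stay binary.
* Cropping uses half-open 0-based windows; `crop_or_pad_center` is
  idempotent when the input already matches.
* Normalization refuses degenerate ranges; denormalize(normalize(x)) = x to
  machine precision.
* Ties in Dp are resolved by the sorted value (deterministic); gamma
  excludes sub-threshold reference voxels from the passing rate.
* The discriminator refuses inputs so small that any layer's output would
  be empty; the generator requires spatial extents divisible by 16 (four
  halvings across five scales — the prose "1/8" with four downsamplings is
  internally inconsistent and the five-scale plan is authoritative).

## Problem sizes used by the tests

The shipped tests run the whole pipeline at desk scale, chosen once as the
package's test conditions: 8 phantoms of 48^3 voxels at 3.5 mm, scheme B,
width multiplier 1/16, 32^3 training crops, batch 2, 30 epochs with decay
from epoch 12 — small enough for routine single-CPU runs while exercising
every code path (adversarial alternation, augmentation, batch norm,
full-scale fusion, checkpointing, the complete evaluation suite). The
architecture constants (parameter totals, receptive field, fused channel
count) are asserted at full width. The full 128^3 / 500-epoch protocol is
available through the same functions with `width_mult = 1`.

## Known limitations

* Phantom realism as above; no claim of clinical-level MAE/DSC/GPR is made
  or tested at desk scale.
* Batch norm at very small batch sizes is noisy; the full protocol's batch
  of 4 is the intended operating point.
* DICOM ingestion is limited to the dose-grid scale-factor arithmetic on
  already-decoded grids; NIfTI is the interchange format.
* Single-device training only; no mixed precision.
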