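---
title: "Simulating respiratory motion from a single chest radiograph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating respiratory motion from a single chest radiograph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rmsim)
```

## The problem

Dynamic chest radiography captures diaphragm kinetics and regional lung
function, but the hardware is scarce and the dose is roughly twice that of a
plain film. `rmsim` implements a generative shortcut: from one end-of-inhale
(EOI) projection image it predicts the nine subsequent phases of a breathing
cycle — not as synthesized pixels, but as per-phase deformation vector
fields (DVFs) that warp the input image. Because every predicted frame is a
resampling of the original radiograph, anatomical detail is preserved by
construction, and the fields themselves carry functional information
(Jacobian-determinant ventilation maps, diaphragm excursion).

## The model

The network is a U-Net bent around a recurrent bottleneck:

* **Encoder** — four down-sampling blocks, each two 3×3 convolutions + ReLU
  followed by 2×2 max pooling with stride 2, channel count doubling per
  level. The bottleneck is flattened through a fully connected layer into a
  1×512 latent vector `x0`. The input image is centered (its mean
  subtracted) before the first convolution; with all-positive smooth
  radiographs and zero-bias initialization most first-level ReLU channels
  would otherwise start silent on one side and never recover.
* **One-to-many LSTM** — a two-layer recurrent cell with hidden size equal
  to the latent width and zero-initialized state. `x0` is the first input;
  each emitted latent is fed back as the next input until `t = 9`, giving
  latents `x1 … x9` for the nine subsequent phases.
* **Decoder** — four up-sampling blocks (2×2 transposed convolution, skip
  concatenation with the encoder feature of the same level, two 3×3
  convolutions + ReLU). The encoder runs once; its skip features are reused
  by all nine decodes. A 1×1 convolution with `max_disp · tanh(·)` bounding
  yields each 2-channel DVF in pixel units (default bound: a quarter of the
  image height).
* **Spatial transformer** — each output pixel `(i, j)` of phase `t` samples
  the input image at `(i + u_y, j + u_x)` with bilinear interpolation and
  border clamping; nearest-neighbour sampling is used for label masks. The
  warp is differentiable in both the image and the field, so the whole
  pipeline trains end to end.

Two architectural choices deserve a note. The convolutions are padded
("same"): unpadded 3×3 convolutions would break the power-of-two size
arithmetic that symmetric skip connections and the flatten-to-512 layer
require. And the decoder emits nine fields for phases 1–9; the identity
field of the input phase is never predicted.

## Training losses

Three terms are combined, `L = w_s·L_smooth + w_m·L_MSE − w_n·L_NCC`:

* `L_smooth` — squared forward finite differences of each displacement
  channel in both directions, summed over the nine fields and divided by
  `2N` (`N` pixels per field). Penalizes physically implausible
  high-frequency deformation.
* `L_MSE` — per-pixel mean squared error between warped and target images,
  summed over phases. The per-pixel mean (rather than a bare pixel sum)
  makes loss weights independent of resolution.
* `L_NCC` — windowed normalized cross-correlation (default 9×9 window,
  `ε = 1e-5` in the denominator), averaged over pixels and phases; it is a
  similarity in [0, 1], so it enters the total with a negative sign —
  adding it, as a literal reading of a summed loss would suggest, would
  reward *de*-correlation under minimization.

The default training weights are `w_s = 1e-3, w_m = w_n = 1`. The
smoothness default needs explaining: with MSE expressed as a pixel *sum*,
equal weights put the smoothness term at roughly `1/N` of the image term.
Re-normalizing MSE to a per-pixel mean without rescaling the smoothness
weight silently multiplies the effective regularization by `N ≈ 4096` — in
our first experiments that drove the optimizer into predicting rigid,
spatially constant shifts (zero smoothness penalty, ventilation identically
zero). `w_s = 1e-3` restores the intended balance at 64×64 while still
suppressing high-frequency noise in the fields.

## The synthetic phantom cohort

Real 4D CT or dynamic radiograph series cannot ship with a package, so
`rmsim` generates its own study population. Each case is an analytic
thoracic scene: a bright soft-tissue background with a mild cranio-caudal
gradient, two darker lung fields shaped as half-ellipses with a convex
diaphragm border (a parabolic dome), a mediastinal gap, smooth cosine
texture, and optional bright nodules. The ten-phase cycle applies a
displacement field scaled by `w_t = sin²(πt/10)` — zero at EOI, maximal
near mid-cycle (end-of-exhale), returning toward inhale by `t = 9` — with
vertical magnitude ramping quadratically from `apex_motion_fraction` at the
lung apex to 1 at the diaphragm (so the motion gradient, and hence
ventilation, concentrates in the lower lung) plus a small lateral
contraction toward the mediastinum.

Phase images are rendered by evaluating the analytic scene at displaced
coordinates (clamped at the field of view, matching the warper's border
policy), so warping the EOI frame with a ground-truth field reproduces each
phase up to bilinear interpolation error; the cohort ships with those
ground-truth fields. Phase masks are the EOI masks warped with
nearest-neighbour sampling.

Default population parameters, chosen once for a cohort that is nontrivial
but learnable at desk scale:

* 64×64 px at 2.5 mm/pixel (a cropped lung field of ~16 cm);
* diaphragm amplitude 20 mm (≈ 8 px) with ±20% per-case jitter. The jitter
  is 80% tied to the case's resting diaphragm position (deeper resting
  inhale ⇒ larger excursion) and 20% independent; motion must be partly
  readable from the single input frame for the task to be well posed, which
  mirrors the physiological correlation between inspiratory level and
  excursion. The default amplitude puts the end-of-exhale mask overlap
  (Dice between the EOI mask and the p5 mask) near 0.90, so a no-motion
  predictor scores clearly below a motion-aware one;
* apex motion fraction 0.12, texture σ = 0.03, no nodules.

What the phantom deliberately does **not** model: rib shadows and cardiac
motion, CT-realistic texture, scatter physics, pathology-driven asymmetric
motion, and inter-phase gating inconsistency. Passing the packaged
acceptance checks therefore demonstrates that the architecture, losses,
training loop and evaluation stack are correct and that the network can
learn smooth respiratory kinematics from single frames — not that the
trained weights transfer to clinical radiographs.

## The preprocessing path

For volumetric input (the package's 3D phantom, or NIfTI volumes), the
chain mirrors standard DRR practice: threshold segmentation at −400 HU with
border-connected air removed and the two largest components kept as lungs;
beam's-eye-view ray casting restricted to the lung mask (attenuation is an
affine map of HU clamped at zero, parallel AP geometry by default —
analytic and exactly testable; perspective ray marching is available); one
shared bounding box per case over the union of all ten projected lung
masks (per-phase boxes would destroy the inter-phase pixel correspondence
the warper needs); bilinear resize to the network size; and case-level
min–max normalization so inter-phase intensity differences survive.
Coordinates are 0-based and boxes half-open throughout.

## Training configuration

The default `train_config()` is sized for a single CPU: Adam at 2e-3,
batch size 2, 30 epochs over the 40-case training split at 64×64 with 8
base channels, validating on the held-out split every 3 epochs and keeping
the best-by-validation parameters. An optional per-epoch learning-rate decay
(`lr_decay`, off by default) helps long single-case memorization runs,
where late-stage Adam oscillation otherwise limits the attainable error. These defaults depart deliberately from
a more conventional 1e-4/300-epoch GPU recipe: with gradient-checked exact
gradients and a smooth synthetic cohort, larger steps are stable, and the
whole run fits in roughly twelve minutes of CPU time. Training is exactly
reproducible from `(dataset, config)` — the seed drives initialization and
shuffling, and checkpoints carry the optimizer and RNG state so a resumed
run is bit-for-bit equivalent to an uninterrupted one at the same epoch
count.

## Evaluation

`evaluate_model()` reports, per test case and phase: whole-lung Dice
between the predicted mask (EOI mask warped by the predicted field,
nearest-neighbour) and the ground-truth phase mask; signed and absolute
left/right diaphragmatic-position errors in mm, where the diaphragmatic
position is the apex-to-dome distance and the dome detector takes the most
superior per-column inferior boundary within the central 60% of the lung's
column span (avoiding costophrenic angles and the mediastinal border); and
regional means of |det J − 1| in the upper and lower halves of the lung.
Warped-mask Dice (rather than re-segmenting predicted images) is exact with
respect to the model's own output, since predictions are deformations of
the input by construction. The Jacobian uses central differences with
one-sided stencils at borders.

Two reference models bracket every run: `"identity"` (zero fields — what a
no-motion predictor scores) and `"oracle"` (ground-truth fields through the
same stack — the ceiling imposed by mask discretization and the dome
detector, Dice ≥ 0.99 and length errors within two pixels).

## Numerical choices and degenerate inputs

* Warping clamps out-of-bounds samples to the border; gradients with
  respect to clamped coordinates are zero (a subgradient choice that keeps
  optimization stable at the field of view edge).
* A constant image min–max normalizes to all zeros by convention.
* NCC windows are clipped at the image border with per-pixel counts, so
  local statistics are exact everywhere; the `ε` guard only matters in
  near-flat windows, where local correlation is ill-defined and scored
  low — on smooth low-texture regions the windowed NCC of an image with
  itself therefore sits slightly below 1 by construction.
* Masks with fewer than three columns, empty mask pairs, and non-finite
  fields are rejected with errors rather than propagated.
* The displacement bound (`max_disp`, tanh-scaled) defaults to a quarter of
  the image height — twice the largest default phantom excursion, so the
  bound never saturates in normal training.

## Known limitations

* The cohort generator and the evaluation suite are 2D; the 3D phantom
  exists to exercise the preprocessing path, not volumetric prediction.
* Amplitude variability beyond what is visible in the input frame is
  irreducible error for any single-frame predictor; the 20% independent
  jitter component sets that floor here.
* DICOM series input is not supported (no reader dependency); NIfTI is.
* Training at 64×64 with 8 base channels is far below clinical resolution;
  the architecture scales, but the shipped defaults are sized for CPU
  reproducibility, and problem sizes in all packaged checks (64×64 cohort
  of 60 cases, 32×32 memorization fixtures) were chosen for that reason.

## A worked example

```{r example, eval = FALSE}
library(rmsim)

# a reproducible 6-case cohort (4 train / 2 test), small for illustration
dir <- file.path(tempdir(), "demo_cohort")
build_phantom_dataset(dir, n_train = 4, n_test = 2, seed = 1)

ck <- rms_train(dir, train_config(epochs = 10), quiet = FALSE)
metrics <- evaluate_model(ck, dir)
metrics             # per-phase Dice and diaphragm errors
glance(metrics)     # one-row cohort summary
autoplot(metrics)   # per-phase Dice distribution

# functional output: ventilation map of the predicted end-of-exhale field
case <- load_phantom_case(dir, phantom_manifest(dir)$case_id[5])
fwd <- rms_forward(ck$params, ck$net_config, case$images[[1]])
autoplot(ventilation_map(fwd$dvfs[[5]]))
```
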