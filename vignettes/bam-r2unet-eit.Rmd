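---
title: "Boundary-attention adversarial post-processing for leg EIT: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Boundary-attention adversarial post-processing for leg EIT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(legeit)
```

## The problem

Electrical impedance tomography (EIT) drives small currents through boundary
electrodes and reconstructs the internal conductivity map from the measured
boundary voltages. The voltage-to-conductivity inverse problem is severely
ill-posed, so model-based reconstructions of a leg cross-section — a
concentric arrangement of skin, subcutaneous fat, muscle, bones, vessels and
nerves — come out blurred and artifact-laden. `legeit` implements a two-stage
pipeline: a hybrid total-variation (HTV) pre-reconstruction retains the
physics of the measurement, and a learned post-processor (a
boundary-attention recurrent-residual U-Net trained as a conditional
Wasserstein GAN) maps the artifact-laden image to a clean conductivity map.
Everything — phantoms, forward model, solver, network layers, backpropagation
and optimizer — is implemented inside the package; no external deep-learning
runtime is involved.

## Phantom simulator

`generate_phantom()` draws a 64 x 64 leg section on a disc of radius R = 30
px (the largest disc leaving a margin inside the grid; the radius is a
package choice, exposed as an argument). Outer-to-inner: a skin ring of
1–3 px, a fat ring of 5–10 px, muscle filling the interior; an eccentric
tibia (cortical shell, cancellous core) at 0.15R–0.35R from the center, a
lateral fibula at up to 0.55R–0.75R, one to three vessels and one or two
nerve bundles (radius 1–3 px), and 0–3 anomalies (edema, tumor, hematoma,
near-insulating foreign body; radius 2–6 px) centered in muscle.
Conductivities are drawn per structure from 1 kHz literature ranges (e.g.
skin 0.30–0.60, muscle 0.80–1.20, cortical bone 0.05–0.15, vessel 1.20–1.60
S/m), all within [0, 2] S/m; geometry and conductivity are perturbed per
sample. Structure sizes not fixed by anatomy (bone, vessel and anomaly radii)
were chosen once so the structures remain resolvable at 64 x 64. Outside the
disc the medium equals the homogeneous reference (1 S/m) so that the
linearized forward model has a clean baseline.

What the simulator does *not* emulate: real anatomical atlases, 3D current
spreading, contact impedance, multi-frequency tissue spectra, and hardware
drift. Passing tests therefore demonstrate correctness of the method on this
family of layered phantoms, not clinical performance.

## Forward model and noise

The disc is meshed by splitting every in-disc pixel into two linear
triangles (~5,600 elements); 16 point electrodes sit on the boundary nodes
closest to uniform angles. Under the adjacent-drive/adjacent-measurement
protocol each of the 16 neighbouring electrode pairs carries 1 mA in turn
and voltages are read on the 13 neighbouring pairs not touching the drive,
giving 208 measurements in a frozen drive-major order. The Jacobian `J`
(208 x P pixels) is assembled by the adjoint method from drive and
measurement fields at the reference conductivity; `solve_forward()` is the
linearization `v = v0 + J (sigma - 1)`, and `fem_forward()` re-assembles and
solves the full FEM as an audit oracle (reciprocity holds to ~1e-15; the
linearization tracks the FEM within 10% for small contrasts).

Measurement noise follows `SNR = 10 log10(RMS(V)/RMS(N))` — an
amplitude-ratio convention with factor 10, implemented exactly as stated and
achieved exactly by rescaling the drawn Gaussian vector; the conventional
power reading (factor 20) is available via `convention = "power"`. Datasets
alternate clean / 30 / 45 / 55 dB by sample index with period four; the tags
are frozen at dataset build time as a property of the sample.

## HTV pre-reconstruction

`htv_solve()` minimizes, over the pixel perturbation `s`,

    || dv - J s ||^2 + alpha ||L s||^2 + beta ||s||_1

with `L` the diagonal Noser matrix (column norms of `J`). The L1 term is
smoothed as `sqrt(s^2 + eps^2)` with `eps = 1e-4` and the objective is
minimized by iteratively reweighted least squares — a majorize–minimize
scheme whose objective trace is non-increasing by construction; with
`beta = 0` the first iterate is the exact generalized-Tikhonov solution.
Each inner ridge solve uses the Woodbury identity, reducing the work to one
208 x 208 system per iteration. Defaults (`alpha = 0.01`, `beta = 1e-12`,
25 iterations, tolerance 1e-6) were frozen after a grid search on a held-out
synthetic batch: `alpha` sits on the RMSE-optimal plateau, and `beta` — which
lives on the volt-squared scale of the data term, hence its magnitude — is
set so the L1 term contributes visibly, which leaves the pre-reconstruction
at the artifact level a model-based solver realistically attains. That
artifact level is the point: the HTV image is the network's input, not the
final product.

## The generator and the boundary attention module

The generator is a symmetric encoder–bottleneck–decoder. Each encoder stage
projects channels with a 1 x 1 convolution, applies two RecurrentBlock-BAM
blocks and halves the resolution by 2 x 2 max-pooling; channels run
32/64/128/256 (a `base_channels` multiple), the bottleneck has 512 channels
and dropout 0.1, and the decoder mirrors the encoder with transposed-conv
upsampling, skip concatenation and 1 x 1 projection. The head is a 3 x 3
convolution, a 1 x 1 convolution to one channel, and `2 * sigmoid(.)`, which
confines the output to the conductivity range [0, 2] at any input
resolution that is a multiple of 16.

A RecurrentBlock applies its first 3 x 3 convolution `t = 2` times with
re-injection of the block input (`h0 = C1(x)`, `h_i = C1(h_{i-1} + x)`),
its second convolution once — the literal reading of the recurrence; the
classical variant with both convolutions recurrent is available behind
`classic_r2u = TRUE` — then the boundary attention module, then a LeakyReLU
over the sum with a 1 x 1-projected residual (applied even when channels
match, for uniformity). Each convolution is followed by batch
normalization and LeakyReLU (slope 0.2).

BAM fuses three branches computed from the same input `z`:

* spatial: 1 x 1 reduction (reduction 8) -> 3 x 3 depthwise -> 3 x 3
  dilated (rate 2) -> 1 x 1 to one channel -> sigmoid map `Ms`;
* channel: global average pool -> two dense layers with ReLU between ->
  sigmoid vector `Mc`;
* edge: a grouped per-channel 3 x 3 convolution initialized to the discrete
  Laplacian and trained freely; `Me = sigmoid(|e| - mean(|e|))`, with the
  mean taken per channel per sample (the "adaptive threshold").

The fusion is `BN(alpha z (1 + Ms) Mc + beta z + gamma Me z)` with trainable
unconstrained scalars initialized 0.5/0.3/0.2; batch norm is applied to the
sum, not per term. `Ms` broadcasts over channels and `Mc` over space.

One architectural point was genuinely underdetermined: the bottleneck depth.
With two bottleneck blocks the 64 x 64 generator would carry ~18 M trainable
parameters, while the reported size of this architecture family is ~12.6 M —
which matches one bottleneck block almost exactly (13.0 M here). The package
therefore defaults to `bottleneck_blocks = 1` and exposes the count in
`generator_config()`. In the resolution study the feature width adapts to
the input: base channels scale with `size/64`, which reproduces the
quadratic parameter growth across the 32/48/64/96 grid.

The critic is a conditional PatchGAN: five 4 x 4 convolutions with strides
2,2,2,2,1, channels 64 -> 512 -> 1, affine-free instance normalization on
layers 2–4, LeakyReLU 0.2, no sigmoid (Wasserstein scores). Its input is the
HTV image and the target image stacked on the channel axis; a 64 x 64 input
yields a 3 x 3 patch score map.

## Losses

The anatomy-prior loss is a weighted sum of six terms (weights 100 / 30 /
20 / 5 / 10 / 2):

* pixel: mean L1 plus 0.5 x mean squared L2;
* edge: mean L1 between Sobel gradient-magnitude maps (valid convolution,
  so constant images respond exactly zero; magnitude smoothed with 1e-8);
* layered tissue: the disc is partitioned by radius into skin (R-3..R), fat
  (R-10..R-3), muscle (0.35R..R-10) and core (< 0.35R) rings — the muscle
  ring's inner bound is set to 0.35R so the four masks are disjoint — and
  the absolute differences of per-ring masked means are summed;
* total variation: anisotropic forward differences, no wraparound;
* SSIM: one minus the mean Gaussian-windowed SSIM (window 11, sigma 1.5);
* histogram: L1 between ascending-sorted pixel vectors, per image.

Inside the total every term is mean-reduced per image and batch-averaged, so
the stated weights remain scale-comparable across resolutions; the
standalone `tv_loss()`/`hist_loss()` default to the literal sum-reduced
definitions. The SSIM stability constants scale with the data range
(`C1 = (0.01 Dr)^2`, `C2 = (0.03 Dr)^2`): at `Dr = 255` they equal the
classic 6.5025/58.5225, and conductivity images use `Dr = 2` — the two
readings agree because SSIM is invariant under a common affine rescaling
when the constants scale accordingly. Train-time and eval-time SSIM share
one implementation.

Adversarial training is standard WGAN-GP: the critic minimizes
`E[D(x, G(x))] - E[D(x, y)] + 10 * GP` with the gradient penalty taken at
per-sample convex interpolates between real and fake targets, and the
generator minimizes `-E[D(x, G(x))] + L_total`.

## Training loop and numerics

Per step the critic is updated `n_critic = 5` times, then the generator
once; Adam(0.5, 0.999) with learning rates 1e-4 (generator) and 4e-4
(critic), cosine-annealed per epoch to 1e-6 for both; global gradient
clipping at norm 1; Kaiming initialization for the generator and N(0, 0.02)
for the critic; the best validation-SSIM checkpoint is retained (no early
stopping). Augmentation (right-angle rotation, horizontal flip, input-only
Gaussian perturbation with sd 0.01) is re-drawn every epoch. The fake batch
of a step is generated once and reused across the five critic iterations —
the fake distribution only changes when the generator is updated — while
the gradient-penalty interpolates are redrawn each iteration.

Backpropagation is implemented in the package (im2col/GEMM and shift-GEMM
convolution kernels in C++, analytic gradients for every loss term
including the windowed SSIM); all of it is finite-difference checked in the
test suite. Two deliberate numerical choices: (1) the gradient penalty's
second derivative is computed by exact double-backprop through the critic's
convolution/LeakyReLU chain with the instance-norm statistics treated as
constants — exact almost everywhere for the piecewise-linear activations,
and a frozen-statistics reading of the norm layers; (2) ReLU/LeakyReLU
backward uses the strict sign of the cached output, so clipped zeros take
the slope branch.

## Scaled-down study conditions

The reference recipe (4800 samples, 120 epochs, base 32, batch 16,
generator learning rate 1e-4) is far beyond a single-CPU R session, so the
package's built-in acceptance study runs the identical pipeline at reduced
scale: 240 samples (192/24/24 split), 4 epochs, batch 8, generator base 8,
critic base 16, evaluated on the held-out test split at 45 dB SNR. One
deliberate adaptation accompanies the shorter schedule: with the cosine
schedule compressed ~150-fold, the reference learning rate moves the
parameters too little to converge at all, so the desk-scale study raises
both learning rates to 1e-3 — the standard rescaling when compressing a
training schedule. These sizes and rates are the package's frozen
desk-scale choices; the qualitative claim under test is that learned
post-processing improves on its HTV input in both mean SSIM and mean RMSE,
not the absolute full-scale table values, which depend on capacity and
training length. `scripts/acceptance.R` re-runs this end to end.

## Fitted-model interface

`eitgan()` returns a classed object with `print`, `summary`, `coef` (the
BAM fusion weights per block), `predict` (HTV images in, reconstructions
out), `residuals` and `plot` (loss and validation curves) methods. A
`simulate` method is deliberately absent: the model is an image restorer,
not a generative model of new measurements; new data come from
`eit_dataset()`.

## Known limitations

Linearized forward physics (difference imaging about a homogeneous
reference); point electrodes; a single leg geometry family with fixed
electrode count; desk-scale training defaults far below the reference
recipe, so absolute metric levels are not comparable to full-scale results;
and the frozen-statistics reading of instance norm inside the gradient
penalty's second derivative.
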