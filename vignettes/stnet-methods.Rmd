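---
title: "Shape and texture joint learning for lesion recognition: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shape and texture joint learning for lesion recognition: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Convolutional classifiers trained (or pre-trained) on large natural-image
collections lean heavily on local texture statistics and represent object
shape comparatively poorly. For melanoma-versus-nevus recognition this matters:
dermatologists read both the texture of a lesion and the irregularity of its
boundary. `stnet` implements a two-stream network that learns both cues
explicitly and fuses them for binary (malignant vs. benign) classification,
with an auxiliary mask-decoding task supplying the shape supervision.

# Model

## Two streams, one classifier

An input RGB image feeds two parallel encoders.

* **Texture stream.** A bottleneck-residual backbone whose 3x3 convolutions
  are *pyramid-grouped*: within each block the group count of the three
  convolutions follows a dense-to-sparse schedule, from a standard convolution
  (1 group) through an intermediate grouping to depth-wise connectivity.
  `pgcGroupSchedule(L, C)` picks, for layer $l$ of $L$, the divisor of $C$
  nearest to $C^{(l-1)/(L-1)}$ — a geometric interpolation between the two
  extremes the design is motivated by. The geometric interior of the schedule
  is a package design decision: only the dense-to-sparse direction and the two
  endpoints follow from the motivation. Ties between equally near divisors go
  to the smaller (denser) one, which keeps the schedule monotone.
* **Shape stream.** The same backbone skeleton with the deep-stage 3x3
  convolutions replaced by *deformable convolutions*:
  $y(p) = \sum_{k} w(p_k)\, x(p + p_k + \Delta p_k)$, where the per-position
  tap offsets $\Delta p_k$ are predicted by an ordinary convolution over the
  same input and fractional reads are resolved by bilinear interpolation
  (zero outside bounds, matching the zero-padding convention). Offset layers
  are zero-initialized, so an untrained shape encoder is *exactly* its
  non-deformable counterpart — a property the test suite asserts.
* **Decoder.** The deepest shape feature map is decoded back to a full-
  resolution lesion-mask probability map through transposed-convolution
  stages interleaved with two-convolution residual blocks, one stage per
  factor of 2 of encoder downsampling, and a logistic output head.
  Deliberately **no** encoder–decoder shortcut connections exist: all mask
  information must pass through the deepest feature map, which is what forces
  that feature map to become shape-biased. The stage count (5 at depth 50,
  mirrored widths; 3 in the desk-scale profile) is our reading of a
  "ResNet-18-like" decoder, which does not pin an exact layer count.

## Fusion and classification

The two final feature maps are concatenated along channels and passed through
channel attention: each channel is collapsed to
$g_k = \tfrac12(\mathrm{mean}_{ij} z_{ijk} + \max_{ij} z_{ijk})$, two 1x1
transforms with logistic activations produce per-channel weights
$w_{att} \in (0,1)^c$, and the map is re-weighted channel-by-channel. Because
every weight is strictly inside $(0,1)$ the operation can only contract
feature magnitudes — asserted as a property test. Both nonlinearities are
logistic (a single squashing function is used for both layers); most
attention blocks rectify the hidden layer instead, but we keep the
double-logistic form. The hidden width is $c/r$ with reduction ratio
$r = 16$ by default (`fusion$reductionRatio`), the SE-style convention for
attention bottlenecks. A global average pool and a single fully connected layer
with logistic output produce $p \in (0,1)$; $p > 0.5$ (strictly) predicts
malignant.

## Gradient scaling and the joint objective

Three parameter groups are optimized with different objectives:

* texture encoder: classification loss $L_{CLS}$ only;
* shape decoder: shape loss $L_{SHP}$ only;
* shape encoder: $\alpha L_{CLS} + \beta L_{SHP}$.

$L_{SHP}$ is the pixel-wise mean squared error between the predicted and true
mask; samples without a mask contribute no shape term (partial mask
availability is the normal regime). The $\alpha$ weighting is realized by a
*gradient-scaling layer* between the shape feature map and the concatenation:
identity forward, gradient multiplied by $\alpha$ backward. Defaults
$\alpha = 0.1$, $\beta = 1$ — the two coefficients are free parameters, and
we damp the classification gradient into the shape
encoder (shape supervision should dominate early) and leave the shape path
at unit weight; both are exposed (`loss$alpha` / `fusion$gradScale` are the
same dial, `loss$beta`). We also route $\beta$ through the decoder path, so
$\beta = 0$ switches joint learning off entirely (decoder receives no
gradient) — this makes the no-joint-learning ablation a one-knob experiment;
at the default $\beta = 1$ the decoder objective is plain $L_{SHP}$.

## Asymmetric classification loss

With many more benign than malignant images, plain cross-entropy
(Equation below, natural log, $p$ clamped to $[10^{-7}, 1-10^{-7}]$) lets the
negative class dominate:

$$L_{CE} = -y \log p - (1-y) \log(1-p).$$

The asymmetric loss decouples the two branches:

$$L_{CLS} = -y\,(1-p)^{\gamma_+} \log p \;-\; (1-y)\, p_t^{\gamma_-} \log(1-p),
\qquad p_t = \max(p - \varphi, 0),$$

with focusing exponents $\gamma_+ = 1$, $\gamma_- = 3$ by default —
asymmetric in the direction that damps the abundant negative class, at the
setting the package's sensitivity harness (`gammaSweep()`) is built to
re-derive for new data — and probability cutoff $\varphi = 0.05$ (small, so
only near-certain easy negatives are discarded entirely). With
$0^0 := 1$, setting
$\gamma_\pm = 0, \varphi = 0$ recovers cross-entropy exactly. The constructor
warns — rather than fails — when $\gamma_+ > \gamma_-$, because the
sensitivity sweep itself must be able to visit $\gamma_- < \gamma_+$.

# Synthetic data

No public dataset is required: `generateDataset()` emulates the statistical
structure the model assumes.

* **Shape cue.** The lesion boundary is
  $r(\theta) = R\,(1 + a\, f(\theta))$ with $f$ a seeded truncated Fourier
  series over angular orders 2–8 normalized to unit peak, so `irregularity`
  $a$ is the exact relative perturbation amplitude. The domain is
  star-shaped, hence simply connected, for $a < 1$. Malignant lesions draw
  $a \sim U(0.25, 0.5)$, benign $a \sim U(0, 0.15)$.
* **Texture cue.** Gaussian luminance speckle inside the lesion with
  class-dependent standard deviation (malignant $U(0.10, 0.20)$, benign
  $U(0.02, 0.08)$) over a darker base color; outside, a skin-toned linear
  illumination gradient in a seeded random direction.
* **Imbalance and masks.** The default malignant:benign call mirrors the
  roughly 1:2.85 ratio of real dermoscopy archives, and `maskFraction`
  (default 0.15, echoing how few archive images carry masks) controls the
  seeded subset of samples written with ground-truth masks.

Everything is a pure function of (spec, seed): identical specifications
render bit-identical images, which is what makes the training runs in the
test suite exactly reproducible. What the generator does *not* emulate:
hair and ruler artifacts, color constancy failures, multi-lesion fields,
pathology-level cell morphology. Tests passing on these images demonstrate
that the mechanisms work as designed — not clinical performance.

# Numerical and design choices

* **Normalization.** Per-sample instance normalization (per-channel spatial
  standardization with learned gain and bias, $\varepsilon = 10^{-5}$)
  instead of batch statistics: identical behavior in training and
  evaluation, no running averages, exact determinism at any batch size.
* **Coordinates.** (row, col), 0-based, pixel centers at integers; bilinear
  reads outside the array contribute zero everywhere (deformable taps and
  affine warps share one resampling kernel).
* **Initialization.** Seeded He-style normal weights; offset layers and
  biases zero, so deformable layers start as their regular counterparts.
* **Optimizer.** RMSprop (squared-gradient decay 0.99, $\varepsilon=10^{-8}$)
  with momentum 0.9, learning rate $5\times10^{-4}$, weight decay
  $10^{-5}$ at the full profile. Batch
  reduction is the mean over the batch for $L_{CLS}$ and the mean over
  mask-bearing samples for $L_{SHP}$.
* **Augmentation.** Random rotation uniform in ±30° and random crop to
  87.5% of the side resized back, applied identically to image and mask
  (mask re-binarized at 0.5); the augmentation names come from the training
  recipe, the magnitudes are ours.
* **Degenerate metrics.** Precision (recall) is defined as 0 when its
  denominator is 0; $p$ exactly at the threshold predicts negative (the
  positive rule is a strict inequality).
* **Pooling ties.** The max-pool half of the dual pooled descriptor routes
  its gradient to the first arg-max on ties.
* **CAFF placement.** Attention is applied once, on the concatenated map
  (not per stream) — the fusion diagram reading we adopted. The ablation
  hook `attnMask` removes channels from the fusion entirely (they are
  excluded from the pooled descriptor and zeroed in the output), so masking
  the shape channels provably makes the prediction independent of the shape
  input.

# Desk-scale profile and problem sizes

All tests and the acceptance script use `stnetTinyConfig()`: depth-8
encoders (two bottleneck stages, /8 downsampling), 64x64 images, batch 8,
learning rate $2\times10^{-3}$, no augmentation. The training runs are
32–48 samples for 60–200 steps; five-fold cross-validation uses a 40-sample
set. These sizes were chosen so a full verification pass — including the
overfitting check and the paired mechanism experiments (asymmetric loss vs.
cross-entropy on 1:3-imbalanced data; joint learning $\beta=1$ vs.
$\beta=0$ on shape-cue-dominated data, three seeds each) — runs end to end
on a single CPU core in well under half an hour. The full 50/101-layer
geometry (224x224 input, 7x7x2048 feature maps) is exercised by a forward
pass in the test suite; archive-scale *training* experiments need real
datasets and GPU-class budgets, and are out of scope for this package.

# Known limitations

* The directional claim that channel-attention weights drift toward the
  shape channels when only the shape cue is informative is **not** reliably
  observable at desk scale: in our short runs the fully connected classifier
  re-weights channels without moving the attention vector. We therefore
  assert the ablation form of the mechanism (masking shape channels makes
  the prediction shape-invariant) rather than the drift.
* Instance normalization is a deliberate departure from the batch-norm
  backbone convention; at archive scale the choice may matter and is not
  evaluated here.
* The gradient-scaling implementation of $\alpha$ scales the classification
  gradient into the shape encoder only (the texture path is unscaled), so
  $\alpha$ and $\beta$ are identifiable only up to the shape-encoder
  learning-rate scale.
* Grouped convolution supports `groups | Cin, Cout` with contiguous channel
  groups; channel shuffling between grouped layers is not implemented.
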