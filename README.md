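# stnet: shape and texture two-stream networks for lesion image recognition

`stnet` is an R implementation of a two-stream convolutional network for
binary lesion recognition (malignant melanoma vs. benign nevus) that learns
**shape** and **texture** features jointly instead of relying on the
texture-biased representations typical of ImageNet-style backbones. It is
aimed at researchers studying knowledge-guided medical image recognition —
in particular the interplay of auxiliary segmentation supervision, feature
fusion and class-imbalance losses — on commodity CPU hardware: the package
ships its own synthetic lesion generator, so every experiment in it runs
end to end without external data, GPUs or a deep-learning framework.

## The model

An input image feeds two parallel encoders whose outputs are fused and
classified:

* **Texture stream** — a bottleneck-residual backbone with *pyramid-grouped
  convolution*: within each block the channel-group counts follow a
  dense-to-sparse schedule `[1, g, C]` from standard to depth-wise
  connectivity (`pgcGroupSchedule()`).
* **Shape stream** — the same skeleton with *deformable convolutions* in the
  deep stages, `y(p) = Σ_k w(p_k) x(p + p_k + Δp_k)`, offsets predicted by a
  zero-initialized convolution and fractional reads resolved by bilinear
  interpolation. A transposed-convolution decoder (no encoder shortcuts)
  reconstructs the lesion mask from the deepest feature map under a
  pixel-wise L2 loss `L_SHP`, forcing that feature map to carry shape.
* **Fusion head** — channel attention over the concatenated maps
  (`w_att = σ(W₂ᵀ σ(W₁ᵀ g))` with `g_k = ½(mean + max)` per channel), a
  gradient-scaling layer (identity forward, gradient × α backward) damping
  the classification gradient entering the shape encoder, then global
  average pooling and one logistic unit: `p > 0.5` predicts malignant.
* **Asymmetric loss** for class imbalance:
  `L_CLS = −y(1−p)^γ₊ log p − (1−y) p_t^γ₋ log(1−p)` with probability
  transfer `p_t = max(p − φ, 0)`; defaults `γ₊ = 1, γ₋ = 3, φ = 0.05`.
  The three parameter groups are optimized as: texture encoder ← `L_CLS`;
  decoder ← `L_SHP`; shape encoder ← `α·L_CLS + β·L_SHP`.

All convolution kernels (grouped, deformable, transposed), their
reverse-mode gradients, and the RMSprop trainer are implemented in this
package (C++ via Rcpp/RcppArmadillo plus an R layer graph) and are verified
against loop-based oracles and finite differences in the test suite.

## Worked example

Generate an imbalanced synthetic dataset (irregular-boundary, high-speckle
malignant lesions; smooth, low-speckle benign ones; masks for 30% of
samples), train the desk-scale model and evaluate:

```r
library(stnet)

man <- generateDataset(16, 40, maskFraction = 0.3, imageSize = 64,
                       seed = 7, outDir = file.path(tempdir(), "demo"))
man <- splitManifest(man, c(0.6, 0.2, 0.2), seed = 7)
man
#> LesionManifest: 56 samples ( 16 malignant / 40 benign ), 16 with masks
#>   splits: train=34 val=11 test=11

cfg <- stnetTinyConfig(seed = 7, train = list(epochs = 30, maxSteps = 120))
model <- stnet(cfg)
model
#> STNet two-stream model
#>   texture encoder : depth 8 (pyramid-grouped conv)
#>   shape encoder   : depth 8 with deformable stages
#>   fusion          : channel attention on, gradient scale 0.1
#>   parameters      : 85,876

res <- trainModel(model, man)          # ~120 seeded steps, CPU
evaluateModel(model, man, split = "test")
#> EvalReport: Acc 0.9091  Pre 1.0000  Rec 0.6667  F1 0.8000  (TP 2 FP 0 TN 8 FN 1)
```

The report reads: of the 11 held-out images the model classifies 10
correctly; both predicted malignancies are true melanomas (precision 1) and
it recovers two of the three malignant cases (recall 2/3). `predictMask()`
returns the decoder's lesion-mask probabilities, `crossValidate()` runs
stratified k-fold CV, and `gammaSweep()` retrains across a grid of γ₋
values to reproduce the loss-sensitivity experiment. A thin command-line
front end with `generate | train | evaluate | cv | sweep-gamma` subcommands
lives at `inst/cli/stnet.R`. The full 50/101-layer profiles
(`stnetConfig()`, 224×224 inputs, 7×7×2048 features) are available for
geometry-faithful experiments; `vignettes/stnet-methods.Rmd` documents the
model, the defaults and their rationale.

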