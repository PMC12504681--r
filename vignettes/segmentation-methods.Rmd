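---
title: "Methods: a four-stage 2D V-Net with a context-boosting bottleneck"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a four-stage 2D V-Net with a context-boosting bottleneck}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the model

Gliomas vary enormously in size, shape and intensity across patients
and MRI modalities, and expert manual delineation is slow.  This
package implements a compact convolutional encoder-decoder for
multi-class tumor segmentation of co-registered multi-modal brain MRI
(T1, T1CE, T2, FLAIR stacked as four input channels), in the BraTS
labeling convention: background 0 plus three tumor compartments with
raw labels 1 (necrotic/core), 2 (edema) and 4 (enhancing), remapped to
contiguous classes 0–3 internally.

The network is a V-shaped encoder-decoder with four encoder stages
holding 1/2/3/3 convolutions at 16/32/64/128 filters.  Each stage ends
with an element-wise residual sum with its own input (a 1×1 projection
aligns channel counts where they differ), and the sum feeds both the
next stage (via a 2×2 stride-2 convolution) and the matching decoder
stage.  Where a classical V-Net would descend to a fifth stage, the
deepest feature map instead enters a *context-boosting bottleneck*:
2×2 max pooling (to bound the cost of what follows) → a wide 500-filter
3×3 convolution → a learned ×2 transpose-convolution upsampling that
restores the spatial size at 256 channels.  The decoder mirrors the
encoder with three transpose-convolution upsampling stages; each
concatenates the encoder skip tensor, so its channel depth is twice
its encoder counterpart.  A 1×1 convolution and a per-pixel softmax
over the four classes close the network.  Replacing the fifth stage by
the bottleneck is what makes the model small: at the shared filter
schedule the four-stage + bottleneck network holds fewer than half the
trainable parameters of the five-stage baseline (the test suite checks
the ratio is below 0.5).

Because no deep-learning framework is available in the supported
environment, the layers (convolution via im2col/col2im kernels,
transpose convolution, max pooling, PReLU, dropout, softmax), the
backward passes and the Nadam optimizer are implemented in the
package itself.  Every analytic gradient is verified against central
finite differences in the test suite, end-to-end through the full
network; that is the load-bearing correctness argument for the whole
training module.

## The composite training loss

Training minimizes a weighted combination of three overlap losses,
computed on *soft confusion counts*: for class $c$,
$TP_c = \sum_i p_{ic} g_{ic}$, $FP_c = \sum_i p_{ic}(1 - g_{ic})$,
$FN_c = \sum_i (1 - p_{ic}) g_{ic}$, where $p$ are softmax
probabilities and $g$ the one-hot truth.  On hard 0/1 inputs these
equal integer pixel counts exactly, which the tests exploit by
checking soft-count metrics against a brute-force per-pixel counting
loop.  With Dice $D = \frac{2TP + \epsilon}{2TP + FN + FP + \epsilon}$,
Tversky index
$TI = \frac{TP + \epsilon}{TP + \alpha FN + \beta FP + \epsilon}$ and
Jaccard $J = \frac{TP + \epsilon}{TP + FP + FN + \epsilon}$, the total
loss is

$$L = 0.6\,\log\cosh(1 - D) \;+\; 0.2\,(1 - TI)^{0.75} \;+\; 0.2\,(1 - J),$$

averaged with equal weight over classes.  The weights sum to 1 so the
total stays below 1.  The log-cosh reshaping keeps the Dice term
smooth and tolerant of skewed class frequencies; the focal exponent
$\gamma = 0.75 < 1$ amplifies the gradient of low-overlap (hard)
classes; the Jaccard term aligns training with the IoU metric models
are usually ranked by.  At $\alpha = \beta = 0.5$ the Tversky index
reduces to Dice and at $\alpha = \beta = 1$ to Jaccard — both
identities are property-tested to 1e-12.

### Parameters that matter

| parameter | default | why |
|---|---|---|
| loss weights (log-cosh Dice / focal Tversky / Jaccard) | 0.6 / 0.2 / 0.2 | published setting; must sum to 1 |
| focal exponent $\gamma$ | 0.75 | published setting |
| Tversky $\alpha, \beta$ | 0.7 / 0.3 | only $\alpha > \beta$ is stated upstream (false negatives cost more in tumor detection); 0.7/0.3 is the canonical focal-Tversky configuration and is configurable |
| smoothing $\epsilon$ | 1e-6 | added to every numerator and denominator; empty-vs-empty masks score a perfect 1 (loss 0) |
| class aggregation | macro over all classes (training); macro over foreground (reported metrics) | the upstream scalars never state an aggregation; both plus a binary whole-tumor Dice are reported |
| learning rate / optimizer | 2e-4, Nadam | published setting |
| dropout rate | 0.1 after each encoder stage | the stated "keep probability of 0.1" is read as *drop* probability 0.1; a literal keep-10% would cripple training |
| bottleneck filters | 500 | published setting; 50 at test scale |
| kernel size | 3×3 | never stated upstream; 3×3 is the modern default (the 5×5 V-Net heritage is available through the spec) |
| input side | 192 (center-cropped from 240) | published crop; removes 24 edge pixels per side |

### Numerical choices

- The focal term $(1-TI)^{\gamma}$ has unbounded slope as $TI \to 1$
  when $\gamma < 1$; the gradient clamps $1 - TI$ at 1e-8.  The loss
  value itself is never clamped.
- Soft counts are pooled over the whole batch before the loss is
  evaluated (the batch is treated as one large image); evaluation
  pools one global confusion table over the dataset, with per-slice
  averaging available by flag.
- Reported evaluation metrics use hard argmax counts; the loss always
  uses soft counts (required for differentiability).
- The reported Tversky index uses the same $\alpha/\beta$ as the loss
  by default; pass `tversky_params(0.5, 0.5)` to make it coincide
  with Dice.
- Nadam uses $\beta_1 = 0.9$, $\beta_2 = 0.999$, $\epsilon =$ 1e-7
  with the Nesterov-corrected first moment.
- Weight initialization is variance-scaling (fan-in, He-style for
  PReLU), seedable; PReLU slopes start at 0.25.

## Design choices where the design was open

- **Residual sums across channel changes.**  The element-wise stage
  sum needs matching channel counts; a 1×1 convolution projects the
  stage input when they differ.  The mechanism is unstated upstream;
  a projection is the standard ResNet solution.
- **Downsampling.**  Between encoder stages, 2×2 stride-2 convolution
  (V-Net convention).  The only max pooling sits inside the
  bottleneck, where it is explicitly prescribed.
- **Bottleneck output.**  The published description ends at the wide
  convolution.  Restoring the spatial size inside the block (transpose
  convolution, 256 channels at paper scale) keeps the decoder contract
  independent of whether the bottleneck is present.  Consequently,
  enabling the bottleneck also widens the first decoder upsampling
  layer; the parameter-accounting test counts that delta explicitly.
- **Filter schedule.**  Only the terminal 128 encoder channels are
  stated; 16/32/64/128 follows the powers-of-two doubling convention.
- **Slice window.**  "Slices 30 to 120" is read half-open and 0-based,
  `[30, 120)`, the only reading consistent with the published corpus
  size of 20 cases × 90 = 1,800 slices; the pipeline-count test pins
  exactly that arithmetic.
- **Train/test split.**  Performed at the patient level to prevent
  neighboring-slice leakage (the upstream "80% of the images" may mean
  slice-level; slice-level is available by flag in the CLI).
- **Normalization.**  Absent upstream; per-volume per-modality z-score
  over nonzero voxels, clipped to [−5, 5], background kept at exact 0.
  Standard for this data family and necessary for stable small-scale
  training.
- **Ablation variant set.**  The upstream ablation table lists six
  rows, but two of them ("5-stage with the composite loss" appearing
  twice) describe the same configuration.  The harness keeps six rows
  by treating the second occurrence (`vnet5_lcft_rerun`) as an
  independent replicate.
- **Five-stage comparison variants** append a stage with 3
  convolutions and doubled filters (256 at paper scale), matching the
  "each deeper stage doubles" convention the four-stage schedule
  implies.

## The phantom generator: what a green test establishes

Real BraTS data cannot ship with the package, so every end-to-end test
runs on deterministic phantoms: an ellipsoidal "brain" with smooth
low-frequency texture, a nested three-compartment tumor (edema shell,
core shell, enhancing center — raw labels 2/1/4) strictly inside the
brain, modality-dependent contrast (edema brightest on FLAIR/T2, the
enhancing center brightest on T1CE), additive Gaussian noise
(sd 0.05 on a ~0–1 intensity scale) confined to brain voxels, and
exact-zero background.  Tumor size defaults to 2–10% of brain volume
(8–15% in training fixtures so every compartment is populated at
reduced resolution).  Generation is bit-deterministic given
`(seed, case_index)`.

The phantoms deliberately exhibit the *statistical* structure the
method assumes — nested multi-class labels, multi-modal contrast,
noise — but none of the hard parts of real MRI: no bias fields,
no scanner artifacts, no lesion-shape realism, no inter-patient
heterogeneity.  A green training test therefore establishes that the
losses, gradients, optimizer and data plumbing work and that the
network can fit a learnable signal; it does not establish clinical
segmentation quality, and the published headline metrics
(Dice 0.99287 etc.) are out of reach without the full external
dataset and GPU-scale training.  Those published scalars are also
internally inconsistent (Jaccard 0.99642 > Dice 0.99287 is impossible
for a single confusion table), so this implementation enforces the
true ordering `jaccard <= dice` and never targets those numbers.

The overfit fixture (the trainability test) uses learning rate 3e-3
rather than the published 2e-4: the published rate is tuned for
30 epochs over 1,800 slices, while the fixture must overfit 8 slices
within 300 optimizer steps on one CPU.  The default configuration is
unchanged.

## Known limitations

- Pure-R/Rcpp training is orders of magnitude slower than a GPU
  framework; paper-scale training (192×192, 1,800 slices, 30 epochs)
  is architecturally supported but practically out of scope.
- Checkpoints serialize parameters with R's native serialization plus
  a JSON architecture spec; they are not interchangeable with other
  frameworks.
- The NIfTI codec covers the single-file NIfTI-1 subset this pipeline
  emits and reads (3-D, five datatypes, slope/intercept scaling); it
  is cross-checked against nibabel in the tests but is not a general
  neuroimaging I/O library.
- The one-way ANOVA helper is provided as a utility for comparing
  model groups; the exact grouping behind the published F = 3.1398,
  p = 0.0461 is not recoverable and is not reproduced.
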