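# vnetseg

Multi-class brain-tumor segmentation of multi-modal MRI in pure
R/Rcpp: a four-stage 2D V-Net-style encoder-decoder whose fifth stage
is replaced by a *context-boosting bottleneck* (2×2 max pooling →
a wide 500-filter convolution → learned ×2 upsampling), trained with a
composite **Log-Cosh-Focal-Tversky (LCFT)** loss on differentiable
soft confusion counts.

The package is aimed at methods work on segmentation losses and
compact encoder-decoder architectures: it contains the full pipeline —
BraTS-style NIfTI I/O and preprocessing, a deterministic multi-modal
phantom generator (so everything is testable without any download), a
Nadam training loop with checkpointing, a six-variant ablation
harness, one-way ANOVA model comparison and a CLI — with no
deep-learning framework dependency.  Convolutions, transpose
convolutions, max pooling, PReLU, dropout, softmax and all backward
passes are implemented in the package and verified against finite
differences in the test suite.

## The model and loss

Inputs are four co-registered modalities (T1, T1CE, T2, FLAIR),
z-scored per volume, center-cropped 240→192 and stacked as channels.
Labels follow the raw BraTS convention {0, 1, 2, 4}, remapped to
contiguous classes 0–3.

Encoder stages hold 1/2/3/3 convolutions at 16/32/64/128 filters with
residual element-wise sums and stride-2 down-convolutions.  The
deepest feature map passes through the bottleneck instead of a fifth
stage; the decoder mirrors the encoder with transpose-convolution
upsampling and skip concatenation (decoder stages run at twice their
encoder counterpart's depth); a 1×1 convolution + per-pixel softmax
yields 4-class probabilities.

With soft counts `TP_c = Σ p·g`, `FP_c = Σ p(1−g)`, `FN_c = Σ (1−p)g`,
Dice `D`, Tversky index `TI` (α = 0.7, β = 0.3) and Jaccard `J`:

```
L = 0.6·log cosh(1 − D) + 0.2·(1 − TI)^0.75 + 0.2·(1 − J)
```

Training uses Nadam at learning rate 2e-4 (the published setting);
metrics are reported from hard argmax counts pooled over the dataset,
with `jaccard ≤ dice` guaranteed (the implementation enforces the
mathematically required ordering).

## Worked example

Generate a small phantom cohort, train the reduced proposed model on
one case and evaluate on another:

```r
library(vnetseg)

cfg <- phantom_config(shape = c(64, 64, 16), n_cases = 2,
                      tumor_fraction_range = c(0.08, 0.15),
                      noise_sd = 0.05, seed = 3)
train <- preprocess_case(generate_phantom_case(cfg, 1),
                         slice_window = c(4, 12), crop_size = 64)
test  <- preprocess_case(generate_phantom_case(cfg, 2),
                         slice_window = c(4, 12), crop_size = 64)

model <- build_segmentation_model(variant_spec("test", 4, TRUE), seed = 7)
tc <- training_config(learning_rate = 1e-3, epochs = 300, batch_size = 8,
                      seed = 7, max_steps = 300, target_dice = 0.9,
                      eval_every = 20)
res <- train_model(model, train, test, tc)
tail(res$history, 1)
#>   epoch train_loss train_dice   val_loss  val_dice
#> 7   140 0.03631837   0.951027 0.08566891 0.8350388

evaluate_model(res$model, test)
#> metrics over 8 slices: loss 0.08567  dice 0.8350  jaccard 0.7183  tversky 0.8531  accuracy 0.9888
```

Reading the numbers: by step 140 the reduced model has fitted its 8
training slices to a foreground Dice of 0.95 (the learnability
property the acceptance tests rely on) and early-stopped past the 0.9
target; the held-out phantom case scores 0.84, since both cases share
the generator's contrast statistics.  `dice` / `jaccard` / `tversky`
are macro means over the three tumor classes from one pooled
confusion table; `accuracy` is per-pixel and dominated by background.
The full published
configuration (192×192, 1,800 slices, 30 epochs) is expressed by
`default_run_config("paper")` but needs GPU-scale compute to be
practical.

The six-row ablation (baseline 5-stage Dice-loss V-Net → proposed
4-stage + bottleneck + LCFT) runs via `run_ablation()`, and
`one_way_anova()` compares metric groups (`F = 1.5, p = 0.288` on
`list(c(1,2,3), c(2,3,4))`).

A command-line pipeline wraps the same functions:

```sh
Rscript inst/cli/vnetseg synth --cases 2 --shape test --out cohort/
Rscript inst/cli/vnetseg preprocess --shape test --cases cohort --out slices.rds
Rscript inst/cli/vnetseg train --shape test --slices slices.rds --out ckpt/
Rscript inst/cli/vnetseg predict --shape test --checkpoint ckpt/best_model.rds \
        --case cohort/case_001 --out pred.nii.gz
```

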