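# Network construction: shapes, softmax normalization, parameter
# accounting, CBF block, variants, gradient flow.

test_that("architecture_spec validates its invariants", {
  expect_error(architecture_spec(convs_per_stage = c(1, 2, 3)), "n_stages")
  expect_error(architecture_spec(input_side = 100), "divisible")
  expect_error(architecture_spec(kernel_size = 4), "odd")
  expect_error(architecture_spec(n_classes = 1), "at least 2")
  expect_error(architecture_spec(dropout_rate = 1), "dropout")
  sp <- architecture_spec()
  expect_identical(sp$filters_per_stage[sp$n_stages], 128L)
})

test_that("CBF block: pooling/upsampling shape contract", {
  blk <- build_cbf_block(8L, 10L, out_channels = 5L, seed = 1)
  x <- array(rnorm(4 * 4 * 8), c(4, 4, 8))
  out <- cbf_forward(blk, x, intermediate = TRUE)
  expect_identical(dim(out$intermediate), c(2L, 2L, 10L))
  expect_identical(dim(out$y), c(4L, 4L, 5L))
  # paper-scale arithmetic: 12x12x128 -> 6x6x500 -> 12x12x256
  blk2 <- build_cbf_block(128L, 500L, seed = 1)
  x2 <- array(rnorm(12 * 12 * 128), c(12, 12, 128))
  out2 <- cbf_forward(blk2, x2, intermediate = TRUE)
  expect_identical(dim(out2$intermediate), c(6L, 6L, 500L))
  expect_identical(dim(out2$y), c(12L, 12L, 256L))
  # odd spatial side violates the pooling contract
  x3 <- array(rnorm(5 * 5 * 8), c(5, 5, 8))
  expect_error(cbf_forward(blk, x3), "even")
})

test_that("model maps inputs to normalized probability maps", {
  m <- build_segmentation_model(tiny_spec(), seed = 2)
  x <- array(rnorm(2 * 8 * 8 * 2), c(2, 8, 8, 2))
  p <- model_predict(m, x)
  expect_identical(dim(p), c(2L, 8L, 8L, 3L))
  sums <- apply(p, c(1, 2, 3), sum)
  expect_true(all(abs(sums - 1) < 1e-5))
  expect_true(all(p >= 0 & p <= 1))
  # n_classes = 2 gives a two-channel head
  sp2 <- tiny_spec(); sp2$n_classes <- 2L
  m2 <- build_segmentation_model(sp2, seed = 2)
  expect_identical(dim(model_predict(m2, array(rnorm(128), c(8, 8, 2)))),
                   c(8L, 8L, 2L))
  expect_error(model_predict(m, array(0, c(8, 8, 5))), "channels")
})

# Independent parameter-count oracle: closed-form k^2*cin*cout + cout
# per conv (+cout PReLU slopes where present), summed layer by layer
# from the declared architecture - never from the model object.
hand_count <- function(spec) {
  k <- spec$kernel_size; f <- spec$filters_per_stage; n <- spec$n_stages
  conv <- function(kk, cin, cout, prelu = TRUE)
    kk * kk * cin * cout + cout + if (prelu) cout else 0
  total <- 0
  cin <- spec$in_channels
  for (i in seq_len(n)) {
    ch <- cin
    for (j in seq_len(spec$convs_per_stage[i])) {
      total <- total + conv(k, ch, f[i]); ch <- f[i]
    }
    if (cin != f[i]) total <- total + conv(1, cin, f[i], prelu = FALSE)
    if (i < n) { total <- total + conv(2, f[i], f[i + 1]); cin <- f[i + 1] }
  }
  below <- f[n]
  if (spec$cbf_enabled) {
    total <- total + conv(k, f[n], spec$cbf_filters) +
      conv(2, spec$cbf_filters, spec$cbf_out_channels)
    below <- spec$cbf_out_channels
  }
  for (j in rev(seq_len(n - 1))) {
    total <- total + conv(2, below, f[j])
    for (m in seq_len(spec$convs_per_stage[j]))
      total <- total + conv(k, 2 * f[j], 2 * f[j])
    below <- 2 * f[j]
  }
  total + conv(1, below, spec$n_classes, prelu = FALSE)
}

test_that("trainable parameter count matches the hand-count oracle", {
  for (sp in list(tiny_spec(),
                  variant_spec("test", 4, TRUE),
                  variant_spec("test", 5, FALSE),
                  variant_spec("paper", 4, TRUE))) {
    m <- build_segmentation_model(sp, seed = 1)
    expect_identical(count_trainable_parameters(m), as.integer(hand_count(sp)))
  }
  # frozen model counts zero
  m <- freeze_layers(build_segmentation_model(tiny_spec(), seed = 1))
  expect_identical(count_trainable_parameters(m), 0L)
})

test_that("parameter monotonicity: dropping stage 5 shrinks, CBF adds its block", {
  p4cbf <- count_trainable_parameters(
    build_segmentation_model(variant_spec("test", 4, TRUE), seed = 1))
  p4 <- count_trainable_parameters(
    build_segmentation_model(variant_spec("test", 4, FALSE), seed = 1))
  p5 <- count_trainable_parameters(
    build_segmentation_model(variant_spec("test", 5, FALSE), seed = 1))
  expect_lt(p4, p5)
  sp <- variant_spec("test", 4, TRUE)
  cbf_params <- 3 * 3 * sp$filters_per_stage[4] * sp$cbf_filters +
    2 * sp$cbf_filters +
    2 * 2 * sp$cbf_filters * sp$cbf_out_channels + 2 * sp$cbf_out_channels
  # enabling CBF also widens the first decoder tconv input; account for it
  f4 <- sp$filters_per_stage[4]; f3 <- sp$filters_per_stage[3]
  tconv_delta <- (sp$cbf_out_channels - f4) * 2 * 2 * f3
  expect_identical(p4cbf - p4, as.integer(cbf_params + tconv_delta))
})

test_that("single 3x3 conv 4->16 with bias holds 592 parameters", {
  p <- vnetseg:::.init_conv(3 * 3 * 4, 16, prelu = FALSE)
  expect_identical(length(p$W) + length(p$b), 592L)
})

test_that("all six variants build; unknown names error", {
  expect_identical(length(variant_names()), 6L)
  for (vn in variant_names()) {
    v <- build_variant(vn, "test", seed = 1)
    expect_s3_class(v$model, "segmentation_model")
    expect_s3_class(v$loss, "loss_config")
  }
  b <- build_variant("baseline_vnet5_dice", "test", seed = 1)
  expect_identical(b$spec$n_stages, 5L)
  expect_false(b$spec$cbf_enabled)
  expect_identical(b$loss$kind, "dice")
  pr <- build_variant("proposed_vnet4_lcft_cbf", "paper", seed = 1)
  expect_identical(unclass(pr$spec), unclass(architecture_spec()))
  expect_identical(pr$loss$kind, "lcft")
  expect_error(build_variant("vnet6_x", "test"), "unknown variant")
})

test_that("gradient flows to every trainable parameter", {
  set.seed(9)
  m <- build_segmentation_model(tiny_spec(), seed = 3)
  sl <- list(slice_sample(array(rnorm(128), c(8, 8, 2)),
                          matrix(sample(0:2, 64, TRUE), 8, 8),
                          n_classes = 3))
  bl <- vnetseg:::.batch_loss_grad(m, sl, loss_config())
  expect_setequal(names(bl$grads), names(m$params))
  for (nm in names(bl$grads)) for (fld in names(bl$grads[[nm]])) {
    g <- bl$grads[[nm]][[fld]]
    expect_true(all(is.finite(g)))
    expect_gt(max(abs(g)), 0)
  }
})

test_that("full-model backprop matches finite differences", {
  set.seed(10)
  m <- build_segmentation_model(tiny_spec(), seed = 4)
  x <- array(rnorm(8 * 8 * 2), c(8, 8, 2))
  oh <- one_hot(matrix(sample(0:2, 64, TRUE), 8, 8), 3)
  cfg <- loss_config(smooth = 1e-3)
  loss_of <- function(model)
    lcft_total_loss(vnetseg:::.forward_sample(model, x)$probs, oh, cfg)
  fw <- vnetseg:::.forward_sample(m, x)
  gz <- vnetseg:::.softmax_bwd(fw$probs, lcft_gradient(fw$probs, oh, cfg))
  grads <- vnetseg:::.backward_sample(m, fw, gz)
  for (nm in c("enc1_conv1", "enc1_proj", "down1", "cbf_conv", "cbf_up",
               "dec1_up", "dec1_conv1", "head")) {
    fld <- "W"
    th <- m$params[[nm]][[fld]]
    for (i in sample(length(th), 2)) {
      fd <- fd_grad(function(v) {
        m2 <- m; m2$params[[nm]][[fld]] <- array(v, dim(th))
        loss_of(m2)
      }, th, i)
      an <- grads[[nm]][[fld]][i]
      expect_equal(an, fd, tolerance = 1e-4,
                   label = sprintf("grad %s$W[%d]", nm, i))
    }
  }
})
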