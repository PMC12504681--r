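# Shared fixtures and independent oracles.

# Tiny architecture that still exercises every structural element
# (residual projection, down/up sampling, CBF, concat skips).
tiny_spec <- function(...) {
  architecture_spec(n_stages = 2L, convs_per_stage = c(1L, 2L),
                    filters_per_stage = c(3L, 5L), cbf_filters = 7L,
                    cbf_out_channels = 6L, in_channels = 2L, n_classes = 3L,
                    input_side = 8L, dropout_rate = 0, ...)
}

# Reduced-size phantom slices for training tests.
phantom_slices <- function(n_cases = 1, seed = 3, shape = c(64, 64, 16),
                           window = c(4, 12),
                           tumor_fraction_range = c(0.08, 0.15)) {
  cfg <- phantom_config(shape = shape, n_cases = n_cases,
                        tumor_fraction_range = tumor_fraction_range,
                        noise_sd = 0.05, seed = seed)
  out <- list()
  for (ci in seq_len(n_cases))
    out <- c(out, preprocess_case(generate_phantom_case(cfg, ci),
                                  slice_window = window,
                                  crop_size = shape[1]))
  out
}

# Independent brute-force oracle: per-pixel counting loop over hard
# label maps.  Deliberately scalar and naive.
brute_force_counts <- function(pred, truth, n_classes) {
  tp <- fp <- fn <- tn <- rep(0, n_classes)
  for (i in seq_along(pred)) {
    for (c in 0:(n_classes - 1)) {
      p <- pred[i] == c
      g <- truth[i] == c
      if (p && g) tp[c + 1] <- tp[c + 1] + 1
      else if (p && !g) fp[c + 1] <- fp[c + 1] + 1
      else if (!p && g) fn[c + 1] <- fn[c + 1] + 1
      else tn[c + 1] <- tn[c + 1] + 1
    }
  }
  list(tp = tp, fp = fp, fn = fn, tn = tn)
}

# Random valid probability map + one-hot truth.
random_probs <- function(side, nc, seed) {
  set.seed(seed)
  z <- array(rnorm(side * side * nc), c(side, side, nc))
  zm <- matrix(z, side * side, nc)
  e <- exp(zm)
  probs <- array(e / rowSums(e), c(side, side, nc))
  mask <- matrix(sample(0:(nc - 1), side * side, TRUE), side, side)
  list(probs = probs, mask = mask, onehot = one_hot(mask, nc))
}

# Central finite difference of f at x (numeric vector/array), index i.
fd_grad <- function(f, x, i, eps = 1e-6) {
  xp <- x; xp[i] <- x[i] + eps
  xm <- x; xm[i] <- x[i] - eps
  (f(xp) - f(xm)) / (2 * eps)
}

expect_rel_equal <- function(a, b, tol = 1e-6) {
  expect_lt(max(abs(a - b)) / max(1, max(abs(b))), tol)
}
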