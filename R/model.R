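#' Architecture specification
#'
#' Fully determines the segmentation network: a V-shaped
#' encoder-decoder with `n_stages` encoder stages (1/2/3/3 convolutions
#' per stage by default, residual element-wise sums, stride-2
#' down-convolutions), an optional context-boosting bottleneck (2x2 max
#' pooling followed by a wide `cbf_filters` convolution and a learned
#' x2 upsampling) after the deepest stage, `n_stages - 1`
#' transpose-convolution decoder stages whose channel depth is twice
#' their encoder counterpart (skip concatenation), and a 1x1
#' convolution + per-pixel softmax head.
#'
#' @param n_stages number of encoder stages (>= 2; default 4, 5 for
#'   the ablation baselines).
#' @param convs_per_stage integer vector, convolutions per stage.
#' @param filters_per_stage integer vector, channels per stage; the
#'   last entry is the encoder output depth (128 by default).
#' @param cbf_filters filter count of the bottleneck convolution
#'   (default 500).
#' @param cbf_enabled logical, include the context-boosting bottleneck.
#' @param cbf_out_channels channels emitted by the bottleneck's
#'   upsampling back to the decoder (default 256).
#' @param kernel_size odd convolution kernel size (default 3).
#' @param in_channels input channels (4 MRI modalities).
#' @param n_classes output classes (>= 2; default 4).
#' @param dropout_rate dropout rate applied after each encoder stage.
#' @param input_side square input side; must be divisible by
#'   `2^n_stages` so every down/upsampling (including the bottleneck
#'   pooling) is exact.
#' @return an `architecture_spec` object.
#' @export
architecture_spec <- function(n_stages = 4L,
                              convs_per_stage = c(1L, 2L, 3L, 3L),
                              filters_per_stage = c(16L, 32L, 64L, 128L),
                              cbf_filters = 500L,
                              cbf_enabled = TRUE,
                              cbf_out_channels = 256L,
                              kernel_size = 3L,
                              in_channels = 4L,
                              n_classes = 4L,
                              dropout_rate = 0.1,
                              input_side = 192L) {
  n_stages <- as.integer(n_stages)
  if (n_stages < 2L) stop("n_stages must be at least 2")
  if (length(convs_per_stage) != n_stages ||
      length(filters_per_stage) != n_stages)
    stop("convs_per_stage and filters_per_stage must have n_stages entries")
  if (any(convs_per_stage < 1L) || any(filters_per_stage < 1L))
    stop("stage sizes must be positive")
  if (kernel_size %% 2L != 1L) stop("kernel_size must be odd")
  if (n_classes < 2L) stop("n_classes must be at least 2")
  if (dropout_rate < 0 || dropout_rate >= 1)
    stop("dropout_rate must lie in [0, 1)")
  if (input_side %% (2^n_stages) != 0)
    stop("input_side must be divisible by 2^n_stages (here ", 2^n_stages, ")")
  if (cbf_filters < 1L || cbf_out_channels < 1L)
    stop("bottleneck channel counts must be positive")
  structure(list(n_stages = n_stages,
                 convs_per_stage = as.integer(convs_per_stage),
                 filters_per_stage = as.integer(filters_per_stage),
                 cbf_filters = as.integer(cbf_filters),
                 cbf_enabled = isTRUE(cbf_enabled),
                 cbf_out_channels = as.integer(cbf_out_channels),
                 kernel_size = as.integer(kernel_size),
                 in_channels = as.integer(in_channels),
                 n_classes = as.integer(n_classes),
                 dropout_rate = dropout_rate,
                 input_side = as.integer(input_side)),
            class = "architecture_spec")
}

# Variance-scaling (fan-in) initialization, He-style for PReLU layers.
.init_conv <- function(fan_in, cout, prelu = TRUE) {
  p <- list(W = matrix(rnorm(fan_in * cout, sd = sqrt(2 / fan_in)),
                       fan_in, cout),
            b = rep(0, cout))
  if (prelu) p$a <- rep(0.25, cout)
  p
}

.init_tconv <- function(cin, k, cout) {
  list(W = matrix(rnorm(cin * k * k * cout, sd = sqrt(2 / cin)),
                  cin, k * k * cout),
       b = rep(0, cout),
       a = rep(0.25, cout))
}

#' Build the context-boosting bottleneck block
#'
#' 2x2 max pooling (halving the spatial side to limit the cost of the
#' wide convolution that follows) -> `cbf_filters` 3x3 convolution with
#' PReLU -> learned x2 transpose-convolution upsampling back to the
#' input spatial size with `out_channels` output channels.
#'
#' @param in_channels input channel count.
#' @param cbf_filters filters of the wide convolution (500 at paper
#'   scale).
#' @param out_channels channels after upsampling (default 256).
#' @param kernel_size convolution kernel size.
#' @param seed optional RNG seed for weight initialization.
#' @return a `cbf_block` object usable with [cbf_forward()].
#' @export
build_cbf_block <- function(in_channels, cbf_filters, out_channels = 256L,
                            kernel_size = 3L, seed = NULL) {
  if (in_channels < 1L || cbf_filters < 1L || out_channels < 1L)
    stop("channel counts must be positive")
  if (!is.null(seed)) set.seed(seed)
  k <- as.integer(kernel_size)
  params <- list(
    cbf_conv = .init_conv(k * k * in_channels, cbf_filters),
    cbf_up = .init_tconv(cbf_filters, 2L, out_channels))
  structure(list(params = params, in_channels = as.integer(in_channels),
                 cbf_filters = as.integer(cbf_filters),
                 out_channels = as.integer(out_channels),
                 kernel_size = k),
            class = "cbf_block")
}

.cbf_fwd <- function(params, x, kernel_size) {
  pad <- (kernel_size - 1L) %/% 2L
  mp <- .maxpool_fwd(x)
  cc <- .conv_fwd(mp$y, params$cbf_conv, kernel_size, 1L, pad)
  pp <- .prelu_fwd(cc$y, params$cbf_conv$a)
  tc <- .tconv_fwd(pp$y, params$cbf_up, 2L)
  tq <- .prelu_fwd(tc$y, params$cbf_up$a)
  list(y = tq$y,
       cache = list(pool = mp$cache, conv = cc$cache, prelu1 = pp$cache,
                    tconv = tc$cache, prelu2 = tq$cache,
                    pooled = mp$y))
}

.cbf_bwd <- function(params, cache, gy) {
  g2 <- .prelu_bwd(gy, params$cbf_up$a, cache$prelu2)
  gt <- .tconv_bwd(g2$gx, params$cbf_up, cache$tconv)
  g1 <- .prelu_bwd(gt$gx, params$cbf_conv$a, cache$prelu1)
  gc <- .conv_bwd(g1$gx, params$cbf_conv, cache$conv)
  gx <- .maxpool_bwd(gc$gx, cache$pool)
  list(gx = gx,
       grads = list(cbf_conv = list(W = gc$gW, b = gc$gb, a = g1$ga),
                    cbf_up = list(W = gt$gW, b = gt$gb, a = g2$ga)))
}

#' Apply a context-boosting block
#'
#' @param block a [build_cbf_block()] object.
#' @param x `(H, W, C)` input array; `H` and `W` must be even.
#' @param intermediate if `TRUE`, also return the pooled+convolved
#'   intermediate tensor (for shape inspection).
#' @return the `(H, W, out_channels)` output array, or a list with
#'   `y` and `intermediate`.
#' @export
cbf_forward <- function(block, x, intermediate = FALSE) {
  if (dim(x)[3] != block$in_channels)
    stop("input has ", dim(x)[3], " channels; block expects ",
         block$in_channels)
  fw <- .cbf_fwd(block$params, x, block$kernel_size)
  if (intermediate) {
    pad <- (block$kernel_size - 1L) %/% 2L
    cc <- .conv_fwd(fw$cache$pooled, block$params$cbf_conv,
                    block$kernel_size, 1L, pad)
    list(y = fw$y, intermediate = cc$y)
  } else fw$y
}

#' Build the segmentation network
#'
#' Instantiates all trainable parameters of the network described by an
#' [architecture_spec()].  The returned model maps
#' `(input_side, input_side, in_channels)` images (or batches with a
#' leading batch dimension) to per-pixel class probabilities of the
#' same spatial size; see [model_predict()].
#'
#' @param spec an [architecture_spec()].
#' @param seed optional RNG seed for reproducible initialization.
#' @return a `segmentation_model` object.
#' @export
build_segmentation_model <- function(spec = architecture_spec(), seed = NULL) {
  stopifnot(inherits(spec, "architecture_spec"))
  if (!is.null(seed)) set.seed(seed)
  k <- spec$kernel_size
  n <- spec$n_stages
  f <- spec$filters_per_stage
  params <- list()
  cin <- spec$in_channels
  for (i in seq_len(n)) {
    ch <- cin
    for (j in seq_len(spec$convs_per_stage[i])) {
      params[[sprintf("enc%d_conv%d", i, j)]] <- .init_conv(k * k * ch, f[i])
      ch <- f[i]
    }
    if (cin != f[i])   # 1x1 projection so the residual sum type-checks
      params[[sprintf("enc%d_proj", i)]] <- .init_conv(cin, f[i],
                                                       prelu = FALSE)
    if (i < n) {
      params[[sprintf("down%d", i)]] <- .init_conv(2L * 2L * f[i], f[i + 1])
      cin <- f[i + 1]
    }
  }
  if (spec$cbf_enabled) {
    params$cbf_conv <- .init_conv(k * k * f[n], spec$cbf_filters)
    params$cbf_up <- .init_tconv(spec$cbf_filters, 2L, spec$cbf_out_channels)
    c_below <- spec$cbf_out_channels
  } else {
    c_below <- f[n]
  }
  for (j in rev(seq_len(n - 1L))) {
    params[[sprintf("dec%d_up", j)]] <- .init_tconv(c_below, 2L, f[j])
    ch <- 2L * f[j]
    for (m in seq_len(spec$convs_per_stage[j]))
      params[[sprintf("dec%d_conv%d", j, m)]] <- .init_conv(k * k * ch, ch)
    c_below <- ch
  }
  params$head <- .init_conv(c_below, spec$n_classes, prelu = FALSE)
  structure(list(spec = spec, params = params, frozen = character()),
            class = "segmentation_model")
}

#' @export
print.segmentation_model <- function(x, ...) {
  sp <- x$spec
  cat(sprintf(
    "segmentation_model: %d stages, filters [%s], CBF %s, %d classes\n",
    sp$n_stages, paste(sp$filters_per_stage, collapse = ","),
    if (sp$cbf_enabled) sprintf("on (%d filters)", sp$cbf_filters) else "off",
    sp$n_classes))
  cat(sprintf("  input %dx%dx%d, %d trainable parameters\n",
              sp$input_side, sp$input_side, sp$in_channels,
              count_trainable_parameters(x)))
  invisible(x)
}

# Forward pass for one (H, W, C) sample.  Returns probs, logits and the
# caches needed by .backward_sample.
.forward_sample <- function(model, x, training = FALSE) {
  sp <- model$spec
  P <- model$params
  k <- sp$kernel_size
  pad <- (k - 1L) %/% 2L
  n <- sp$n_stages
  cache <- list()
  skips <- vector("list", n)
  h <- x
  for (i in seq_len(n)) {
    stage_in <- h
    for (j in seq_len(sp$convs_per_stage[i])) {
      nm <- sprintf("enc%d_conv%d", i, j)
      cc <- .conv_fwd(h, P[[nm]], k, 1L, pad)
      pp <- .prelu_fwd(cc$y, P[[nm]]$a)
      cache[[nm]] <- list(conv = cc$cache, prelu = pp$cache)
      h <- pp$y
    }
    pn <- sprintf("enc%d_proj", i)
    if (!is.null(P[[pn]])) {
      pc <- .conv_fwd(stage_in, P[[pn]], 1L, 1L, 0L)
      cache[[pn]] <- pc$cache
      h <- h + pc$y
    } else {
      h <- h + stage_in
    }
    if (training && sp$dropout_rate > 0) {
      dr <- .dropout_fwd(h, sp$dropout_rate)
      cache[[sprintf("drop%d", i)]] <- dr$cache
      h <- dr$y
    }
    skips[[i]] <- h
    if (i < n) {
      dn <- sprintf("down%d", i)
      dc <- .conv_fwd(h, P[[dn]], 2L, 2L, 0L)
      dp <- .prelu_fwd(dc$y, P[[dn]]$a)
      cache[[dn]] <- list(conv = dc$cache, prelu = dp$cache)
      h <- dp$y
    }
  }
  if (sp$cbf_enabled) {
    cf <- .cbf_fwd(P, h, k)
    cache$cbf <- cf$cache
    h <- cf$y
  }
  for (j in rev(seq_len(n - 1L))) {
    un <- sprintf("dec%d_up", j)
    tc <- .tconv_fwd(h, P[[un]], 2L)
    tq <- .prelu_fwd(tc$y, P[[un]]$a)
    cache[[un]] <- list(tconv = tc$cache, prelu = tq$cache)
    d <- dim(tq$y)
    cat_in <- array(c(tq$y, skips[[j]]), c(d[1], d[2], d[3] + dim(skips[[j]])[3]))
    h <- cat_in
    for (m in seq_len(sp$convs_per_stage[j])) {
      nm <- sprintf("dec%d_conv%d", j, m)
      cc <- .conv_fwd(h, P[[nm]], k, 1L, pad)
      pp <- .prelu_fwd(cc$y, P[[nm]]$a)
      cache[[nm]] <- list(conv = cc$cache, prelu = pp$cache)
      h <- pp$y
    }
    h <- h + cat_in
  }
  hc <- .conv_fwd(h, P$head, 1L, 1L, 0L)
  cache$head <- hc$cache
  probs <- .softmax_hw(hc$y)
  list(probs = probs, logits = hc$y, cache = cache)
}

# Backward pass for one sample given dL/dlogits; returns grads named
# like model$params (each list(W, b[, a])).
.backward_sample <- function(model, fw, glogits) {
  sp <- model$spec
  P <- model$params
  n <- sp$n_stages
  cache <- fw$cache
  grads <- list()
  hb <- .conv_bwd(glogits, P$head, cache$head)
  grads$head <- list(W = hb$gW, b = hb$gb)
  g <- hb$gx
  gskip <- vector("list", n)
  for (j in seq_len(n - 1L)) {
    # reverse of decoder stage j: residual add, conv chain, split, up
    g_cat <- g                                # direct residual branch
    gc <- g
    for (m in rev(seq_len(sp$convs_per_stage[j]))) {
      nm <- sprintf("dec%d_conv%d", j, m)
      pb <- .prelu_bwd(gc, P[[nm]]$a, cache[[nm]]$prelu)
      cb <- .conv_bwd(pb$gx, P[[nm]], cache[[nm]]$conv)
      grads[[nm]] <- list(W = cb$gW, b = cb$gb, a = pb$ga)
      gc <- cb$gx
    }
    g_cat <- g_cat + gc
    fj <- sp$filters_per_stage[j]
    d <- dim(g_cat)
    g_up <- g_cat[, , seq_len(d[3] - fj), drop = FALSE]
    gs <- g_cat[, , d[3] - fj + seq_len(fj), drop = FALSE]
    gskip[[j]] <- gs
    un <- sprintf("dec%d_up", j)
    pb <- .prelu_bwd(g_up, P[[un]]$a, cache[[un]]$prelu)
    tb <- .tconv_bwd(pb$gx, P[[un]], cache[[un]]$tconv)
    grads[[un]] <- list(W = tb$gW, b = tb$gb, a = pb$ga)
    g <- tb$gx
  }
  if (sp$cbf_enabled) {
    cb <- .cbf_bwd(P, cache$cbf, g)
    grads$cbf_conv <- cb$grads$cbf_conv
    grads$cbf_up <- cb$grads$cbf_up
    g <- cb$gx
  }
  for (i in rev(seq_len(n))) {
    if (i < n) {
      dn <- sprintf("down%d", i)
      pb <- .prelu_bwd(g, P[[dn]]$a, cache[[dn]]$prelu)
      db <- .conv_bwd(pb$gx, P[[dn]], cache[[dn]]$conv)
      grads[[dn]] <- list(W = db$gW, b = db$gb, a = pb$ga)
      g <- db$gx
      g <- g + gskip[[i]]
    }
    dnm <- sprintf("drop%d", i)
    if (!is.null(cache[[dnm]])) g <- g * cache[[dnm]]
    # residual split: conv chain branch + identity/projection branch
    gc <- g
    for (j in rev(seq_len(sp$convs_per_stage[i]))) {
      nm <- sprintf("enc%d_conv%d", i, j)
      pb <- .prelu_bwd(gc, P[[nm]]$a, cache[[nm]]$prelu)
      cb <- .conv_bwd(pb$gx, P[[nm]], cache[[nm]]$conv)
      grads[[nm]] <- list(W = cb$gW, b = cb$gb, a = pb$ga)
      gc <- cb$gx
    }
    pn <- sprintf("enc%d_proj", i)
    if (!is.null(P[[pn]])) {
      jb <- .conv_bwd(g, P[[pn]], cache[[pn]])
      grads[[pn]] <- list(W = jb$gW, b = jb$gb)
      g <- gc + jb$gx
    } else {
      g <- gc + g
    }
  }
  grads
}

#' Predict class probabilities
#'
#' Runs the network on one `(H, W, C)` image or a `(B, H, W, C)` batch
#' and returns per-pixel class probabilities of the same spatial shape
#' with `n_classes` channels; each pixel's probabilities sum to 1.
#'
#' @param model a [build_segmentation_model()] object.
#' @param x input array.
#' @return probability array `(H, W, n_classes)` or
#'   `(B, H, W, n_classes)`.
#' @export
model_predict <- function(model, x) {
  d <- dim(x)
  sp <- model$spec
  if (length(d) == 3) {
    .check_input_dims(sp, d)
    return(.forward_sample(model, x, training = FALSE)$probs)
  }
  if (length(d) != 4) stop("input must be (H, W, C) or (B, H, W, C)")
  .check_input_dims(sp, d[-1])
  out <- array(0, c(d[1], d[2], d[3], sp$n_classes))
  for (b in seq_len(d[1]))
    out[b, , , ] <- .forward_sample(model,
                                    array(x[b, , , ], d[-1]),
                                    training = FALSE)$probs
  out
}

.check_input_dims <- function(sp, d) {
  if (d[3] != sp$in_channels)
    stop("input has ", d[3], " channels; model expects ", sp$in_channels)
  if (d[1] %% (2^sp$n_stages) != 0 || d[2] %% (2^sp$n_stages) != 0)
    stop("spatial dims must be divisible by 2^n_stages")
  invisible(TRUE)
}

#' Count trainable parameters
#'
#' Exact number of learnable scalars (weights, biases, PReLU slopes)
#' over all layers not marked frozen.
#'
#' @param model a segmentation model.
#' @return nonnegative integer.
#' @export
count_trainable_parameters <- function(model) {
  tot <- 0
  for (nm in names(model$params)) {
    if (nm %in% model$frozen) next
    tot <- tot + sum(vapply(model$params[[nm]], length, 0L))
  }
  as.integer(tot)
}

#' Freeze layers
#'
#' Marks layers as non-trainable; frozen layers are excluded from
#' [count_trainable_parameters()] and from optimizer updates.
#'
#' @param model a segmentation model.
#' @param layers layer names to freeze (default: all).
#' @export
freeze_layers <- function(model, layers = names(model$params)) {
  unknown <- setdiff(layers, names(model$params))
  if (length(unknown)) stop("unknown layers: ", paste(unknown, collapse = ", "))
  model$frozen <- union(model$frozen, layers)
  model
}
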