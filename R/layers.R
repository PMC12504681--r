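# Low-level differentiable layer primitives.  Every *_fwd returns
# list(y, cache); every *_bwd takes (gy, params, cache) and returns the
# input gradient plus parameter gradients.  Tensors are (H, W, C)
# arrays; convolution weights are (k*k*Cin) x Cout matrices so the
# forward pass is a single im2col + matmul.

.conv_fwd <- function(x, p, k, stride, pad) {
  d <- dim(x)
  cols <- im2col_cpp(x, d[1], d[2], d[3], k, stride, pad)
  hout <- (d[1] + 2 * pad - k) %/% stride + 1L
  wout <- (d[2] + 2 * pad - k) %/% stride + 1L
  out <- cols %*% p$W
  out <- sweep(out, 2, p$b, "+")
  list(y = array(out, c(hout, wout, ncol(p$W))),
       cache = list(cols = cols, xdim = d, k = k, stride = stride, pad = pad))
}

.conv_bwd <- function(gy, p, cache) {
  dy <- dim(gy)
  gym <- matrix(gy, dy[1] * dy[2], dy[3])
  gW <- crossprod(cache$cols, gym)
  gb <- colSums(gym)
  gcols <- tcrossprod(gym, p$W)
  gx <- col2im_cpp(gcols, cache$xdim[1], cache$xdim[2], cache$xdim[3],
                   cache$k, cache$stride, cache$pad)
  list(gx = gx, gW = gW, gb = gb)
}

# Transpose convolution, kernel k, stride k (non-overlapping), used for
# exact x2 upsampling with k = 2.  Weights: Cin x (k*k*Cout).
.tconv_fwd <- function(x, p, k = 2L) {
  d <- dim(x)
  cout <- ncol(p$W) %/% (k * k)
  xm <- matrix(x, d[1] * d[2], d[3])
  cols <- xm %*% p$W
  y <- col2im_cpp(cols, d[1] * k, d[2] * k, cout, k, k, 0L)
  y <- sweep(y, 3, p$b, "+")
  list(y = y, cache = list(xm = xm, xdim = d, k = k, cout = cout))
}

.tconv_bwd <- function(gy, p, cache) {
  k <- cache$k
  dy <- dim(gy)
  gcols <- im2col_cpp(gy, dy[1], dy[2], dy[3], k, k, 0L)
  gx <- tcrossprod(gcols, p$W)
  gW <- crossprod(cache$xm, gcols)
  gb <- apply(gy, 3, sum)
  list(gx = array(gx, cache$xdim), gW = gW, gb = gb)
}

# PReLU with one learned slope per channel (kept fully vectorized:
# logical subset-assignment on large arrays dominates the profile).
.prelu_fwd <- function(x, a) {
  d <- dim(x)
  af <- rep(a, each = d[1] * d[2])
  xn <- pmin(x, 0)
  list(y = pmax(x, 0) + af * xn, cache = list(x = x, af = af, xn = xn))
}

.prelu_bwd <- function(gy, a, cache) {
  d <- dim(cache$x)
  pos <- cache$x > 0
  gx <- gy * (cache$af + (1 - cache$af) * pos)
  ga <- colSums(matrix(gy * cache$xn, d[1] * d[2], d[3]))
  list(gx = gx, ga = ga)
}

.maxpool_fwd <- function(x) {
  d <- dim(x)
  if (d[1] %% 2L != 0L || d[2] %% 2L != 0L)
    stop("max pooling requires even spatial dimensions, got ",
         d[1], "x", d[2])
  r <- maxpool2_fwd_cpp(x, d[1], d[2], d[3])
  list(y = r$y, cache = list(idx = r$idx, xdim = d))
}

.maxpool_bwd <- function(gy, cache) {
  maxpool2_bwd_cpp(gy, cache$idx, cache$xdim[1], cache$xdim[2],
                   cache$xdim[3])
}

# Inverted dropout; mask is kept for the backward pass.
.dropout_fwd <- function(x, rate) {
  mask <- array((runif(length(x)) >= rate) / (1 - rate), dim(x))
  list(y = x * mask, cache = mask)
}

# Per-pixel softmax over the channel dimension of an (H, W, C) array.
.softmax_hw <- function(z) {
  d <- dim(z)
  zm <- matrix(z, d[1] * d[2], d[3])
  m <- zm[, 1]
  for (c in seq_len(d[3])[-1]) m <- pmax(m, zm[, c])
  e <- exp(zm - m)
  array(e / rowSums(e), d)
}

# Backward of softmax given dL/dprobs: dL/dz = p * (g - sum(g*p)).
.softmax_bwd <- function(probs, gprobs) {
  d <- dim(probs)
  pm <- matrix(probs, d[1] * d[2], d[3])
  gm <- matrix(gprobs, d[1] * d[2], d[3])
  s <- rowSums(gm * pm)
  array(pm * (gm - s), d)
}
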