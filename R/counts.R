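#' Per-class confusion counts
#'
#' Container for per-class true-positive / false-positive /
#' false-negative / true-negative mass.  Counts may be fractional
#' ("soft" counts, the differentiable substrate of the training loss)
#' or integer ("hard" counts from argmax predictions).  For every class
#' `tp + fn` equals the total ground-truth mass of that class and
#' `tp + fp + fn + tn` equals the number of pixels.
#'
#' @param tp,fp,fn,tn numeric vectors of equal length (one entry per
#'   class), all entries nonnegative.
#' @return an object of class `per_class_counts` with fields `tp`,
#'   `fp`, `fn`, `tn` and `n_classes`.
#' @export
per_class_counts <- function(tp, fp, fn, tn = NULL) {
  tp <- as.numeric(tp); fp <- as.numeric(fp); fn <- as.numeric(fn)
  nc <- length(tp)
  if (length(fp) != nc || length(fn) != nc)
    stop("tp, fp, fn must have one entry per class")
  if (is.null(tn)) tn <- rep(0, nc)
  tn <- as.numeric(tn)
  if (length(tn) != nc) stop("tn must have one entry per class")
  if (any(tp < 0) || any(fp < 0) || any(fn < 0) || any(tn < 0))
    stop("confusion counts must be nonnegative")
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn, n_classes = nc),
            class = "per_class_counts")
}

.as_counts <- function(counts) {
  if (inherits(counts, "per_class_counts")) return(counts)
  if (is.list(counts) && all(c("tp", "fp", "fn") %in% names(counts)))
    return(per_class_counts(counts$tp, counts$fp, counts$fn, counts$tn))
  stop("expected a per_class_counts object")
}

#' @export
print.per_class_counts <- function(x, ...) {
  cat("per_class_counts over", x$n_classes, "classes\n")
  print(data.frame(class = seq_len(x$n_classes) - 1L,
                   tp = x$tp, fp = x$fp, fn = x$fn, tn = x$tn))
  invisible(x)
}

# Coerce an (H, W, C) array or (N, C) matrix of per-pixel class scores
# to an N x C matrix.
.as_pixel_matrix <- function(x) {
  d <- dim(x)
  if (is.null(d)) stop("expected an array or matrix of class scores")
  if (length(d) == 2) return(x)
  if (length(d) == 3) return(matrix(x, d[1] * d[2], d[3]))
  if (length(d) == 4) {
    # batch (B, H, W, C): fold batch and space together
    x <- aperm(x, c(2, 3, 1, 4))
    return(matrix(x, d[1] * d[2] * d[3], d[4]))
  }
  stop("class-score input must have 2, 3 or 4 dimensions")
}

#' One-hot encode an integer label map
#'
#' @param mask integer matrix/array with values in `0:(n_classes-1)`.
#' @param n_classes number of classes.
#' @return array with one trailing binary channel per class.
#' @export
one_hot <- function(mask, n_classes) {
  v <- as.integer(mask)
  if (any(v < 0L) || any(v >= n_classes))
    stop("mask values must lie in [0, n_classes)")
  out <- matrix(0, length(v), n_classes)
  out[cbind(seq_along(v), v + 1L)] <- 1
  d <- dim(mask)
  if (is.null(d)) d <- length(mask)
  array(out, c(d, n_classes))
}

#' Soft confusion counts from a probability map
#'
#' Accumulates differentiable per-class confusion mass from a per-pixel
#' class-probability map against a one-hot truth map:
#' `tp_c = sum p_c g_c`, `fp_c = sum p_c (1 - g_c)`,
#' `fn_c = sum (1 - p_c) g_c`, with `tn_c` the remainder to the pixel
#' count.  On hard (0/1) probabilities these equal integer pixel counts
#' exactly.
#'
#' @param probs array (H, W, C), matrix (N, C) or batch (B, H, W, C) of
#'   per-pixel class probabilities; entries in `[0, 1]`, rows summing
#'   to 1.
#' @param truth one-hot label map of the same shape.
#' @return [per_class_counts()]
#' @export
soft_confusion_counts <- function(probs, truth) {
  p <- .as_pixel_matrix(probs)
  g <- .as_pixel_matrix(truth)
  if (!identical(dim(p), dim(g)))
    stop("probs and truth must share shape and class count")
  if (any(p < -1e-9) || any(p > 1 + 1e-9))
    stop("probabilities must lie in [0, 1]")
  rs <- rowSums(p)
  if (any(abs(rs - 1) > 1e-5))
    stop("per-pixel probabilities must sum to 1")
  if (any(g != 0 & g != 1) || any(abs(rowSums(g) - 1) > 1e-9))
    stop("truth must be one-hot")
  n <- nrow(p)
  tp <- colSums(p * g)
  fp <- colSums(p) - tp
  fn <- colSums(g) - tp
  tn <- n - tp - fp - fn
  per_class_counts(tp, fp, fn, tn)
}

#' Hard confusion counts from label maps
#'
#' Integer per-class confusion counts from predicted and true label
#' maps (values `0:(n_classes-1)`).
#'
#' @param pred,truth integer label maps of identical shape.
#' @param n_classes number of classes.
#' @return [per_class_counts()]
#' @export
hard_confusion_counts <- function(pred, truth, n_classes) {
  p <- as.integer(pred); g <- as.integer(truth)
  if (length(p) != length(g)) stop("pred and truth must share shape")
  if (any(p < 0L) || any(p >= n_classes) || any(g < 0L) || any(g >= n_classes))
    stop("labels must lie in [0, n_classes)")
  n <- length(p)
  cm <- table(factor(g, levels = 0:(n_classes - 1)),
              factor(p, levels = 0:(n_classes - 1)))
  cm <- unclass(cm)
  tp <- diag(cm)
  fn <- rowSums(cm) - tp
  fp <- colSums(cm) - tp
  tn <- n - tp - fp - fn
  per_class_counts(tp, fp, fn, tn)
}

#' Add two sets of per-class counts
#'
#' Confusion mass is additive over slices/batches, so dataset-level
#' metrics pool counts with `+`.
#' @param e1,e2 `per_class_counts` with matching class count.
#' @export
"+.per_class_counts" <- function(e1, e2) {
  if (e1$n_classes != e2$n_classes) stop("class counts differ")
  per_class_counts(e1$tp + e2$tp, e1$fp + e2$fp,
                   e1$fn + e2$fn, e1$tn + e2$tn)
}
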