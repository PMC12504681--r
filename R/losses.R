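#' Tversky index asymmetry parameters
#'
#' `alpha_tv` weights false negatives, `beta_tv` false positives.  The
#' default 0.7/0.3 penalizes false negatives more (missing tumor is
#' worse than over-calling it); with 0.5/0.5 the index reduces to the
#' Dice coefficient and with 1/1 to the Jaccard index.
#'
#' @param alpha_tv,beta_tv nonnegative reals.
#' @export
tversky_params <- function(alpha_tv = 0.7, beta_tv = 0.3) {
  if (alpha_tv < 0 || beta_tv < 0) stop("Tversky weights must be nonnegative")
  structure(list(alpha_tv = alpha_tv, beta_tv = beta_tv),
            class = "tversky_params")
}

#' Loss configuration
#'
#' Configuration of the composite Log-Cosh-Focal-Tversky (LCFT)
#' training loss: a weighted sum of the log-cosh Dice loss, the focal
#' Tversky loss and the Jaccard loss.  The three weights must sum to 1
#' so the total stays below 1.  Defaults: weights 0.6/0.2/0.2, focal
#' exponent 0.75, Tversky 0.7/0.3, smoothing 1e-6 added to every
#' numerator and denominator (empty-vs-empty masks then score a perfect
#' 1), equal-weight aggregation over all classes.
#'
#' @param w_lc,w_ft,w_j weights of the log-cosh Dice, focal Tversky and
#'   Jaccard terms; must sum to 1.
#' @param focal_gamma positive focal exponent.
#' @param tversky a [tversky_params()].
#' @param smooth small positive ratio smoothing.
#' @param class_aggregation `"macro_all"` (mean over all classes,
#'   background included) or `"macro_foreground"` (classes 1..C-1).
#' @param kind `"lcft"` for the composite loss or `"dice"` for a plain
#'   mean Dice loss (used by the ablation baselines).
#' @export
loss_config <- function(w_lc = 0.6, w_ft = 0.2, w_j = 0.2,
                        focal_gamma = 0.75,
                        tversky = tversky_params(),
                        smooth = 1e-6,
                        class_aggregation = c("macro_all", "macro_foreground"),
                        kind = c("lcft", "dice")) {
  kind <- match.arg(kind)
  class_aggregation <- match.arg(class_aggregation)
  if (kind == "lcft" && abs(w_lc + w_ft + w_j - 1) > 1e-8)
    stop("loss weights w_lc + w_ft + w_j must sum to 1")
  if (focal_gamma <= 0) stop("focal_gamma must be positive")
  if (smooth < 0) stop("smooth must be nonnegative")
  structure(list(w_lc = w_lc, w_ft = w_ft, w_j = w_j,
                 focal_gamma = focal_gamma, tversky = tversky,
                 smooth = smooth, class_aggregation = class_aggregation,
                 kind = kind),
            class = "loss_config")
}

#' Per-class Dice coefficient
#'
#' `(2 tp + smooth) / (2 tp + fn + fp + smooth)` per class.
#' @param counts a [per_class_counts()].
#' @param smooth nonnegative smoothing added to numerator and
#'   denominator.
#' @return numeric vector, one value in `[0, 1]` per class.
#' @export
dice_coefficient <- function(counts, smooth = 1e-6) {
  ct <- .as_counts(counts)
  (2 * ct$tp + smooth) / (2 * ct$tp + ct$fn + ct$fp + smooth)
}

#' Per-class Jaccard index (IoU)
#'
#' `(tp + smooth) / (tp + fp + fn + smooth)`; never exceeds the Dice
#' coefficient on the same counts.
#' @inheritParams dice_coefficient
#' @export
jaccard_index <- function(counts, smooth = 1e-6) {
  ct <- .as_counts(counts)
  (ct$tp + smooth) / (ct$tp + ct$fp + ct$fn + smooth)
}

#' Per-class Tversky index
#'
#' `(tp + smooth) / (tp + alpha*fn + beta*fp + smooth)`.  Reduces to
#' Dice at alpha = beta = 0.5 and to Jaccard at alpha = beta = 1.
#' @inheritParams dice_coefficient
#' @param params a [tversky_params()].
#' @export
tversky_index <- function(counts, params = tversky_params(), smooth = 1e-6) {
  ct <- .as_counts(counts)
  (ct$tp + smooth) /
    (ct$tp + params$alpha_tv * ct$fn + params$beta_tv * ct$fp + smooth)
}

#' Log-cosh Dice loss
#'
#' `log(cosh(1 - Dice))` per class (natural log); a smooth, outlier
#' tolerant reshaping of the Dice loss that is 0 iff Dice = 1.
#' @inheritParams dice_coefficient
#' @export
log_cosh_dice_loss <- function(counts, smooth = 1e-6) {
  log(cosh(1 - dice_coefficient(counts, smooth)))
}

#' Focal Tversky loss
#'
#' `(1 - Tversky index)^focal_gamma` per class; the exponent (< 1 by
#' default) amplifies the gradient on hard, low-overlap classes.
#' @inheritParams tversky_index
#' @param focal_gamma positive exponent.
#' @export
focal_tversky_loss <- function(counts, params = tversky_params(),
                               focal_gamma = 0.75, smooth = 1e-6) {
  (1 - tversky_index(counts, params, smooth))^focal_gamma
}

#' Jaccard loss
#'
#' `1 - Jaccard index` per class.
#' @inheritParams jaccard_index
#' @export
jaccard_loss <- function(counts, smooth = 1e-6) {
  1 - jaccard_index(counts, smooth)
}

.aggregate_classes <- function(per_class, config) {
  nc <- length(per_class)
  idx <- if (config$class_aggregation == "macro_foreground" && nc > 1)
    2:nc else seq_len(nc)
  mean(per_class[idx])
}

#' Composite loss from confusion counts
#'
#' Evaluates the configured loss on an existing set of per-class
#' counts: `w_lc * logcosh-Dice + w_ft * focal-Tversky + w_j * Jaccard`
#' (or the plain Dice loss when `config$kind == "dice"`), aggregated
#' over classes per `config$class_aggregation`.
#'
#' @param counts a [per_class_counts()].
#' @param config a [loss_config()].
#' @return scalar loss in `[0, 1]`.
#' @export
composite_loss_from_counts <- function(counts, config = loss_config()) {
  ct <- .as_counts(counts)
  s <- config$smooth
  if (config$kind == "dice") {
    per <- 1 - dice_coefficient(ct, s)
  } else {
    per <- config$w_lc * log_cosh_dice_loss(ct, s) +
      config$w_ft * focal_tversky_loss(ct, config$tversky,
                                       config$focal_gamma, s) +
      config$w_j * jaccard_loss(ct, s)
  }
  .aggregate_classes(per, config)
}

#' Total LCFT training loss on probability maps
#'
#' Builds soft confusion counts from the probability and one-hot truth
#' maps and evaluates the composite loss.  Differentiable with respect
#' to `probs`; see [lcft_gradient()].
#'
#' @param probs per-pixel class probability map ((H, W, C), (N, C) or
#'   (B, H, W, C)).
#' @param truth one-hot truth of the same shape.
#' @param config a [loss_config()].
#' @return scalar loss in `[0, 1]`.
#' @export
lcft_total_loss <- function(probs, truth, config = loss_config()) {
  composite_loss_from_counts(soft_confusion_counts(probs, truth), config)
}

# Partial derivatives of the aggregated composite loss with respect to
# the per-class counts (tp, fp, fn).  tn never enters any term.
.loss_count_grads <- function(counts, config) {
  ct <- .as_counts(counts)
  s <- config$smooth
  nc <- ct$n_classes
  w <- rep(0, nc)
  idx <- if (config$class_aggregation == "macro_foreground" && nc > 1)
    2:nc else seq_len(nc)
  w[idx] <- 1 / length(idx)

  tp <- ct$tp; fp <- ct$fp; fn <- ct$fn
  # Dice pieces
  dnum <- 2 * tp + s
  dden <- 2 * tp + fn + fp + s
  dD_dtp <- 2 * (fn + fp) / dden^2
  dD_dfx <- -dnum / dden^2                       # d Dice / d fp = d / d fn
  if (config$kind == "dice") {
    return(list(dtp = -w * dD_dtp, dfp = -w * dD_dfx, dfn = -w * dD_dfx))
  }
  D <- dnum / dden
  dLlc_dD <- -tanh(1 - D)
  # Jaccard pieces
  jnum <- tp + s
  jden <- tp + fp + fn + s
  dJ_dtp <- (fp + fn) / jden^2
  dJ_dfx <- -jnum / jden^2
  # Tversky pieces
  a <- config$tversky$alpha_tv; b <- config$tversky$beta_tv
  tden <- tp + a * fn + b * fp + s
  TI <- (tp + s) / tden
  dT_dtp <- (a * fn + b * fp) / tden^2
  dT_dfn <- -a * (tp + s) / tden^2
  dT_dfp <- -b * (tp + s) / tden^2
  g <- config$focal_gamma
  # (1-TI)^g has unbounded slope at TI -> 1 when g < 1; clamp for stability
  one_m <- pmax(1 - TI, 1e-8)
  dFT_dTI <- -g * one_m^(g - 1)

  dtp <- w * (config$w_lc * dLlc_dD * dD_dtp +
                config$w_ft * dFT_dTI * dT_dtp +
                config$w_j * (-dJ_dtp))
  dfp <- w * (config$w_lc * dLlc_dD * dD_dfx +
                config$w_ft * dFT_dTI * dT_dfp +
                config$w_j * (-dJ_dfx))
  dfn <- w * (config$w_lc * dLlc_dD * dD_dfx +
                config$w_ft * dFT_dTI * dT_dfn +
                config$w_j * (-dJ_dfx))
  list(dtp = dtp, dfp = dfp, dfn = dfn)
}

#' Gradient of the composite loss with respect to the probabilities
#'
#' Analytic gradient of [lcft_total_loss()] (or the Dice-only loss)
#' with respect to every entry of `probs`, using
#' `d tp_c / d p_c = g_c`, `d fp_c / d p_c = 1 - g_c`,
#' `d fn_c / d p_c = -g_c`.
#'
#' @inheritParams lcft_total_loss
#' @return array of the same shape as `probs`.
#' @export
lcft_gradient <- function(probs, truth, config = loss_config()) {
  counts <- soft_confusion_counts(probs, truth)
  gr <- .loss_count_grads(counts, config)
  g <- .as_pixel_matrix(truth)
  gp <- sweep(g, 2, gr$dtp - gr$dfn, "*") +
    sweep(1 - g, 2, gr$dfp, "*")
  array(gp, dim(probs) %||% dim(gp))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
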