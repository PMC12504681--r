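#' Evaluate a model on a slice set
#'
#' Pools one global confusion table over the whole dataset: hard
#' (argmax) counts for the reported overlap metrics and accuracy, soft
#' counts for the loss.  Reported dice/jaccard/tversky are macro means
#' over foreground classes by default; a binary whole-tumor (any
#' foreground vs background) Dice and the per-class breakdown are
#' included alongside.
#'
#' @param model a segmentation model.
#' @param data nonempty list of [slice_sample()] objects.
#' @param loss_config a [loss_config()]; also supplies the Tversky
#'   alpha/beta used for the reported Tversky index.
#' @param aggregation `"macro_foreground"` (default) or `"macro_all"`
#'   for the reported scalars.
#' @param per_slice if `TRUE`, average per-slice metrics instead of
#'   pooling counts.
#' @return a `metrics_report` with fields `loss`, `dice`, `jaccard`,
#'   `tversky`, `accuracy`, `whole_tumor_dice`, `per_class`,
#'   `n_samples`.
#' @export
evaluate_model <- function(model, data, loss_config = vnetseg::loss_config(),
                           aggregation = c("macro_foreground", "macro_all"),
                           per_slice = FALSE) {
  aggregation <- match.arg(aggregation)
  if (!length(data)) stop("evaluation data is empty")
  nc <- model$spec$n_classes
  s <- loss_config$smooth
  agg_idx <- if (aggregation == "macro_foreground" && nc > 1) 2:nc
             else seq_len(nc)
  pool_hard <- NULL; pool_soft <- NULL; pool_bin <- NULL
  slice_rows <- list()
  for (si in seq_along(data)) {
    sl <- data[[si]]
    probs <- .forward_sample(model, sl$image, training = FALSE)$probs
    d <- dim(probs)
    pred <- max.col(matrix(probs, d[1] * d[2], d[3])) - 1L
    hc <- hard_confusion_counts(pred, sl$mask, nc)
    sc <- soft_confusion_counts(probs, one_hot(sl$mask, nc))
    bc <- hard_confusion_counts(as.integer(pred > 0L),
                                as.integer(sl$mask > 0L), 2L)
    pool_hard <- if (is.null(pool_hard)) hc else pool_hard + hc
    pool_soft <- if (is.null(pool_soft)) sc else pool_soft + sc
    pool_bin <- if (is.null(pool_bin)) bc else pool_bin + bc
    if (per_slice)
      slice_rows[[si]] <- c(
        dice = mean(dice_coefficient(hc, s)[agg_idx]),
        jaccard = mean(jaccard_index(hc, s)[agg_idx]),
        tversky = mean(tversky_index(hc, loss_config$tversky, s)[agg_idx]))
  }
  counts <- pool_hard
  if (per_slice) {
    m <- colMeans(do.call(rbind, slice_rows))
    dice <- m[["dice"]]; jac <- m[["jaccard"]]; tv <- m[["tversky"]]
  } else {
    dice <- mean(dice_coefficient(counts, s)[agg_idx])
    jac <- mean(jaccard_index(counts, s)[agg_idx])
    tv <- mean(tversky_index(counts, loss_config$tversky, s)[agg_idx])
  }
  npix <- sum(counts$tp + counts$fn)
  report <- structure(list(
    loss = composite_loss_from_counts(pool_soft, loss_config),
    dice = dice, jaccard = jac, tversky = tv,
    accuracy = sum(counts$tp) / npix,
    whole_tumor_dice = dice_coefficient(pool_bin, s)[2],
    per_class = data.frame(class = seq_len(nc) - 1L,
                           dice = dice_coefficient(counts, s),
                           jaccard = jaccard_index(counts, s),
                           tversky = tversky_index(counts,
                                                   loss_config$tversky, s)),
    n_samples = length(data)), class = "metrics_report")
  report
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(paste0("metrics over %d slices: loss %.5f  dice %.4f  ",
                     "jaccard %.4f  tversky %.4f  accuracy %.4f\n"),
              x$n_samples, x$loss, x$dice, x$jaccard, x$tversky, x$accuracy))
  invisible(x)
}

#' Run the six-variant ablation
#'
#' Trains and evaluates all six ablation variants under identical
#' data, seed and step budget and returns one report row per variant
#' (columns: loss, dice, jaccard, tversky, accuracy).
#'
#' @param train_data,test_data slice lists.
#' @param scale `"paper"` or `"test"`.
#' @param base_config a [training_config()]; its `loss` field is
#'   overridden per variant.
#' @param variants variant names to run (default all six).
#' @return an `ablation_report` with `rows` (named list of
#'   `metrics_report`), `table` (data frame) and `scale`.
#' @export
run_ablation <- function(train_data, test_data, scale = c("test", "paper"),
                         base_config = training_config(),
                         variants = variant_names()) {
  scale <- match.arg(scale)
  rows <- list()
  for (vn in variants) {
    v <- build_variant(vn, scale, seed = base_config$seed)
    cfg <- base_config
    cfg$loss <- v$loss
    res <- train_model(v$model, train_data, test_data, cfg)
    rows[[vn]] <- evaluate_model(res$model, test_data, v$loss)
  }
  tab <- do.call(rbind, lapply(names(rows), function(vn) {
    r <- rows[[vn]]
    data.frame(variant = vn, loss = r$loss, dice = r$dice,
               jaccard = r$jaccard, tversky = r$tversky,
               accuracy = r$accuracy)
  }))
  structure(list(rows = rows, table = tab, scale = scale),
            class = "ablation_report")
}

#' @export
print.ablation_report <- function(x, ...) {
  cat("ablation report (", x$scale, " scale)\n", sep = "")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' One-way analysis of variance
#'
#' Classical between/within mean-square F ratio with `(k-1, N-k)`
#' degrees of freedom and upper-tail p value.  Zero within-group
#' variance with unequal means yields `F = Inf`, `p = 0`; zero
#' between-group variance yields `F = 0`, `p = 1`.
#'
#' @param groups list of (>= 2) numeric vectors; at least one group
#'   must have >= 2 values.
#' @return list with `f_statistic`, `p_value`, `df`.
#' @export
one_way_anova <- function(groups) {
  if (!is.list(groups) || length(groups) < 2)
    stop("need at least 2 groups")
  groups <- lapply(groups, as.numeric)
  if (any(vapply(groups, length, 0L) < 1))
    stop("every group needs at least one value")
  n <- vapply(groups, length, 0L)
  if (sum(n) - length(groups) < 1)
    stop("need at least one group with 2 or more values")
  k <- length(groups)
  N <- sum(n)
  gm <- mean(unlist(groups))
  means <- vapply(groups, mean, 0)
  ssb <- sum(n * (means - gm)^2)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0))
  df1 <- k - 1L
  df2 <- N - k
  if (ssw <= 0 && ssb > 0)
    return(list(f_statistic = Inf, p_value = 0, df = c(df1, df2)))
  if (ssb <= 0)
    return(list(f_statistic = 0, p_value = 1, df = c(df1, df2)))
  f <- (ssb / df1) / (ssw / df2)
  list(f_statistic = f, p_value = pf(f, df1, df2, lower.tail = FALSE),
       df = c(df1, df2))
}

.label_colors <- rbind(c(0, 0, 0),        # background
                       c(230, 60, 60),    # class 1 (necrotic core)
                       c(60, 200, 60),    # class 2 (edema)
                       c(250, 220, 60))   # class 3 (enhancing)

.colorize_mask <- function(mask) {
  idx <- as.integer(mask) + 1L
  idx[idx > nrow(.label_colors)] <- nrow(.label_colors)
  array(.label_colors[idx, ], c(dim(mask), 3))
}

#' Render a qualitative montage
#'
#' Writes a side-by-side raster (binary PPM) of one input channel, the
#' ground-truth mask and the predicted mask with a consistent label
#' color map.
#'
#' @param sample a [slice_sample()].
#' @param prediction integer class map of the same spatial shape.
#' @param out_path output path (`.ppm`).
#' @param channel input channel to show (default 4 = flair).
#' @return `out_path`, invisibly.
#' @export
render_montage <- function(sample, prediction, out_path, channel = 4L) {
  img <- sample$image[, , channel]
  if (!identical(dim(prediction), dim(sample$mask)))
    stop("prediction shape does not match the sample mask")
  rng <- range(img)
  gs <- if (diff(rng) > 0) (img - rng[1]) / diff(rng) else img * 0
  panel_in <- array(rep(round(255 * gs), 3), c(dim(img), 3))
  panel_gt <- .colorize_mask(sample$mask)
  panel_pr <- .colorize_mask(prediction)
  gap <- array(255, c(nrow(img), 2, 3))
  canvas <- function(...) {
    parts <- list(...)
    h <- nrow(parts[[1]])
    w <- sum(vapply(parts, ncol, 0L))
    out <- array(0, c(h, w, 3))
    at <- 0L
    for (p in parts) {
      out[, at + seq_len(ncol(p)), ] <- p
      at <- at + ncol(p)
    }
    out
  }
  rgb <- canvas(panel_in, gap, panel_gt, gap, panel_pr)
  con <- file(out_path, "wb")
  on.exit(close(con))
  writeLines(c("P6", paste(dim(rgb)[2], dim(rgb)[1]), "255"), con)
  # PPM is row-major RGB-interleaved
  px <- aperm(rgb, c(3, 2, 1))
  writeBin(as.raw(pmin(255, pmax(0, round(px)))), con)
  invisible(out_path)
}
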