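#' Training configuration
#'
#' Defaults follow the published setup: Nesterov-accelerated adaptive
#' moment estimation (Nadam) at learning rate 2e-4, 30 epochs, LCFT
#' loss.  `batch_size` defaults to 8 (the source only states the batch
#' was reduced to fit RAM).  `max_steps` optionally caps the total
#' number of optimizer steps and `target_dice` stops training early
#' once the pooled training Dice (macro over foreground classes)
#' reaches the given value.
#'
#' @param learning_rate positive step size.
#' @param optimizer currently `"nadam"`.
#' @param epochs positive integer.
#' @param batch_size positive integer.
#' @param seed integer RNG seed (shuffling, dropout).
#' @param loss a [loss_config()].
#' @param checkpoint_dir directory for checkpoints, or `NULL` to skip
#'   checkpointing.
#' @param max_steps optional cap on optimizer steps.
#' @param target_dice optional early-stop threshold on training Dice.
#' @param eval_every compute the pooled train/validation metrics every
#'   this many epochs (default 1: every epoch, one history row per
#'   epoch; larger values trade history resolution for speed on
#'   overfit fixtures).
#' @export
training_config <- function(learning_rate = 2e-4,
                            optimizer = c("nadam"),
                            epochs = 30L, batch_size = 8L, seed = 1L,
                            loss = loss_config(), checkpoint_dir = NULL,
                            max_steps = NULL, target_dice = NULL,
                            eval_every = 1L) {
  optimizer <- match.arg(optimizer)
  if (learning_rate <= 0) stop("learning_rate must be positive")
  if (epochs < 1) stop("epochs must be a positive integer")
  if (batch_size < 1) stop("batch_size must be a positive integer")
  if (eval_every < 1) stop("eval_every must be a positive integer")
  structure(list(learning_rate = learning_rate, optimizer = optimizer,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed), loss = loss,
                 checkpoint_dir = checkpoint_dir,
                 max_steps = if (is.null(max_steps)) NULL
                             else as.integer(max_steps),
                 target_dice = target_dice,
                 eval_every = as.integer(eval_every)),
            class = "training_config")
}

# Nadam (Nesterov Adam) update for one parameter tensor.
.nadam_update <- function(theta, g, state, lr, t,
                          b1 = 0.9, b2 = 0.999, eps = 1e-7) {
  state$m <- b1 * state$m + (1 - b1) * g
  state$v <- b2 * state$v + (1 - b2) * g * g
  m_bar <- b1 * state$m / (1 - b1^(t + 1)) + (1 - b1) * g / (1 - b1^t)
  v_hat <- state$v / (1 - b2^t)
  list(theta = theta - lr * m_bar / (sqrt(v_hat) + eps), state = state)
}

.zero_like <- function(p) lapply(p, function(x) x * 0)

# Pooled (soft) loss and its per-sample prob gradients for one batch.
.batch_loss_grad <- function(model, batch, config) {
  fws <- lapply(batch, function(s)
    .forward_sample(model, s$image, training = TRUE))
  if (any(vapply(fws, function(f) !all(is.finite(f$probs)), TRUE)))
    return(list(loss = NaN, grads = NULL))   # diverged; caller aborts
  nc <- model$spec$n_classes
  counts <- NULL
  onehots <- list()
  for (i in seq_along(batch)) {
    oh <- one_hot(batch[[i]]$mask, nc)
    onehots[[i]] <- oh
    ct <- soft_confusion_counts(fws[[i]]$probs, oh)
    counts <- if (is.null(counts)) ct else counts + ct
  }
  loss <- composite_loss_from_counts(counts, config)
  gr <- .loss_count_grads(counts, config)
  grads <- NULL
  for (i in seq_along(batch)) {
    g <- .as_pixel_matrix(onehots[[i]])
    gp <- sweep(g, 2, gr$dtp - gr$dfn, "*") + sweep(1 - g, 2, gr$dfp, "*")
    gp <- array(gp, dim(fws[[i]]$probs))
    gz <- .softmax_bwd(fws[[i]]$probs, gp)
    sg <- .backward_sample(model, fws[[i]], gz)
    if (is.null(grads)) {
      grads <- sg
    } else {
      for (nm in names(sg))
        grads[[nm]] <- Map(`+`, grads[[nm]], sg[[nm]])
    }
  }
  list(loss = loss, grads = grads)
}

# Pooled hard metrics over a slice list (macro over foreground classes).
.pooled_hard_metrics <- function(model, data, config) {
  nc <- model$spec$n_classes
  hard <- NULL
  soft <- NULL
  for (s in data) {
    probs <- .forward_sample(model, s$image, training = FALSE)$probs
    d <- dim(probs)
    pred <- max.col(matrix(probs, d[1] * d[2], d[3])) - 1L
    hc <- hard_confusion_counts(pred, s$mask, nc)
    sc <- soft_confusion_counts(probs, one_hot(s$mask, nc))
    hard <- if (is.null(hard)) hc else hard + hc
    soft <- if (is.null(soft)) sc else soft + sc
  }
  fg <- if (nc > 1) 2:nc else 1
  list(loss = composite_loss_from_counts(soft, config),
       dice = mean(dice_coefficient(hard, config$smooth)[fg]),
       hard = hard, soft = soft)
}

#' Train a segmentation model
#'
#' Minimizes the configured loss with Nadam over shuffled mini-batches
#' of slice samples, recording per-epoch training/validation loss and
#' Dice (pooled hard counts, macro over foreground classes) and
#' checkpointing the best validation Dice when `checkpoint_dir` is
#' set.  Fully deterministic under `config$seed`.
#'
#' @param model a [build_segmentation_model()] object.
#' @param train_data nonempty list of [slice_sample()] objects.
#' @param val_data optional validation slice list (defaults to
#'   `train_data`).
#' @param config a [training_config()].
#' @return a `training_result` with fields `model` (trained), `history`
#'   (data frame: epoch, train_loss, train_dice, val_loss, val_dice),
#'   `final_checkpoint`, `steps_run` and `config_echo`.
#' @export
train_model <- function(model, train_data, val_data = NULL,
                        config = training_config()) {
  stopifnot(inherits(config, "training_config"))
  if (!length(train_data)) stop("training data is empty")
  if (is.null(val_data)) val_data <- train_data
  set.seed(config$seed)
  opt_state <- lapply(model$params, function(p)
    lapply(p, function(x) list(m = x * 0, v = x * 0)))
  t_step <- 0L
  steps_cap <- config$max_steps %||% Inf
  best_val <- -Inf
  best_path <- NULL
  hist <- data.frame()
  n <- length(train_data)
  for (epoch in seq_len(config$epochs)) {
    ord <- sample.int(n)
    ep_losses <- c()
    for (start in seq(1, n, by = config$batch_size)) {
      if (t_step >= steps_cap) break
      idx <- ord[start:min(start + config$batch_size - 1L, n)]
      bl <- .batch_loss_grad(model, train_data[idx], config$loss)
      if (!is.finite(bl$loss))
        stop("non-finite loss at step ", t_step + 1L,
             "; aborting (check learning rate / inputs)")
      t_step <- t_step + 1L
      ep_losses <- c(ep_losses, bl$loss)
      for (nm in names(bl$grads)) {
        if (nm %in% model$frozen) next
        for (fld in names(bl$grads[[nm]])) {
          up <- .nadam_update(model$params[[nm]][[fld]],
                              bl$grads[[nm]][[fld]],
                              opt_state[[nm]][[fld]],
                              config$learning_rate, t_step)
          model$params[[nm]][[fld]] <- up$theta
          opt_state[[nm]][[fld]] <- up$state
        }
      }
    }
    last <- epoch == config$epochs || t_step >= steps_cap
    if (epoch %% config$eval_every == 0 || last) {
      tr <- .pooled_hard_metrics(model, train_data, config$loss)
      va <- .pooled_hard_metrics(model, val_data, config$loss)
      hist <- rbind(hist, data.frame(epoch = epoch,
                                     train_loss = mean(ep_losses),
                                     train_dice = tr$dice,
                                     val_loss = va$loss,
                                     val_dice = va$dice))
      if (!is.null(config$checkpoint_dir) && va$dice > best_val) {
        best_val <- va$dice
        best_path <- file.path(config$checkpoint_dir, "best_model.rds")
        save_checkpoint(model, best_path)
      }
      if (!is.null(config$target_dice) && tr$dice >= config$target_dice)
        break
    }
    if (t_step >= steps_cap) break
  }
  structure(list(model = model, history = hist,
                 final_checkpoint = best_path, steps_run = t_step,
                 config_echo = config),
            class = "training_result")
}

#' Save a model checkpoint
#'
#' Serializes the parameters together with a JSON rendering of the
#' architecture spec so checkpoints are self-describing.
#'
#' @param model a segmentation model.
#' @param path output `.rds` path.
#' @export
save_checkpoint <- function(model, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  saveRDS(list(params = model$params, frozen = model$frozen,
               spec_json = jsonlite::toJSON(unclass(model$spec),
                                            auto_unbox = TRUE)),
          path)
  spec_path <- sub("\\.rds$", "_spec.json", path)
  writeLines(as.character(jsonlite::toJSON(unclass(model$spec),
                                           auto_unbox = TRUE,
                                           pretty = TRUE)), spec_path)
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path a checkpoint written by [save_checkpoint()].
#' @return a segmentation model.
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  sp <- jsonlite::fromJSON(obj$spec_json)
  spec <- architecture_spec(n_stages = sp$n_stages,
                            convs_per_stage = sp$convs_per_stage,
                            filters_per_stage = sp$filters_per_stage,
                            cbf_filters = sp$cbf_filters,
                            cbf_enabled = sp$cbf_enabled,
                            cbf_out_channels = sp$cbf_out_channels,
                            kernel_size = sp$kernel_size,
                            in_channels = sp$in_channels,
                            n_classes = sp$n_classes,
                            dropout_rate = sp$dropout_rate,
                            input_side = sp$input_side)
  structure(list(spec = spec, params = obj$params,
                 frozen = obj$frozen %||% character()),
            class = "segmentation_model")
}
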