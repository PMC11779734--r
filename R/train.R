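#' Training configuration
#'
#' Defaults follow the published schedule: SGD with momentum 0.937, cosine
#' learning-rate decay from 0.005 to 0.0001, batch size 8, at most 500
#' epochs with early stopping once the validation loss has not improved for
#' 20 consecutive epochs.
#'
#' @param lr_init,lr_end Cosine schedule endpoints.
#' @param momentum SGD momentum.
#' @param batch_size Images per optimization step.
#' @param max_epochs Hard epoch cap.
#' @param patience Early-stopping patience (epochs without validation-loss
#'   improvement).
#' @param optimizer `"sgd"` or `"adam"`.
#' @param weight_decay L2 regularization coefficient.
#' @param seed RNG seed controlling shuffling and augmentation draws.
#' @return Configuration list.
#' @export
train_config <- function(lr_init = 0.005, lr_end = 0.0001, momentum = 0.937,
                         batch_size = 8L, max_epochs = 500L, patience = 20L,
                         optimizer = c("sgd", "adam"), weight_decay = 5e-4,
                         seed = 1L) {
  optimizer <- match.arg(optimizer)
  stopifnot(lr_end < lr_init, patience < max_epochs)
  list(lr_init = lr_init, lr_end = lr_end, momentum = momentum,
       batch_size = as.integer(batch_size), max_epochs = as.integer(max_epochs),
       patience = as.integer(patience), optimizer = optimizer,
       weight_decay = weight_decay, seed = as.integer(seed))
}

#' Cosine learning-rate schedule
#'
#' `lr(0) = lr_init`; the rate decays along a half cosine and reaches
#' `lr_end` at `max_epochs - 1`.
#'
#' @param epoch 0-based epoch index.
#' @param max_epochs Total epochs of the schedule.
#' @param lr_init,lr_end Endpoints.
#' @return Learning rate.
#' @export
cosine_lr <- function(epoch, max_epochs, lr_init = 0.005, lr_end = 0.0001) {
  t <- pmin(pmax(epoch, 0), max_epochs - 1)
  denom <- max(max_epochs - 1, 1)
  lr_end + 0.5 * (lr_init - lr_end) * (1 + cos(pi * t / denom))
}

#' Early-stopping epoch for a validation-loss trace
#'
#' Training stops after the first epoch at which the loss has not improved
#' (strictly) for `patience` consecutive epochs.
#'
#' @param losses Numeric vector of per-epoch validation losses.
#' @param patience Number of non-improving epochs tolerated.
#' @return The 1-based index of the stopping epoch, or `length(losses)` if
#'   the trace ends first.
#' @export
early_stop_epoch <- function(losses, patience) {
  best <- Inf
  since <- 0L
  for (t in seq_along(losses)) {
    if (losses[t] < best) {
      best <- losses[t]
      since <- 0L
    } else {
      since <- since + 1L
    }
    if (since >= patience) return(t)
  }
  length(losses)
}

# --- optimizers -------------------------------------------------------------

opt_state <- function(params) {
  lapply(params, function(p) {
    s <- new.env(parent = emptyenv())
    s$m <- 0
    s$v <- 0
    s
  })
}

opt_step <- function(params, state, cfg, lr, step) {
  for (i in seq_along(params)) {
    p <- params[[i]]
    if (is.null(p$grad)) next
    g <- p$grad + cfg$weight_decay * p$val
    s <- state[[i]]
    if (cfg$optimizer == "sgd") {
      s$m <- cfg$momentum * s$m - lr * g
      p$val <- p$val + s$m
    } else {
      b1 <- 0.9; b2 <- 0.999
      s$m <- b1 * s$m + (1 - b1) * g
      s$v <- b2 * s$v + (1 - b2) * g * g
      mhat <- s$m / (1 - b1^step)
      vhat <- s$v / (1 - b2^step)
      p$val <- p$val - lr * mhat / (sqrt(vhat) + 1e-8)
    }
  }
  invisible(NULL)
}

# Stack samples into one channels-first batch matrix (intensities scaled to
# [0, 1]) plus the 0-based target vector.
batch_tensors <- function(samples) {
  n <- length(samples)
  d <- dim(samples[[1L]]$image)
  mats <- lapply(samples, function(s) as_fmat(aperm(s$image, c(3L, 1L, 2L)) / 255))
  x <- tmat(do.call(cbind, mats), d[1L], d[2L], n)
  target <- unlist(lapply(samples, function(s) as.integer(t(s$mask))))
  list(x = x, target = target)
}

eval_model <- function(model, samples, batch_size) {
  cm <- matrix(0L, model$cfg$num_classes, model$cfg$num_classes)
  loss <- 0
  idx <- seq_along(samples)
  for (b in split(idx, ceiling(idx / batch_size))) {
    bt <- batch_tensors(samples[b])
    tp <- ag_tape(grad = FALSE)
    logits <- fwd_dfma(tp, ag_input(tp, bt$x), model, training = FALSE)
    l <- ag_seg_loss(tp, logits, bt$target)
    loss <- loss + l$val * length(b)
    pred <- max.col(t(logits$val), ties.method = "first") - 1L
    cm <- cm + confusion(pred, bt$target, model$cfg$num_classes)
  }
  list(loss = loss / length(samples), miou = suppressMessages(miou(cm)))
}

#' Train a segmentation model
#'
#' Runs the full loop: shuffled mini-batches, optional online augmentation
#' (training split only), cosine learning-rate decay, per-epoch validation
#' loss/mIoU, early stopping, and retention of the best-validation weights.
#'
#' @param model A [dfma_init()] model (modified in place; the returned model
#'   carries the best-validation weights).
#' @param train_samples,val_samples Lists of samples (`image` `H x W x 3` in
#'   0-255, `mask` `H x W` 0-based).
#' @param cfg A [train_config()].
#' @param augment_cfg Optional [augment_config()] applied to training
#'   samples each epoch.
#' @param verbose Print one line per epoch.
#' @return List with `model` and `history` (data frame of epoch, lr, train
#'   loss, validation loss, validation mIoU).
#' @export
train <- function(model, train_samples, val_samples, cfg = train_config(),
                  augment_cfg = NULL, verbose = FALSE) {
  if (length(train_samples) == 0L || length(val_samples) == 0L) {
    stop("empty training or validation split")
  }
  params <- collect_params(model$params)
  state <- opt_state(params)
  history <- NULL
  best_loss <- Inf
  best_state <- NULL
  since <- 0L
  step <- 0L
  with_seed(cfg$seed, {
    for (epoch in seq_len(cfg$max_epochs) - 1L) {
      lr <- cosine_lr(epoch, cfg$max_epochs, cfg$lr_init, cfg$lr_end)
      ord <- sample(seq_along(train_samples))
      tr_loss <- 0
      nb <- 0L
      for (b in split(ord, ceiling(seq_along(ord) / cfg$batch_size))) {
        batch <- train_samples[b]
        if (!is.null(augment_cfg)) batch <- lapply(batch, augment, cfg = augment_cfg)
        bt <- batch_tensors(batch)
        tp <- ag_tape(grad = TRUE)
        logits <- fwd_dfma(tp, ag_input(tp, bt$x), model, training = TRUE)
        l <- ag_seg_loss(tp, logits, bt$target)
        zero_grads(params)
        ag_backward(tp, l)
        step <- step + 1L
        opt_step(params, state, cfg, lr, step)
        tr_loss <- tr_loss + l$val
        nb <- nb + 1L
      }
      ev <- eval_model(model, val_samples, cfg$batch_size)
      history <- rbind(history, data.frame(
        epoch = epoch, lr = lr, train_loss = tr_loss / nb,
        val_loss = ev$loss, val_miou = ev$miou))
      if (verbose) {
        message(sprintf("epoch %3d lr %.5f train %.4f val %.4f mIoU %.3f",
                        epoch, lr, tr_loss / nb, ev$loss, ev$miou))
      }
      if (ev$loss < best_loss) {
        best_loss <- ev$loss
        best_state <- params_state(model$params)
        since <- 0L
      } else {
        since <- since + 1L
      }
      if (since >= cfg$patience) break
    }
  })
  if (!is.null(best_state)) params_restore(model$params, best_state)
  list(model = model, history = history)
}
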