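# Training loop (Adam + early stopping on validation loss) and the
# evaluation protocols built on it.

#' Training configuration
#'
#' Defaults follow the reference protocol for the full-resolution models:
#' Adam with learning rate 1e-5, batch size 64, up to 200 epochs with
#' early stopping at patience 20 on the validation loss, categorical
#' cross-entropy. For the small synthetic-phantom experiments shipped with
#' the package a larger learning rate and fewer epochs are appropriate
#' (see [reduced_train_config()]).
#'
#' @param learning_rate Adam learning rate (> 0).
#' @param batch_size Minibatch size.
#' @param max_epochs Maximum number of epochs.
#' @param patience Early-stopping patience in epochs (must be smaller than
#'   `max_epochs`); training stops once the validation loss has not
#'   improved for this many consecutive epochs, and the best-validation
#'   weights are restored.
#' @param seed Optional integer making initialization-independent parts of
#'   training (shuffling) deterministic.
#' @param lr_schedule `"constant"` or `"cosine"` (cosine decay of the
#'   learning rate to zero over `max_epochs`).
#' @param verbose Print one line per epoch.
#' @return A `train_config` object.
#' @export
train_config <- function(learning_rate = 1e-5, batch_size = 64,
                         max_epochs = 200, patience = 20, seed = NULL,
                         lr_schedule = c("constant", "cosine"),
                         verbose = FALSE) {
  stopifnot(learning_rate > 0, patience < max_epochs, batch_size >= 1)
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 seed = seed, lr_schedule = match.arg(lr_schedule),
                 verbose = isTRUE(verbose)),
            class = "train_config")
}

#' Training configuration for the reduced synthetic experiments
#'
#' Adam at 1e-3 for up to 30 epochs (patience 8): appropriate for the
#' 8-16-32-64 backbone at 64 x 64 trained from scratch on a few hundred
#' phantoms, where the reference rate of 1e-5 would need far more epochs
#' than the small problem warrants.
#'
#' @param ... Overrides passed to [train_config()].
#' @return A `train_config` object.
#' @export
reduced_train_config <- function(...) {
  defaults <- list(learning_rate = 1e-3, batch_size = 32, max_epochs = 30,
                   patience = 8, lr_schedule = "cosine")
  args <- utils::modifyList(defaults, list(...))
  do.call(train_config, args)
}

# early-stopping bookkeeping: given the validation losses seen so far,
# returns the best epoch and whether training should stop now
early_stop_state <- function(val_losses, patience) {
  best <- which.min(val_losses)
  list(best_epoch = best,
       stop = (length(val_losses) - best) >= patience)
}

#' Train a network
#'
#' Minimizes categorical cross-entropy with Adam. After every epoch the
#' validation loss is computed; training stops at `max_epochs` or once the
#' validation loss has not improved for `patience` consecutive epochs,
#' whichever comes first, and the weights of the best-validation epoch are
#' restored. Prune masks attached to the network are enforced after every
#' optimizer step; frozen layers (e.g. LoRA base weights) are never
#' updated.
#'
#' @param net An `ansa_net`.
#' @param data `list(train = ..., val = ...)` where each element is a list
#'   of [labeled_image()]s (or a prebuilt batch from the internal stacking
#'   helper). Class levels are taken from the training part.
#' @param cfg A [train_config()].
#' @return `list(net, history, levels)`: the trained network, a data frame
#'   with per-epoch train/validation loss and validation accuracy, and the
#'   class levels used for the output units.
#' @export
train_network <- function(net, data, cfg = train_config()) {
  if (is.null(data$train) || length(data$train) == 0)
    stop("empty training set")
  if (is.null(data$val) || length(data$val) == 0)
    stop("training requires a validation part for early stopping")
  if (!is.null(cfg$seed)) set.seed(cfg$seed)

  tr <- if (is.list(data$train) && !is.null(data$train$x)) data$train
        else as_image_batch(data$train)
  va <- if (is.list(data$val) && !is.null(data$val$x)) data$val
        else as_image_batch(data$val, levels = tr$levels)
  n <- dim(tr$x)[4]
  slots <- trainable_slots(net)
  state <- adam_state(net, slots)
  step <- 0L
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_loss = numeric(), val_acc = numeric())
  best_params <- lapply(slots, function(s) get_slot(net, s))
  val_losses <- numeric()

  for (epoch in seq_len(cfg$max_epochs)) {
    lr_e <- if (identical(cfg$lr_schedule, "cosine"))
      cfg$learning_rate * 0.5 * (1 + cos(pi * (epoch - 1) / cfg$max_epochs))
    else cfg$learning_rate
    ord <- sample.int(n)
    ep_loss <- 0
    nb <- 0L
    for (b0 in seq(1L, n, by = cfg$batch_size)) {
      ii <- ord[b0:min(b0 + cfg$batch_size - 1L, n)]
      xb <- tr$x[, , , ii, drop = FALSE]
      fw <- net_forward(net, xb)
      ls <- softmax_xent(fw$out, tr$y[ii])
      bw <- net_backward(net, fw$caches, ls$dlogits)
      step <- step + 1L
      upd <- adam_step(net, bw$grads, slots, state, lr = lr_e, t = step)
      net <- upd$net
      state <- upd$state
      ep_loss <- ep_loss + ls$loss
      nb <- nb + 1L
    }
    vl <- evaluate_loss(net, va)
    val_losses <- c(val_losses, vl$loss)
    history <- rbind(history, data.frame(
      epoch = epoch, train_loss = ep_loss / nb,
      val_loss = vl$loss, val_acc = vl$acc))
    if (cfg$verbose)
      message(sprintf("epoch %3d  train %.4f  val %.4f  acc %.3f",
                      epoch, ep_loss / nb, vl$loss, vl$acc))
    es <- early_stop_state(val_losses, cfg$patience)
    if (es$best_epoch == epoch)
      best_params <- lapply(slots, function(s) get_slot(net, s))
    if (es$stop) break
  }
  for (k in seq_along(slots)) net <- set_slot(net, slots[[k]], best_params[[k]])
  list(net = net, history = history, levels = tr$levels)
}

evaluate_loss <- function(net, batch, chunk = 64L) {
  n <- dim(batch$x)[4]
  loss <- 0
  correct <- 0L
  for (b0 in seq(1L, n, by = chunk)) {
    ii <- b0:min(b0 + chunk - 1L, n)
    out <- net_forward(net, batch$x[, , , ii, drop = FALSE])$out
    ls <- softmax_xent(out, batch$y[ii])
    loss <- loss + ls$loss * length(ii)
    correct <- correct + sum(apply(ls$prob, 2, which.max) == batch$y[ii])
  }
  list(loss = loss / n, acc = correct / n)
}

#' Evaluate a network on labeled images
#'
#' Computes the confusion matrix (rows = true class, columns = predicted)
#' and the multi-class metrics report.
#'
#' @param net An `ansa_net`.
#' @param images Non-empty list of [labeled_image()]s.
#' @param levels Class levels matching the network's output units; by
#'   default the sorted unique labels of `images`.
#' @return `list(confusion, metrics)`.
#' @export
evaluate_model <- function(net, images, levels = NULL) {
  stopifnot(length(images) >= 1)
  batch <- as_image_batch(images, levels)
  n <- dim(batch$x)[4]
  pred <- integer(n)
  for (b0 in seq(1L, n, by = 64L)) {
    ii <- b0:min(b0 + 63L, n)
    out <- net_forward(net, batch$x[, , , ii, drop = FALSE])$out
    pred[ii] <- apply(out, 2, which.max)
  }
  cm <- confusion_matrix(batch$y, pred, length(batch$levels), batch$levels)
  list(confusion = cm, metrics = metrics_report(cm))
}

#' Average per-image inference time
#'
#' Wall-clock milliseconds per image: after `warmup` untimed batches, the
#' full set is timed `repeats` times and the median of the per-image means
#' is returned. Timings are hardware-dependent and are reported, never
#' asserted against reference values.
#'
#' @param net An `ansa_net`.
#' @param images List of [labeled_image()]s (or a prebuilt batch).
#' @param repeats Timed repetitions (default 5).
#' @param warmup Untimed warm-up passes (default 2).
#' @param batch_size Images per forward pass.
#' @return Milliseconds per image (positive scalar).
#' @export
inference_time_per_image <- function(net, images, repeats = 5, warmup = 2,
                                     batch_size = 64L) {
  batch <- if (is.list(images) && !is.null(images$x)) images
           else as_image_batch(images)
  n <- dim(batch$x)[4]
  run_once <- function() {
    for (b0 in seq(1L, n, by = batch_size)) {
      ii <- b0:min(b0 + batch_size - 1L, n)
      net_forward(net, batch$x[, , , ii, drop = FALSE])
    }
  }
  for (i in seq_len(warmup)) run_once()
  times <- vapply(seq_len(repeats), function(i) {
    t0 <- proc.time()[["elapsed"]]
    run_once()
    (proc.time()[["elapsed"]] - t0) / n * 1000
  }, 0)
  stats::median(times)
}
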