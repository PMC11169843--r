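#' Training configuration
#'
#' Collects every knob of a training stage. Defaults follow the published
#' recipe where one exists: leak 0.5, thresholds initialised at 0.5,
#' dropout 0.5 on spiking fully connected layers, learning rate
#' multiplied by 0.9 every `decay_interval` epochs, pre-train at five
#' timesteps and re-train at one. Batch size, initial learning rate,
#' optimizer and loss form are free choices (64, 0.05, plain SGD,
#' softmax cross-entropy).
#'
#' @param timesteps Simulation ticks per presentation, `T >= 1`.
#' @param lr Initial learning rate (> 0).
#' @param lr_decay Multiplicative factor applied every `decay_interval`
#'   epochs ("dropped by 10%" = 0.9).
#' @param decay_interval Epochs between decays.
#' @param epochs Epochs in this stage.
#' @param leak Leakage factor \eqn{\lambda}.
#' @param dropout_p Dropout probability on spiking fully connected
#'   outputs, in `[0, 1)`; applied during training only.
#' @param batch_size Mini-batch size.
#' @param seed Integer RNG seed for shuffling, dropout and (when
#'   parameters are initialised inside a stage) weight draws.
#' @param stage `"pretrain"` or `"retrain"`.
#' @param pooling `"avg"` or `"max"`.
#' @param temporal_membrane_path Logical; expand the membrane-to-membrane
#'   temporal chain fully (standard STBP) instead of one step. Moot at
#'   `T = 1`.
#' @param threshold_init Initial threshold value.
#' @param threshold_floor Lower clip applied to thresholds after every
#'   update, preserving the division by `Vth` in the gradients.
#' @param momentum SGD momentum (0 disables, the default).
#' @return An object of class `train_config`.
#' @export
train_config <- function(timesteps = 1L, lr = 0.05, lr_decay = 0.9,
                         decay_interval = 25L, epochs = 100L, leak = 0.5,
                         dropout_p = 0.5, batch_size = 64L, seed = 1L,
                         stage = c("pretrain", "retrain"),
                         pooling = c("avg", "max"),
                         temporal_membrane_path = FALSE,
                         threshold_init = 0.5, threshold_floor = 0.01,
                         momentum = 0) {
  stage <- match.arg(stage)
  pooling <- match.arg(pooling)
  stopifnot(timesteps >= 1, lr > 0, lr_decay > 0, decay_interval >= 1,
            epochs >= 0, leak >= 0, leak <= 1,
            dropout_p >= 0, dropout_p < 1, batch_size >= 1,
            threshold_init > 0, threshold_floor > 0, momentum >= 0)
  structure(list(timesteps = as.integer(timesteps), lr = lr,
                 lr_decay = lr_decay,
                 decay_interval = as.integer(decay_interval),
                 epochs = as.integer(epochs), leak = leak,
                 dropout_p = dropout_p,
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed), stage = stage,
                 pooling = pooling,
                 temporal_membrane_path = temporal_membrane_path,
                 threshold_init = threshold_init,
                 threshold_floor = threshold_floor,
                 momentum = momentum),
            class = "train_config")
}

#' Effective learning rate at a given epoch
#'
#' The rate is multiplied by `lr_decay` once every `decay_interval`
#' completed epochs: at epoch 60 with decay 0.9 every 25 epochs the rate
#' is `lr * 0.9^2`.
#'
#' @param cfg A [train_config()].
#' @param epoch 1-based epoch number.
#' @return The scalar learning rate.
#' @export
effective_lr <- function(cfg, epoch) {
  cfg$lr * cfg$lr_decay^((epoch - 1L) %/% cfg$decay_interval)
}

#' Evaluate a network on labelled data
#'
#' Forward-only pass (no dropout) over the data in batches.
#'
#' @param arch,params Network description and parameters.
#' @param images,labels Image array `(h, w, c, n)` and 1-based labels.
#' @param timesteps Ticks per presentation.
#' @param batch_size Evaluation batch size.
#' @param pooling Pooling mode.
#' @return List with `accuracy` (fraction correct), `loss` and
#'   `predictions`.
#' @export
evaluate_network <- function(arch, params, images, labels, timesteps = 1L,
                             batch_size = 128L, pooling = "avg") {
  images <- as_image_batch(images, arch$input_shape)
  n <- dim(images)[4]
  labels <- as.integer(labels)
  stopifnot(length(labels) == n)
  preds <- integer(n)
  loss_sum <- 0
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    fwd <- network_forward(arch, params,
                           images[, , , idx, drop = FALSE], timesteps,
                           pooling = pooling)
    preds[idx] <- predict_class(fwd$output)
    loss_sum <- loss_sum + compute_loss(fwd$output, labels[idx]) *
      length(idx)
  }
  list(accuracy = mean(preds == labels), loss = loss_sum / n,
       predictions = preds)
}

apply_updates <- function(params, grads, lr, floor, momentum = 0,
                          velocity = NULL) {
  for (i in seq_along(params$layers)) {
    g <- grads[[i]]
    if (is.null(g) || is.null(g$dW)) next
    step_w <- g$dW
    if (momentum > 0) {
      if (is.null(velocity[[i]])) velocity[[i]] <- list(W = 0, vth = 0)
      velocity[[i]]$W <- momentum * velocity[[i]]$W + step_w
      step_w <- velocity[[i]]$W
    }
    params$layers[[i]]$W <- params$layers[[i]]$W - lr * step_w
    if (!is.null(g$dvth)) {
      step_t <- g$dvth
      if (momentum > 0) {
        velocity[[i]]$vth <- momentum * velocity[[i]]$vth + step_t
        step_t <- velocity[[i]]$vth
      }
      params$layers[[i]]$vth <- pmax(params$layers[[i]]$vth - lr * step_t,
                                     floor)
    }
  }
  list(params = params, velocity = velocity)
}

#' Train one stage
#'
#' Mini-batch gradient descent on weights and thresholds with the variant
#' surrogate-gradient STBP backward pass. Dropout is applied during
#' training only; after each epoch the whole training set is re-evaluated
#' without dropout to log loss and accuracy. All randomness (shuffling,
#' dropout masks) is driven by `cfg$seed`, so identical calls produce
#' identical histories.
#'
#' @param arch Architecture.
#' @param params Starting parameters (see [init_params()]).
#' @param data List with `images` (`(h, w, c, n)` array) and `labels`
#'   (1-based integers).
#' @param cfg A [train_config()].
#' @param verbose Print one line per epoch.
#' @return List with `params` (trained) and `history` (data frame with
#'   columns epoch, stage, loss, accuracy, lr).
#' @export
train_stage <- function(arch, params, data, cfg, verbose = FALSE) {
  stopifnot(inherits(cfg, "train_config"), inherits(params, "scnn_params"))
  if (is.null(data$images) || is.null(data$labels) ||
      length(data$labels) == 0L) {
    stop("`data` must contain non-empty images and labels", call. = FALSE)
  }
  images <- as_image_batch(data$images, arch$input_shape)
  labels <- as.integer(data$labels)
  n <- dim(images)[4]
  stopifnot(length(labels) == n)

  history <- data.frame(epoch = integer(), stage = character(),
                        loss = numeric(), accuracy = numeric(),
                        lr = numeric())
  if (cfg$epochs == 0L) {
    return(list(params = params, history = history))
  }

  set.seed(cfg$seed)
  velocity <- vector("list", length(params$layers))
  for (epoch in seq_len(cfg$epochs)) {
    lr <- effective_lr(cfg, epoch)
    ord <- sample.int(n)
    for (start in seq(1L, n, by = cfg$batch_size)) {
      idx <- ord[start:min(start + cfg$batch_size - 1L, n)]
      fwd <- network_forward(arch, params,
                             images[, , , idx, drop = FALSE],
                             cfg$timesteps, trace = TRUE, training = TRUE,
                             dropout_p = cfg$dropout_p,
                             pooling = cfg$pooling)
      bk <- network_backward(arch, params, fwd, labels[idx],
                             cfg$temporal_membrane_path)
      upd <- apply_updates(params, bk$grads, lr, cfg$threshold_floor,
                           cfg$momentum, velocity)
      params <- upd$params
      velocity <- upd$velocity
    }
    ev <- evaluate_network(arch, params, images, labels, cfg$timesteps,
                           pooling = cfg$pooling)
    history <- rbind(history,
                     data.frame(epoch = epoch, stage = cfg$stage,
                                loss = ev$loss, accuracy = ev$accuracy,
                                lr = lr))
    if (verbose) {
      message(sprintf("[%s] epoch %3d  loss %.4f  acc %.3f  lr %.4g",
                      cfg$stage, epoch, ev$loss, ev$accuracy, lr))
    }
  }
  list(params = params, history = history)
}

#' Two-stage training: pre-train at T = 5, re-train at T = 1
#'
#' Stage one trains from the given (or freshly initialised) parameters at
#' the pre-train timestep count; stage two continues from the stage-one
#' parameters with the timestep reduced (to 1 by default), yielding a
#' single-timestep network without the gradient starvation of training at
#' `T = 1` from scratch.
#'
#' @param arch Architecture.
#' @param params_init Starting parameters, or `NULL` to initialise from
#'   `cfg_pretrain` (its seed, leak and `threshold_init`).
#' @param data Training data as in [train_stage()].
#' @param cfg_pretrain,cfg_retrain Stage configurations; their `stage`
#'   fields are forced to `"pretrain"`/`"retrain"`.
#' @param verbose Print per-epoch lines.
#' @return List with `params` (final), `pretrain` and `retrain` (the two
#'   histories).
#' @export
two_stage_train <- function(arch, params_init = NULL, data,
                            cfg_pretrain = train_config(timesteps = 5L,
                                                        stage = "pretrain"),
                            cfg_retrain = train_config(timesteps = 1L,
                                                       stage = "retrain"),
                            verbose = FALSE) {
  cfg_pretrain$stage <- "pretrain"
  cfg_retrain$stage <- "retrain"
  if (is.null(params_init)) {
    params_init <- init_params(arch, leak = cfg_pretrain$leak,
                               threshold_init = cfg_pretrain$threshold_init,
                               seed = cfg_pretrain$seed)
  }
  s1 <- train_stage(arch, params_init, data, cfg_pretrain, verbose)
  s2 <- train_stage(arch, s1$params, data, cfg_retrain, verbose)
  list(params = s2$params, pretrain = s1$history, retrain = s2$history)
}
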