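#' Softmax cross-entropy loss on output membrane potentials
#'
#' The classifier is trained by softmax cross-entropy on the final-
#' timestep output membrane potentials, the standard choice consistent
#' with the largest-membrane prediction rule.
#'
#' @param output_vms Per-class membrane potentials: numeric vector or
#'   `classes x batch` matrix.
#' @param labels Integer class labels in `1..classes`, one per sample.
#' @return Mean cross-entropy (a scalar).
#' @examples
#' compute_loss(rep(0, 10), 3)          # log(10)
#' compute_loss(c(1, 0), 1)             # log(1 + exp(-1))
#' @export
compute_loss <- function(output_vms, labels) {
  m <- if (is.matrix(output_vms)) output_vms else matrix(output_vms)
  labels <- as.integer(labels)
  if (length(labels) != ncol(m)) {
    stop("need one label per sample", call. = FALSE)
  }
  if (anyNA(labels) || any(labels < 1L) || any(labels > nrow(m))) {
    stop("labels out of range", call. = FALSE)
  }
  lp <- log_softmax(m)
  -mean(lp[cbind(labels, seq_len(ncol(m)))])
}

log_softmax <- function(m) {
  mx <- apply(m, 2, max)
  z <- sweep(m, 2, mx)
  sweep(z, 2, log(colSums(exp(z))))
}

softmax_ce_grad <- function(m, labels) {
  p <- exp(log_softmax(m))
  y <- matrix(0, nrow(m), ncol(m))
  y[cbind(labels, seq_len(ncol(m)))] <- 1
  (p - y) / ncol(m)
}

#' Gradient arriving at a layer's spikes
#'
#' Error reaching a spike `x_k(t)` is the sum of the spatial
#' contributions routed back from both threshold pathways of the next
#' layer plus, for `t < T`, the temporal contribution from the same
#' pathway at `t + 1`. This helper performs the elementwise sum; the
#' spatial routing itself is the transpose of the synaptic connectivity
#' and the temporal term exists only for the reset-carrying pathway.
#'
#' @param grad_up_path0,grad_up_path1 Spatially routed gradients from the
#'   next layer's two pathways (`grad_up_path1` may be `NULL` when the
#'   next layer is single-threshold).
#' @param grad_future Temporal contribution from `t + 1` (`NULL` at
#'   `t = T`).
#' @return Elementwise sum, congruent with `grad_up_path0`.
#' @export
backward_spike <- function(grad_up_path0, grad_up_path1 = NULL,
                           grad_future = NULL) {
  g <- grad_up_path0
  for (extra in list(grad_up_path1, grad_future)) {
    if (!is.null(extra)) {
      check_congruent(g, extra)
      g <- g + extra
    }
  }
  g
}

#' Gradient arriving at a membrane potential
#'
#' Surrogate backpropagation through the spike generation: each pathway
#' contributes `grad_spike_k * h(v / Vth_k) / Vth_k` at time `t`, and the
#' spikes of `t + 1` contribute through the leak-and-reset carry
#' `leak * (1 - x0(t))` applied to the same expression evaluated at
#' `t + 1`.
#'
#' @param grad_spikes_t List of per-pathway gradients w.r.t. this layer's
#'   spikes at `t` (length 1 for LIF, 2 for DT-LIF).
#' @param membrane_t Membrane potentials at `t`.
#' @param thresholds Threshold scalar or pair.
#' @param grad_spikes_t1,membrane_t1,spike0_t Same quantities at `t + 1`
#'   plus the pathway-0 spikes at `t`; leave `NULL` at `t = T`.
#' @param leak Leakage factor.
#' @return Gradient w.r.t. `membrane_t`.
#' @export
backward_membrane <- function(grad_spikes_t, membrane_t, thresholds,
                              grad_spikes_t1 = NULL, membrane_t1 = NULL,
                              spike0_t = NULL, leak = 0.5) {
  if (!is.list(grad_spikes_t)) grad_spikes_t <- list(grad_spikes_t)
  if (length(grad_spikes_t) != length(thresholds)) {
    stop("one spike gradient per threshold pathway expected", call. = FALSE)
  }
  spike_to_vm <- function(grads, v) {
    g <- 0
    for (k in seq_along(grads)) {
      g <- g + grads[[k]] * surrogate_gradient(v / thresholds[k]) /
        thresholds[k]
    }
    g
  }
  gv <- spike_to_vm(grad_spikes_t, membrane_t)
  if (!is.null(grad_spikes_t1)) {
    if (is.null(membrane_t1) || is.null(spike0_t)) {
      stop("future term needs membrane_t1 and spike0_t", call. = FALSE)
    }
    if (!is.list(grad_spikes_t1)) grad_spikes_t1 <- list(grad_spikes_t1)
    gv <- gv + leak * (1 - spike0_t) * spike_to_vm(grad_spikes_t1,
                                                   membrane_t1)
  }
  gv
}

#' Gradient of the loss with respect to a firing threshold
#'
#' Each layer's thresholds are learned. Through the surrogate, a
#' threshold's gradient sums `grad_spike * h(v / Vth) * (-v / Vth^2)` over
#' all neurons (and timesteps) of its pathway; the update applied during
#' training is `-learning_rate * gradient`.
#'
#' @param grad_spikes Gradient w.r.t. the pathway's spikes (array, or list
#'   of arrays over timesteps).
#' @param membrane Matching membrane potentials (array or list).
#' @param vth The pathway's threshold (positive scalar).
#' @return Scalar gradient.
#' @export
threshold_gradient <- function(grad_spikes, membrane, vth) {
  if (!is.numeric(vth) || length(vth) != 1L || vth <= 0) {
    stop("threshold must be a positive scalar", call. = FALSE)
  }
  if (!is.list(grad_spikes)) grad_spikes <- list(grad_spikes)
  if (!is.list(membrane)) membrane <- list(membrane)
  g <- 0
  for (t in seq_along(grad_spikes)) {
    v <- membrane[[t]]
    g <- g + sum(grad_spikes[[t]] * surrogate_gradient(v / vth) *
                   (-v / vth^2))
  }
  g
}

new_gradient_set <- function(arch) {
  lapply(arch$layers, function(ly) {
    switch(ly$kind,
      conv = , fc = list(dW = NULL, dvth = 0),
      dtc = list(dW = NULL, dvth = c(0, 0)),
      fc_out = list(dW = NULL),
      NULL)
  })
}

#' Backpropagate through a traced forward pass
#'
#' Computes weight and threshold gradients for every layer by
#' spatio-temporal backpropagation with the rectangular surrogate
#' gradient. Errors reaching a dual-threshold layer arrive through both
#' pathway blocks of its concatenated output and converge onto the shared
#' membrane; only the reset-carrying pathway receives a temporal term.
#'
#' By default the membrane-to-membrane temporal chain is expanded exactly
#' one step (the spikes of `t + 1` contribute through the leak-and-reset
#' carry, deeper history does not); `temporal_membrane_path = TRUE`
#' switches to the full recursion of standard STBP, in which the carry
#' propagates the complete accumulated membrane gradient. At `T = 1` the
#' two are identical and no temporal code runs.
#'
#' @param arch,params Architecture and parameters used for the forward
#'   pass.
#' @param fwd Result of `network_forward(..., trace = TRUE)`.
#' @param labels Integer class labels (1-based), one per sample.
#' @param temporal_membrane_path Logical; see above.
#' @return A list with `grads` (per layer: `dW`, and `dvth` for spiking
#'   layers; threshold gradients are summed over neurons and timesteps,
#'   and the batch average enters through the mean-loss gradient),
#'   `loss`, and `output`.
#' @export
network_backward <- function(arch, params, fwd, labels,
                             temporal_membrane_path = FALSE) {
  if (is.null(fwd$trace)) {
    stop("network_backward() needs a traced forward pass", call. = FALSE)
  }
  nl <- length(arch$layers)
  tt <- fwd$timesteps
  bsz <- fwd$batch_size
  leak <- params$leak
  labels <- as.integer(labels)

  grads <- new_gradient_set(arch)
  loss <- compute_loss(fwd$output, labels)
  gout_final <- softmax_ce_grad(fwd$output, labels)

  # G[[t]]: gradient w.r.t. the *output* of the layer below the one being
  # processed, in that output's own shape
  G <- vector("list", tt)

  for (i in rev(seq_len(nl))) {
    ly <- arch$layers[[i]]
    pl <- params$layers[[i]]
    trc <- fwd$trace[[i]]

    if (ly$kind == "fc_out") {
      dW <- matrix(0, nrow(pl$W), ncol(pl$W))
      gv_next <- NULL
      for (t in rev(seq_len(tt))) {
        gv <- if (t == tt) gout_final else leak * gv_next
        dW <- dW + trc[[t]]$input %*% t(gv)
        g_in <- pl$W %*% gv
        G[[t]] <- reshape_to_input(g_in, ly, bsz)
        gv_next <- gv
      }
      grads[[i]]$dW <- dW
    } else if (ly$kind == "pool") {
      for (t in seq_len(tt)) {
        G[[t]] <- pool_backward(G[[t]], ly$k, trc[[t]]$in_dim,
                                fwd$pooling, trc[[t]]$argmax)
      }
    } else {
      dual <- ly$kind == "dtc"
      vth <- pl$vth
      is_conv <- ly$kind %in% c("conv", "dtc")
      if (is_conv) {
        pi <- conv_patch_index(ly$in_shape[1], ly$in_shape[2],
                               ly$in_shape[3], ly$k)
      }
      dW <- matrix(0, nrow(pl$W), ncol(pl$W))
      dvth <- if (dual) c(0, 0) else 0
      Gin <- vector("list", tt)

      gx0_next <- NULL; h0_next <- NULL
      S_next <- NULL; gv_next <- NULL
      for (t in rev(seq_len(tt))) {
        rec <- trc[[t]]
        v_t <- rec$membrane
        x0_t <- rec$spikes[[1]]
        h0 <- surrogate_gradient(v_t / vth[1])

        gout <- G[[t]]
        if (ly$kind == "fc" && !is.null(fwd$masks[[i]])) {
          gout <- gout * fwd$masks[[i]]
        }
        if (dual) {
          gs0 <- gout[, , seq_len(ly$n), , drop = FALSE]
          gs1 <- gout[, , ly$n + seq_len(ly$n), , drop = FALSE]
        } else {
          gs0 <- gout
          gs1 <- NULL
        }

        gx0 <- gs0
        if (t < tt) {
          carry <- if (temporal_membrane_path) gv_next
                   else gx0_next * h0_next / vth[1]
          gx0 <- gx0 + (-leak * v_t) * carry
        }
        S <- gx0 * h0 / vth[1]
        if (dual) {
          h1 <- surrogate_gradient(v_t / vth[2])
          S <- S + gs1 * h1 / vth[2]
        }
        gv <- S
        if (t < tt) {
          gv <- gv + leak * (1 - x0_t) *
            (if (temporal_membrane_path) gv_next else S_next)
        }

        dvth[1] <- dvth[1] + threshold_gradient(gx0, v_t, vth[1])
        if (dual) dvth[2] <- dvth[2] + threshold_gradient(gs1, v_t, vth[2])

        if (is_conv) {
          cb <- conv_backward(gv, rec$input, pl$W, pi)
          dW <- dW + cb$dW
          if (i > 1L) Gin[[t]] <- cb$dx
        } else {
          dW <- dW + rec$input %*% t(gv)
          Gin[[t]] <- reshape_to_input(pl$W %*% gv, ly, bsz)
        }

        gx0_next <- gx0; h0_next <- h0; S_next <- S; gv_next <- gv
      }
      grads[[i]]$dW <- dW
      grads[[i]]$dvth <- dvth
      G <- Gin
    }
  }
  list(grads = grads, loss = loss, output = fwd$output)
}

reshape_to_input <- function(g, ly, bsz) {
  if (length(ly$in_shape) == 3L) {
    dim(g) <- c(ly$in_shape, bsz)
  }
  g
}
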