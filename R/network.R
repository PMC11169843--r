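#' Initialise network parameters
#'
#' Creates synaptic weights and per-layer firing thresholds for an
#' architecture. Weights are drawn from a fan-in-scaled uniform
#' distribution `U(-gain/sqrt(fan_in), gain/sqrt(fan_in))`; all
#' thresholds start at a common value (default 0.5, the value the
#' networks are trained from), and DT-LIF layers get an identical pair so
#' the two pathways only diverge through learning.
#'
#' The gain (default 3) keeps early synaptic currents on the scale of the
#' 0.5 threshold: spiking neurons whose membranes sit far below threshold
#' never enter the rectangular surrogate window, and a silent layer
#' passes no gradient at all, so unit-gain initialisation can leave the
#' whole network untrainable.
#'
#' @param arch An [parse_arch()] result.
#' @param leak Shared leakage factor \eqn{\lambda} (default 0.5).
#' @param threshold_init Initial threshold value for every spiking layer.
#' @param seed Optional integer seed for reproducible draws.
#' @param gain Multiplier on the fan-in-scaled weight range.
#' @return An object of class `scnn_params`.
#' @export
init_params <- function(arch, leak = 0.5, threshold_init = 0.5,
                        seed = NULL, gain = 3) {
  stopifnot(inherits(arch, "scnn_arch"))
  if (!is.null(seed)) set.seed(seed)
  layers <- vector("list", length(arch$layers))
  for (i in seq_along(arch$layers)) {
    ly <- arch$layers[[i]]
    layers[[i]] <- switch(ly$kind,
      conv = {
        fan_in <- ly$k * ly$k * ly$in_shape[3]
        s <- gain / sqrt(fan_in)
        list(W = matrix(stats::runif(fan_in * ly$n, -s, s), fan_in, ly$n),
             vth = threshold_init)
      },
      dtc = {
        fan_in <- ly$k * ly$k * ly$in_shape[3]
        s <- gain / sqrt(fan_in)
        list(W = matrix(stats::runif(fan_in * ly$n, -s, s), fan_in, ly$n),
             vth = c(threshold_init, threshold_init))
      },
      pool = NULL,
      fc = {
        n_in <- prod(ly$in_shape)
        s <- gain / sqrt(n_in)
        list(W = matrix(stats::runif(n_in * ly$n, -s, s), n_in, ly$n),
             vth = threshold_init)
      },
      fc_out = {
        n_in <- prod(ly$in_shape)
        s <- gain / sqrt(n_in)
        list(W = matrix(stats::runif(n_in * ly$n, -s, s), n_in, ly$n))
      }
    )
  }
  structure(list(leak = leak, layers = layers, arch_text = arch$text),
            class = "scnn_params")
}

#' @export
print.scnn_params <- function(x, ...) {
  nw <- sum(vapply(x$layers, function(l) {
    if (is.null(l$W)) 0L else length(l$W)
  }, integer(1)))
  cat(sprintf("<scnn_params> for '%s': %d weights, leak = %g\n",
              x$arch_text, nw, x$leak))
  invisible(x)
}

as_image_batch <- function(images, input_shape) {
  d <- dim(images)
  if (is.null(d)) stop("images must be an array", call. = FALSE)
  if (length(d) == 3L && all(d == input_shape)) {
    dim(images) <- c(d, 1L)
  } else if (length(d) == 3L && input_shape[3] == 1L &&
             all(d[1:2] == input_shape[1:2])) {
    images <- array(images, c(input_shape, d[3]))
  } else if (length(d) != 4L || !all(d[1:3] == input_shape)) {
    stop(sprintf("image batch %s does not match input shape %s",
                 paste(d, collapse = "x"),
                 paste(input_shape, collapse = "x")), call. = FALSE)
  }
  images
}

#' Synaptic current of one layer
#'
#' Computes the weighted sum of presynaptic activity,
#' \eqn{i_i(t) = \sum_j w_{ij} x_j(t)}. For convolutional layers this is a
#' same-padding stride-1 convolution; for fully connected layers a matrix
#' product. At the coding (first) layer `x` holds real pixel values and
#' the sum needs multiply-accumulate (MAC) operations; at every other
#' layer `x` is binary spikes and accumulate-only (ACC) operations
#' suffice.
#'
#' @param x Input activity: `(h, w, c)` or `(h, w, c, batch)` array for a
#'   convolutional layer, a vector or `(units, batch)` matrix for a fully
#'   connected layer.
#' @param weights Weight matrix in canonical layout: `k*k*cin` rows by
#'   `cout` columns for convolutions (patch order: kernel row fastest,
#'   then kernel column, then input channel), `n_in` by `n_out` otherwise.
#' @param layer One element of `arch$layers`.
#' @return Current with the layer's output shape (for `dtc` layers the
#'   `cout/2` membrane maps, since both pathways share one current).
#' @export
synaptic_current <- function(x, weights, layer) {
  if (layer$kind %in% c("conv", "dtc")) {
    single <- length(dim(x)) == 3L
    if (single) dim(x) <- c(dim(x), 1L)
    d <- dim(x)
    if (!all(d[1:3] == layer$in_shape)) {
      stop("input shape does not match the layer", call. = FALSE)
    }
    if (nrow(weights) != layer$k^2 * layer$in_shape[3] ||
        ncol(weights) != layer$n) {
      stop("weight matrix shape does not match the layer", call. = FALSE)
    }
    pi <- conv_patch_index(d[1], d[2], d[3], layer$k)
    out <- conv_forward(x, weights, pi)
    if (single) dim(out) <- dim(out)[1:3]
    out
  } else if (layer$kind %in% c("fc", "fc_out")) {
    xm <- if (is.matrix(x)) x else matrix(x)
    if (nrow(xm) != nrow(weights)) {
      stop("input length does not match the weight matrix", call. = FALSE)
    }
    cur <- fc_forward(xm, weights)
    if (!is.matrix(x)) cur <- drop(cur)
    cur
  } else {
    stop("pooling layers carry no weights", call. = FALSE)
  }
}

#' One timestep of a dual-threshold convolutional layer
#'
#' Applies the layer's convolution to the input, advances the DT-LIF
#' membranes one step, and concatenates the two resulting spiking feature
#' maps along the channel dimension (all pathway-0 maps first, then all
#' pathway-1 maps), so `cout/2` membrane maps emit `cout` spike maps.
#'
#' @param x Layer input, `(h, w, cin)` array (single sample).
#' @param weights Canonical conv weight matrix (`k*k*cin` by `cout/2`).
#' @param cfg [neuron_config()] with the threshold pair.
#' @param layer The layer's `scnn_arch` entry.
#' @param state_prev Previous `neuron_state`, or `NULL` for a zero initial
#'   state.
#' @return A list with `state` (the new `neuron_state`) and `output` (the
#'   concatenated `(h, w, cout)` binary array).
#' @export
dtc_forward <- function(x, weights, cfg, layer, state_prev = NULL) {
  stopifnot(layer$kind == "dtc", length(cfg$thresholds) == 2L)
  cur <- synaptic_current(x, weights, layer)
  vshape <- layer$vm_shape
  if (is.null(state_prev)) {
    v_prev <- array(0, vshape)
    s0_prev <- array(0, vshape)
  } else {
    v_prev <- state_prev$membrane
    s0_prev <- state_prev$spikes[[1]]
  }
  t_new <- if (is.null(state_prev)) 1L else state_prev$time_index + 1L
  st <- dtlif_step(v_prev, s0_prev, cur, cfg, t_new)
  out <- array(0, layer$out_shape)
  out[, , seq_len(layer$n)] <- st$spikes[[1]]
  out[, , layer$n + seq_len(layer$n)] <- st$spikes[[2]]
  list(state = st, output = out)
}

#' Multi-timestep forward pass
#'
#' Runs an SCNN or DT-SCNN forward for `timesteps` ticks. The real-valued
#' image is presented to the coding layer at every tick (direct encoding);
#' spiking layers update leaky integrate-and-fire membranes with hard
#' reset on the (pathway-0) threshold; pooling averages binary spike maps
#' (fractional pooled values feed the next layer's weighted sum as graded
#' inputs); the final layer accumulates current into leaky, non-spiking
#' membranes whose values at the last tick are the output, one per class.
#' All membranes and spikes start at zero.
#'
#' @param arch,params Architecture and matching parameters.
#' @param images `(h, w, c, batch)` array (a single `(h, w, c)` image is
#'   accepted).
#' @param timesteps Number of ticks `T >= 1`.
#' @param trace If `TRUE`, record per-layer, per-timestep currents,
#'   membranes and spikes (needed for backpropagation and analysis).
#' @param training If `TRUE`, apply dropout masks (probability
#'   `dropout_p`) to spiking fully connected outputs; one mask per layer,
#'   shared across timesteps.
#' @param dropout_p Dropout probability used when `training = TRUE`.
#' @param pooling `"avg"` (default) or `"max"`.
#' @return A list with `output` (`classes x batch` membrane potentials at
#'   the final timestep), and when requested `trace` (nested list
#'   `[[layer]][[t]]` with `input`, `current`, `membrane`, `spikes`,
#'   `output`) plus the dropout `masks`.
#' @export
network_forward <- function(arch, params, images, timesteps = 1L,
                            trace = FALSE, training = FALSE,
                            dropout_p = 0, pooling = c("avg", "max")) {
  pooling <- match.arg(pooling)
  stopifnot(inherits(arch, "scnn_arch"), inherits(params, "scnn_params"))
  timesteps <- as.integer(timesteps)
  if (is.na(timesteps) || timesteps < 1L) {
    stop("`timesteps` must be a positive integer", call. = FALSE)
  }
  images <- as_image_batch(images, arch$input_shape)
  bsz <- dim(images)[4]
  nl <- length(arch$layers)
  leak <- params$leak

  pidx <- vector("list", nl)
  for (i in seq_len(nl)) {
    ly <- arch$layers[[i]]
    if (ly$kind %in% c("conv", "dtc")) {
      pidx[[i]] <- conv_patch_index(ly$in_shape[1], ly$in_shape[2],
                                    ly$in_shape[3], ly$k)
    }
  }

  masks <- vector("list", nl)
  if (training && dropout_p > 0) {
    for (i in seq_len(nl)) {
      ly <- arch$layers[[i]]
      if (ly$kind == "fc") {
        keep <- (matrix(stats::runif(ly$n * bsz), ly$n, bsz) >= dropout_p) + 0
        masks[[i]] <- keep / (1 - dropout_p)
      }
    }
  }

  v <- vector("list", nl)     # membranes
  s0 <- vector("list", nl)    # pathway-0 spikes (reset carriers)
  tr <- if (trace) lapply(seq_len(nl), function(i) vector("list", timesteps))

  out_vm <- NULL
  for (t in seq_len(timesteps)) {
    a <- images
    for (i in seq_len(nl)) {
      ly <- arch$layers[[i]]
      pl <- params$layers[[i]]
      rec <- NULL
      if (ly$kind %in% c("conv", "dtc")) {
        input_t <- a
        cur <- conv_forward(a, pl$W, pidx[[i]])
        if (t == 1L) {
          vshape <- c(ly$vm_shape, bsz)
          v[[i]] <- array(0, vshape)
          s0[[i]] <- array(0, vshape)
        }
        vm <- leak * v[[i]] * (1 - s0[[i]]) + cur
        x0 <- (vm >= pl$vth[1]) + 0
        v[[i]] <- vm
        s0[[i]] <- x0
        if (ly$kind == "conv") {
          a <- x0
          if (trace) rec <- list(input = input_t, current = cur,
                                 membrane = vm, spikes = list(x0),
                                 output = a)
        } else {
          x1 <- (vm >= pl$vth[2]) + 0
          a <- array(0, c(ly$out_shape, bsz))
          a[, , seq_len(ly$n), ] <- x0
          a[, , ly$n + seq_len(ly$n), ] <- x1
          if (trace) rec <- list(input = input_t, current = cur,
                                 membrane = vm, spikes = list(x0, x1),
                                 output = a)
        }
      } else if (ly$kind == "pool") {
        input_dim <- dim(a)
        a <- pool_forward(a, ly$k, pooling)
        if (trace) rec <- list(in_dim = input_dim,
                               argmax = attr(a, "pool_argmax"))
      } else if (ly$kind == "fc") {
        dim(a) <- c(prod(ly$in_shape), bsz)
        input_t <- a
        cur <- fc_forward(a, pl$W)
        if (t == 1L) {
          v[[i]] <- matrix(0, ly$n, bsz)
          s0[[i]] <- matrix(0, ly$n, bsz)
        }
        vm <- leak * v[[i]] * (1 - s0[[i]]) + cur
        x0 <- (vm >= pl$vth[1]) + 0
        v[[i]] <- vm
        s0[[i]] <- x0
        a <- if (is.null(masks[[i]])) x0 else x0 * masks[[i]]
        if (trace) rec <- list(input = input_t, current = cur,
                               membrane = vm, spikes = list(x0),
                               output = a)
      } else { # fc_out: leaky accumulator, never spikes, never resets
        dim(a) <- c(prod(ly$in_shape), bsz)
        input_t <- a
        cur <- fc_forward(a, pl$W)
        if (t == 1L) v[[i]] <- matrix(0, ly$n, bsz)
        vm <- leak * v[[i]] + cur
        v[[i]] <- vm
        out_vm <- vm
        a <- vm
        if (trace) rec <- list(input = input_t, current = cur,
                               membrane = vm)
      }
      if (trace) tr[[i]][[t]] <- rec
    }
  }

  res <- list(output = out_vm)
  if (trace) {
    res$trace <- tr
    res$masks <- masks
    res$timesteps <- timesteps
    res$pooling <- pooling
    res$batch_size <- bsz
  }
  res
}

#' Flatten a forward trace into a named archive
#'
#' Serialises a traced forward pass into a flat named list keyed
#' `"layer{L}/t{T}/{membrane|spikes|current}"`, suitable for JSON export
#' or inspection.
#'
#' @param fwd Result of `network_forward(..., trace = TRUE)`.
#' @return Named list of numeric arrays.
#' @export
trace_archive <- function(fwd) {
  if (is.null(fwd$trace)) stop("forward pass was not traced", call. = FALSE)
  out <- list()
  for (li in seq_along(fwd$trace)) {
    for (t in seq_along(fwd$trace[[li]])) {
      rec <- fwd$trace[[li]][[t]]
      if (is.null(rec) || is.null(rec$membrane)) next
      key <- sprintf("layer%d/t%d", li, t)
      out[[paste0(key, "/membrane")]] <- rec$membrane
      out[[paste0(key, "/current")]] <- rec$current
      if (!is.null(rec$spikes)) {
        for (k in seq_along(rec$spikes)) {
          out[[sprintf("%s/spikes%d", key, k - 1L)]] <- rec$spikes[[k]]
        }
      }
    }
  }
  out
}
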