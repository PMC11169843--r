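# Independent scalar oracles used across the suite.
#
# oracle_forward/oracle_backward evaluate the neuron dynamics and the
# spatio-temporal chain rule neuron by neuron with explicit loops: no
# im2col, no vectorised comparisons, no code shared with the package's
# forward/backward implementation. oracle_count_ops counts synaptic
# multiply/accumulate events one by one in a literal nested-loop forward
# pass.

oracle_surrogate <- function(u) if (abs(u - 1) < 0.5) 1 else 0

# canonical weight-matrix row for kernel offset (di, dj) and channel ci
oracle_wrow <- function(di, dj, ci, k) {
  p <- (k - 1) %/% 2
  (ci - 1) * k * k + (dj + p) * k + (di + p + 1)
}

oracle_conv <- function(a, wmat, k, cout) {
  d <- dim(a)
  p <- (k - 1) %/% 2
  out <- array(0, c(d[1], d[2], cout))
  for (co in seq_len(cout)) {
    for (i in seq_len(d[1])) {
      for (j in seq_len(d[2])) {
        acc <- 0
        for (ci in seq_len(d[3])) {
          for (dj in -p:p) {
            for (di in -p:p) {
              ii <- i + di; jj <- j + dj
              if (ii >= 1 && ii <= d[1] && jj >= 1 && jj <= d[2]) {
                acc <- acc + wmat[oracle_wrow(di, dj, ci, k), co] *
                  a[ii, jj, ci]
              }
            }
          }
        }
        out[i, j, co] <- acc
      }
    }
  }
  out
}

oracle_pool_avg <- function(a, s) {
  d <- dim(a)
  h2 <- d[1] %/% s; w2 <- d[2] %/% s
  out <- array(0, c(h2, w2, d[3]))
  for (c in seq_len(d[3])) {
    for (i in seq_len(h2)) {
      for (j in seq_len(w2)) {
        acc <- 0
        for (di in seq_len(s)) {
          for (dj in seq_len(s)) {
            acc <- acc + a[(i - 1) * s + di, (j - 1) * s + dj, c]
          }
        }
        out[i, j, c] <- acc / (s * s)
      }
    }
  }
  out
}

oracle_flatten <- function(a) as.vector(a)   # column-major, matches dim<-

oracle_fc <- function(x, w) {
  n_out <- ncol(w)
  out <- numeric(n_out)
  for (u in seq_len(n_out)) {
    acc <- 0
    for (j in seq_len(nrow(w))) acc <- acc + w[j, u] * x[j]
    out[u] <- acc
  }
  out
}

# Forward pass for ONE sample; returns all per-layer per-timestep scalars.
oracle_forward <- function(arch, params, image, timesteps) {
  nl <- length(arch$layers)
  leak <- params$leak
  st <- lapply(seq_len(nl), function(i) vector("list", timesteps))
  v <- vector("list", nl)
  x0 <- vector("list", nl)
  out_vm <- NULL
  for (t in seq_len(timesteps)) {
    a <- image
    for (i in seq_len(nl)) {
      ly <- arch$layers[[i]]
      pl <- params$layers[[i]]
      if (ly$kind %in% c("conv", "dtc")) {
        input <- a
        cur <- oracle_conv(a, pl$W, ly$k, ly$n)
        if (t == 1L) {
          v[[i]] <- array(0, dim(cur)); x0[[i]] <- array(0, dim(cur))
        }
        vm <- leak * v[[i]] * (1 - x0[[i]]) + cur
        s0 <- (vm >= pl$vth[1]) + 0
        v[[i]] <- vm; x0[[i]] <- s0
        if (ly$kind == "dtc") {
          s1 <- (vm >= pl$vth[2]) + 0
          a <- array(0, c(dim(vm)[1:2], 2 * ly$n))
          a[, , seq_len(ly$n)] <- s0
          a[, , ly$n + seq_len(ly$n)] <- s1
          st[[i]][[t]] <- list(input = input, cur = cur, v = vm,
                               s0 = s0, s1 = s1, out = a)
        } else {
          a <- s0
          st[[i]][[t]] <- list(input = input, cur = cur, v = vm,
                               s0 = s0, out = a)
        }
      } else if (ly$kind == "pool") {
        st[[i]][[t]] <- list(in_dim = dim(a))
        a <- oracle_pool_avg(a, ly$k)
      } else if (ly$kind == "fc") {
        x <- oracle_flatten(a)
        cur <- oracle_fc(x, pl$W)
        if (t == 1L) {
          v[[i]] <- numeric(ly$n); x0[[i]] <- numeric(ly$n)
        }
        vm <- leak * v[[i]] * (1 - x0[[i]]) + cur
        s0 <- (vm >= pl$vth[1]) + 0
        v[[i]] <- vm; x0[[i]] <- s0
        a <- s0
        st[[i]][[t]] <- list(input = x, cur = cur, v = vm, s0 = s0,
                             out = a)
      } else {
        x <- oracle_flatten(a)
        cur <- oracle_fc(x, pl$W)
        if (t == 1L) v[[i]] <- numeric(ly$n)
        vm <- leak * v[[i]] + cur
        v[[i]] <- vm
        out_vm <- vm
        a <- vm
        st[[i]][[t]] <- list(input = x, cur = cur, v = vm)
      }
    }
  }
  list(states = st, output = out_vm)
}

oracle_softmax_grad <- function(vm, label) {
  p <- exp(vm - max(vm)); p <- p / sum(p)
  y <- numeric(length(vm)); y[label] <- 1
  p - y
}

# gradient w.r.t. a conv layer's input, by literal adjoint loops
oracle_conv_input_grad <- function(gv, wmat, k, in_dim) {
  p <- (k - 1) %/% 2
  d <- dim(gv)
  dx <- array(0, in_dim)
  for (co in seq_len(d[3])) {
    for (i in seq_len(d[1])) {
      for (j in seq_len(d[2])) {
        g <- gv[i, j, co]
        if (g == 0) next
        for (ci in seq_len(in_dim[3])) {
          for (dj in -p:p) {
            for (di in -p:p) {
              ii <- i + di; jj <- j + dj
              if (ii >= 1 && ii <= in_dim[1] && jj >= 1 && jj <= in_dim[2]) {
                dx[ii, jj, ci] <- dx[ii, jj, ci] +
                  wmat[oracle_wrow(di, dj, ci, k), co] * g
              }
            }
          }
        }
      }
    }
  }
  dx
}

oracle_conv_weight_grad <- function(gv, input, k, nvm) {
  in_dim <- dim(input)
  d <- dim(gv)
  dW <- matrix(0, k * k * in_dim[3], nvm)
  for (co in seq_len(nvm)) {
    for (i in seq_len(d[1])) {
      for (j in seq_len(d[2])) {
        g <- gv[i, j, co]
        if (g == 0) next
        p <- (k - 1) %/% 2
        for (ci in seq_len(in_dim[3])) {
          for (dj in -p:p) {
            for (di in -p:p) {
              ii <- i + di; jj <- j + dj
              if (ii >= 1 && ii <= in_dim[1] && jj >= 1 && jj <= in_dim[2]) {
                q <- oracle_wrow(di, dj, ci, k)
                dW[q, co] <- dW[q, co] + input[ii, jj, ci] * g
              }
            }
          }
        }
      }
    }
  }
  dW
}

oracle_pool_input_grad <- function(g2, s, in_dim) {
  dx <- array(0, in_dim)
  d2 <- dim(g2)
  for (c in seq_len(d2[3])) {
    for (i in seq_len(d2[1])) {
      for (j in seq_len(d2[2])) {
        for (di in seq_len(s)) {
          for (dj in seq_len(s)) {
            dx[(i - 1) * s + di, (j - 1) * s + dj, c] <-
              g2[i, j, c] / (s * s)
          }
        }
      }
    }
  }
  dx
}

# Backward pass for ONE sample. Returns per-layer dW and dvth (threshold
# gradients NOT batch-averaged; caller divides). `full_temporal` selects
# the complete membrane-carry recursion instead of the one-step
# expansion.
oracle_backward <- function(arch, params, fw, label, timesteps,
                            full_temporal = FALSE) {
  nl <- length(arch$layers)
  leak <- params$leak
  st <- fw$states
  grads <- vector("list", nl)
  G <- vector("list", timesteps)   # grad w.r.t. output of layer below

  for (i in rev(seq_len(nl))) {
    ly <- arch$layers[[i]]
    pl <- params$layers[[i]]
    if (ly$kind == "fc_out") {
      dW <- matrix(0, nrow(pl$W), ncol(pl$W))
      gv_next <- NULL
      for (t in rev(seq_len(timesteps))) {
        gv <- if (t == timesteps) oracle_softmax_grad(fw$output, label)
              else leak * gv_next
        x <- st[[i]][[t]]$input
        for (u in seq_along(gv)) {
          for (j in seq_along(x)) dW[j, u] <- dW[j, u] + x[j] * gv[u]
        }
        gin <- numeric(length(x))
        for (j in seq_along(x)) {
          for (u in seq_along(gv)) gin[j] <- gin[j] + pl$W[j, u] * gv[u]
        }
        if (length(ly$in_shape) == 3L) dim(gin) <- ly$in_shape
        G[[t]] <- gin
        gv_next <- gv
      }
      grads[[i]] <- list(dW = dW)
    } else if (ly$kind == "pool") {
      for (t in seq_len(timesteps)) {
        G[[t]] <- oracle_pool_input_grad(G[[t]], ly$k,
                                         st[[i]][[t]]$in_dim)
      }
    } else {
      dual <- ly$kind == "dtc"
      vth <- pl$vth
      dW <- matrix(0, nrow(pl$W), ncol(pl$W))
      dvth <- if (dual) c(0, 0) else 0
      Gin <- vector("list", timesteps)
      gx0_next <- NULL; S_next <- NULL; gv_next <- NULL; v_next <- NULL
      for (t in rev(seq_len(timesteps))) {
        rec <- st[[i]][[t]]
        v_t <- rec$v
        if (dual) {
          gs0 <- G[[t]][, , seq_len(ly$n), drop = FALSE]
          gs1 <- G[[t]][, , ly$n + seq_len(ly$n), drop = FALSE]
          dim(gs0) <- dim(v_t); dim(gs1) <- dim(v_t)
        } else {
          gs0 <- G[[t]]
          gs1 <- NULL
        }
        h0 <- array(vapply(v_t / vth[1], oracle_surrogate, numeric(1)),
                    dim(v_t) %||% length(v_t))
        gx0 <- gs0
        if (t < timesteps) {
          if (full_temporal) {
            gx0 <- gx0 + (-leak * v_t) * gv_next
          } else {
            h0n <- array(vapply(v_next / vth[1], oracle_surrogate,
                                numeric(1)),
                         dim(v_next) %||% length(v_next))
            gx0 <- gx0 + (-leak * v_t) * (gx0_next * h0n / vth[1])
          }
        }
        S <- gx0 * h0 / vth[1]
        if (dual) {
          h1 <- array(vapply(v_t / vth[2], oracle_surrogate, numeric(1)),
                      dim(v_t) %||% length(v_t))
          S <- S + gs1 * h1 / vth[2]
        }
        gv <- S
        if (t < timesteps) {
          carry <- if (full_temporal) gv_next else S_next
          gv <- gv + leak * (1 - rec$s0) * carry
        }
        dvth[1] <- dvth[1] + sum(gx0 * h0 * (-v_t / vth[1]^2))
        if (dual) dvth[2] <- dvth[2] + sum(gs1 * h1 * (-v_t / vth[2]^2))
        if (ly$kind %in% c("conv", "dtc")) {
          dW <- dW + oracle_conv_weight_grad(gv, rec$input, ly$k, ly$n)
          if (i > 1L) {
            Gin[[t]] <- oracle_conv_input_grad(gv, pl$W, ly$k,
                                               dim(rec$input))
          }
        } else {
          x <- rec$input
          for (u in seq_along(gv)) {
            for (j in seq_along(x)) dW[j, u] <- dW[j, u] + x[j] * gv[u]
          }
          gin <- numeric(length(x))
          for (j in seq_along(x)) {
            for (u in seq_along(gv)) gin[j] <- gin[j] + pl$W[j, u] * gv[u]
          }
          if (length(ly$in_shape) == 3L) dim(gin) <- ly$in_shape
          Gin[[t]] <- gin
        }
        gx0_next <- gx0; S_next <- S; gv_next <- gv; v_next <- v_t
      }
      grads[[i]] <- list(dW = dW, dvth = dvth)
      G <- Gin
    }
  }
  grads
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Oracle gradients for a batch: mean loss over samples; weight gradients
# add up (the loss divides by batch size), thresholds likewise then the
# implementation averages over the batch.
oracle_batch_gradients <- function(arch, params, images, labels,
                                   timesteps, full_temporal = FALSE) {
  bsz <- dim(images)[4]
  total <- NULL
  for (b in seq_len(bsz)) {
    img <- array(images[, , , b], dim(images)[1:3])
    fw <- oracle_forward(arch, params, img, timesteps)
    g <- oracle_backward(arch, params, fw, labels[b], timesteps,
                         full_temporal)
    if (is.null(total)) {
      total <- g
    } else {
      for (i in seq_along(g)) {
        if (is.null(g[[i]])) next
        total[[i]]$dW <- total[[i]]$dW + g[[i]]$dW
        if (!is.null(g[[i]]$dvth)) {
          total[[i]]$dvth <- total[[i]]$dvth + g[[i]]$dvth
        }
      }
    }
  }
  for (i in seq_along(total)) {
    if (is.null(total[[i]])) next
    total[[i]]$dW <- total[[i]]$dW / bsz
    if (!is.null(total[[i]]$dvth)) {
      total[[i]]$dvth <- total[[i]]$dvth / bsz
    }
  }
  total
}

# literal nested-loop count of synaptic multiply/accumulate events
oracle_count_ops <- function(layer) {
  if (layer$kind %in% c("conv", "dtc")) {
    n <- 0
    for (co in seq_len(layer$n)) {
      for (i in seq_len(layer$out_shape[1])) {
        for (j in seq_len(layer$out_shape[2])) {
          for (ci in seq_len(layer$in_shape[3])) {
            for (dj in seq_len(layer$k)) {
              for (di in seq_len(layer$k)) n <- n + 1
            }
          }
        }
      }
    }
    n
  } else if (layer$kind %in% c("fc", "fc_out")) {
    n <- 0
    for (u in seq_len(layer$n)) {
      for (j in seq_len(prod(layer$in_shape))) n <- n + 1
    }
    n
  } else {
    0
  }
}

# small helper: parameters with hand-set weights for tiny nets
tiny_params <- function(arch, weights, thresholds, leak = 0.5) {
  layers <- vector("list", length(arch$layers))
  for (i in seq_along(arch$layers)) {
    ly <- arch$layers[[i]]
    if (ly$kind == "pool") next
    l <- list(W = weights[[i]])
    if (ly$kind != "fc_out") l$vth <- thresholds[[i]]
    layers[[i]] <- l
  }
  structure(list(leak = leak, layers = layers, arch_text = arch$text),
            class = "scnn_params")
}
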