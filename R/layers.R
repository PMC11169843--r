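# Low-level batched layer primitives. Activations are stored as arrays of
# dimension (h, w, c, batch) while spatial and (units, batch) after
# flattening. Convolution is same-padding stride-1, realised as an
# im2col gather followed by one matrix product per sample; the patch
# column order is (kernel row, kernel column, input channel), row fastest,
# which fixes the weight-matrix layout (k*k*cin rows by cout columns).

conv_patch_index <- function(h, w, cin, k) {
  p <- (k - 1L) %/% 2L
  hp <- h + 2L * p
  wp <- w + 2L * p
  pos_i <- rep(seq_len(h), times = w)
  pos_j <- rep(seq_len(w), each = h)
  base <- (pos_j + p - 1L) * hp + (pos_i + p)   # flat center, channel 1
  off <- as.vector(outer(
    seq(-p, p),
    as.vector(outer((-p):p * hp, (seq_len(cin) - 1L) * hp * wp, "+")),
    "+"
  ))
  idx <- outer(base, off, "+")
  list(idx = idx, hp = hp, wp = wp, pad = p)
}

pad_input <- function(x, pad) {
  d <- dim(x)
  if (pad == 0L) return(x)
  xp <- array(0, c(d[1] + 2L * pad, d[2] + 2L * pad, d[3], d[4]))
  xp[pad + seq_len(d[1]), pad + seq_len(d[2]), , ] <- x
  xp
}

im2col <- function(x, pi) {
  # x: (h, w, cin, B) -> list of B patch matrices (h*w) x (k*k*cin)
  d <- dim(x)
  xp <- pad_input(x, pi$pad)
  per <- prod(dim(xp)[1:3])
  xf <- as.vector(xp)
  lapply(seq_len(d[4]), function(b) {
    m <- xf[(b - 1L) * per + pi$idx]
    dim(m) <- dim(pi$idx)
    m
  })
}

conv_forward <- function(x, wmat, pi) {
  d <- dim(x)
  cout <- ncol(wmat)
  patches <- im2col(x, pi)
  out <- array(0, c(d[1], d[2], cout, d[4]))
  for (b in seq_len(d[4])) {
    out[, , , b] <- patches[[b]] %*% wmat
  }
  out
}

conv_backward <- function(dout, x, wmat, pi) {
  # dout: (h, w, cout, B); returns dW and gradient w.r.t. x
  d <- dim(x)
  npos <- d[1] * d[2]
  cout <- ncol(wmat)
  patches <- im2col(x, pi)
  hp <- pi$hp; wp <- pi$wp
  per <- hp * wp * d[3]
  dW <- matrix(0, nrow(wmat), cout)
  dxp <- array(0, c(hp, wp, d[3], d[4]))
  dxpf <- as.vector(dxp)
  for (b in seq_len(d[4])) {
    db <- matrix(dout[, , , b], npos, cout)
    dW <- dW + crossprod(patches[[b]], db)
    dp <- db %*% t(wmat)
    offb <- (b - 1L) * per
    # per kernel-offset column the output->input map is injective
    for (q in seq_len(ncol(pi$idx))) {
      tgt <- offb + pi$idx[, q]
      dxpf[tgt] <- dxpf[tgt] + dp[, q]
    }
  }
  dim(dxpf) <- c(hp, wp, d[3], d[4])
  p <- pi$pad
  dx <- dxpf[p + seq_len(d[1]), p + seq_len(d[2]), , , drop = FALSE]
  list(dW = dW, dx = dx)
}

pool_forward <- function(x, s, mode = c("avg", "max")) {
  mode <- match.arg(mode)
  d <- dim(x)
  h2 <- d[1] %/% s
  w2 <- d[2] %/% s
  xc <- x[seq_len(h2 * s), seq_len(w2 * s), , , drop = FALSE]
  dim(xc) <- c(s, h2, s, w2, d[3] * d[4])
  xc <- aperm(xc, c(1, 3, 2, 4, 5))
  dim(xc) <- c(s * s, h2 * w2 * d[3] * d[4])
  out <- if (mode == "avg") colMeans(xc) else apply(xc, 2, max)
  dim(out) <- c(h2, w2, d[3], d[4])
  attr(out, "pool_argmax") <- if (mode == "max") max.col(t(xc), "first") else NULL
  out
}

pool_backward <- function(dout, s, in_dim, mode = c("avg", "max"),
                          argmax = NULL) {
  mode <- match.arg(mode)
  d2 <- dim(dout)
  h2 <- d2[1]; w2 <- d2[2]
  ncols <- h2 * w2 * d2[3] * d2[4]
  if (mode == "avg") {
    g <- matrix(rep(as.vector(dout) / (s * s), each = s * s), s * s, ncols)
  } else {
    g <- matrix(0, s * s, ncols)
    g[cbind(argmax, seq_len(ncols))] <- as.vector(dout)
  }
  dim(g) <- c(s, s, h2, w2, d2[3] * d2[4])
  g <- aperm(g, c(1, 3, 2, 4, 5))
  dim(g) <- c(h2 * s, w2 * s, d2[3], d2[4])
  if (h2 * s == in_dim[1] && w2 * s == in_dim[2]) {
    dim(g) <- c(in_dim[1], in_dim[2], d2[3], d2[4])
    return(g)
  }
  dx <- array(0, c(in_dim[1], in_dim[2], d2[3], d2[4]))
  dx[seq_len(h2 * s), seq_len(w2 * s), , ] <- g
  dx
}

fc_forward <- function(x, w) {
  crossprod(w, x)                       # (n_out x B)
}

fc_backward <- function(dout, x, w) {
  list(dW = x %*% t(dout), dx = w %*% dout)
}
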