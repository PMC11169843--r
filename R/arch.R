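#' Parse an architecture string
#'
#' Networks are described by compact strings such as
#' `"16c5-p2-40c5-p2-256fc-10fc"`: tokens separated by `-`, where
#' `<n>c<k>` is a spiking convolutional layer with `n` output channels and
#' an odd `k`-by-`k` kernel (same padding, stride 1), `<n>dtc<k>` is a
#' dual-threshold convolutional layer with `n` membrane-potential maps
#' (emitting `2n` spiking feature maps), `p<s>` is an `s`-by-`s`
#' stride-`s` pooling layer, and `<n>fc` is a fully connected layer. The
#' final `fc` token becomes the non-spiking output accumulator whose
#' membrane potentials at the last timestep are the network output, one
#' per class.
#'
#' The first layer must be convolutional (`c` or `dtc`): it is the coding
#' layer and receives the real-valued image directly at every timestep.
#'
#' @param text Architecture string (case-sensitive).
#' @param input_shape Integer vector `(height, width, channels)`.
#' @return An object of class `scnn_arch`: a list with `text`,
#'   `input_shape` and `layers`, each layer holding its kind
#'   (`conv`, `dtc`, `pool`, `fc`, `fc_out`), size `n`, kernel/window `k`,
#'   whether it spikes, and propagated input/output shapes.
#' @examples
#' parse_arch("16c5-p2-40c5-p2-256fc-10fc", c(28, 28, 1))
#' parse_arch("8dtc5-p2-20dtc5-p2-256fc-10fc", c(28, 28, 1))
#' @export
parse_arch <- function(text, input_shape) {
  if (!is.character(text) || length(text) != 1L || is.na(text) ||
      !nzchar(text)) {
    stop("architecture string must be a non-empty character scalar",
         call. = FALSE)
  }
  input_shape <- as.integer(input_shape)
  if (length(input_shape) != 3L || anyNA(input_shape) ||
      any(input_shape < 1L)) {
    stop("`input_shape` must be three positive integers (h, w, c)",
         call. = FALSE)
  }
  tokens <- strsplit(text, "-", fixed = TRUE)[[1]]
  if (length(tokens) < 2L) {
    stop("architecture needs at least one hidden layer and one fc output",
         call. = FALSE)
  }

  layers <- vector("list", length(tokens))
  cur <- input_shape   # c(h, w, c) while spatial; after fc: c(units)
  spatial <- TRUE
  for (i in seq_along(tokens)) {
    tok <- tokens[i]
    err <- function(msg) {
      stop(sprintf("token %d ('%s'): %s", i, tok, msg), call. = FALSE)
    }
    if (grepl("^[0-9]+dtc[0-9]+$", tok)) {
      m <- regmatches(tok, regexec("^([0-9]+)dtc([0-9]+)$", tok))[[1]]
      n <- as.integer(m[2]); k <- as.integer(m[3])
      if (!spatial) err("convolutional layer after a fully connected layer")
      if (n < 1L || k < 1L) err("channel count and kernel must be positive")
      if (k %% 2L == 0L) err("same-padding convolution needs an odd kernel")
      out <- c(cur[1], cur[2], 2L * n)
      layers[[i]] <- list(kind = "dtc", n = n, k = k, spiking = TRUE,
                          in_shape = cur, out_shape = out,
                          vm_shape = c(cur[1], cur[2], n))
      cur <- out
    } else if (grepl("^[0-9]+c[0-9]+$", tok)) {
      m <- regmatches(tok, regexec("^([0-9]+)c([0-9]+)$", tok))[[1]]
      n <- as.integer(m[2]); k <- as.integer(m[3])
      if (!spatial) err("convolutional layer after a fully connected layer")
      if (n < 1L || k < 1L) err("channel count and kernel must be positive")
      if (k %% 2L == 0L) err("same-padding convolution needs an odd kernel")
      out <- c(cur[1], cur[2], n)
      layers[[i]] <- list(kind = "conv", n = n, k = k, spiking = TRUE,
                          in_shape = cur, out_shape = out,
                          vm_shape = out)
      cur <- out
    } else if (grepl("^p[0-9]+$", tok)) {
      s <- as.integer(sub("^p", "", tok))
      if (!spatial) err("pooling after a fully connected layer")
      if (s < 1L) err("pool window must be positive")
      h2 <- cur[1] %/% s; w2 <- cur[2] %/% s
      if (h2 < 1L || w2 < 1L) {
        err(sprintf("pooling a %dx%d map below 1x1", cur[1], cur[2]))
      }
      out <- c(h2, w2, cur[3])
      layers[[i]] <- list(kind = "pool", n = cur[3], k = s, spiking = FALSE,
                          in_shape = cur, out_shape = out, vm_shape = NULL)
      cur <- out
    } else if (grepl("^[0-9]+fc$", tok)) {
      n <- as.integer(sub("fc$", "", tok))
      if (n < 1L) err("unit count must be positive")
      n_in <- prod(cur)
      kind <- if (i == length(tokens)) "fc_out" else "fc"
      layers[[i]] <- list(kind = kind, n = n, k = NA_integer_,
                          spiking = (kind == "fc"),
                          in_shape = cur, out_shape = n,
                          vm_shape = n)
      cur <- n
      spatial <- FALSE
    } else {
      err("unknown token (expected <n>c<k>, <n>dtc<k>, p<s> or <n>fc)")
    }
  }
  if (layers[[length(layers)]]$kind != "fc_out") {
    stop("the last token must be a fully connected output layer (<n>fc)",
         call. = FALSE)
  }
  if (!layers[[1]]$kind %in% c("conv", "dtc")) {
    stop("the first layer must be convolutional (the coding layer)",
         call. = FALSE)
  }
  structure(list(text = text, input_shape = input_shape, layers = layers),
            class = "scnn_arch")
}

#' @export
print.scnn_arch <- function(x, ...) {
  cat(sprintf("<scnn_arch> %s  on input %s\n", x$text,
              paste(x$input_shape, collapse = "x")))
  for (i in seq_along(x$layers)) {
    ly <- x$layers[[i]]
    shp <- paste(ly$out_shape, collapse = "x")
    cat(sprintf("  %2d. %-6s n=%-5d k=%-3s -> %s\n", i, ly$kind, ly$n,
                ifelse(is.na(ly$k), "-", ly$k), shp))
  }
  invisible(x)
}

n_classes <- function(arch) {
  arch$layers[[length(arch$layers)]]$n
}

#' Predict class labels from output membrane potentials
#'
#' The classifier reads out the non-spiking output layer at the final
#' timestep: the class with the largest membrane potential wins. Ties are
#' broken toward the lowest class index.
#'
#' @param output_vms Numeric vector of per-class membrane potentials, or a
#'   `classes x batch` matrix.
#' @return Integer class index (1-based), one per sample.
#' @examples
#' predict_class(c(0.1, 0.9, 0.3))  # 2
#' predict_class(c(0.5, 0.5))       # 1 (tie rule)
#' @export
predict_class <- function(output_vms) {
  if (!is.numeric(output_vms) || length(output_vms) == 0L) {
    stop("`output_vms` must be a non-empty numeric vector or matrix",
         call. = FALSE)
  }
  m <- if (is.matrix(output_vms)) output_vms else matrix(output_vms)
  max.col(t(m), ties.method = "first")
}
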