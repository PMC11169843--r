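#' Operation, weight and membrane counts of one layer
#'
#' Synaptic-operation accounting: a convolutional layer performing a
#' same-padding stride-1 convolution onto an `h' x w'` output grid costs
#' `h' * w' * cin * k * k * cout` operations; a dual-threshold layer only
#' updates `cout/2` membrane maps, so it costs
#' `h' * w' * cin * k * k * cout/2`. Fully connected layers cost
#' `n_in * n_out`. The coding (first) layer consumes real pixel values and
#' needs multiply-accumulate (MAC) operations; every other layer consumes
#' binary spikes and needs accumulate-only (ACC) operations, a convention
#' kept even where pooling makes some inputs fractional. Weights are
#' counted for convolutional kernels only; membranes for every spiking
#' layer plus the output accumulators; pooling costs nothing.
#'
#' @param layer One element of `arch$layers` (shapes already propagated).
#' @param coding Is this the coding (first) layer?
#' @return List with `op_kind` (`"MAC"`, `"ACC"` or `"none"`), `ops`,
#'   `weights` (convolutional parameters) and `vms`.
#' @export
count_layer <- function(layer, coding = FALSE) {
  if (is.null(layer$kind) || is.null(layer$out_shape)) {
    stop("layer shapes have not been propagated; use parse_arch()",
         call. = FALSE)
  }
  kind <- layer$kind
  if (kind == "pool") {
    return(list(op_kind = "none", ops = 0, weights = 0, vms = 0))
  }
  op_kind <- if (coding) "MAC" else "ACC"
  if (kind %in% c("conv", "dtc")) {
    hw <- prod(layer$out_shape[1:2])
    cin <- layer$in_shape[3]
    nvm <- layer$n                      # dtc: cout/2 membrane maps
    ops <- hw * cin * layer$k^2 * nvm
    list(op_kind = op_kind, ops = ops, weights = layer$k^2 * cin * nvm,
         vms = hw * nvm)
  } else {                              # fc / fc_out
    n_in <- prod(layer$in_shape)
    list(op_kind = op_kind, ops = n_in * layer$n, weights = 0,
         vms = layer$n)
  }
}

#' Profile a network's computational cost
#'
#' Aggregates [count_layer()] over the network and multiplies the
#' operation totals by the number of inference timesteps (weights and
#' membranes are storage and do not scale with time).
#'
#' @param arch An [parse_arch()] result.
#' @param timesteps Inference timesteps `T`.
#' @return A `complexity_report`: per-layer data frame plus totals
#'   (`ACC`, `MAC`, `conv_weights`, `vms`, and the convolutional-layer
#'   subtotals `conv_vms` used by halving comparisons).
#' @examples
#' profile_network(parse_arch("16c5-p2-40c5-p2-256fc-10fc", c(28, 28, 1)))
#' @export
profile_network <- function(arch, timesteps = 1L) {
  stopifnot(inherits(arch, "scnn_arch"))
  timesteps <- as.integer(timesteps)
  stopifnot(timesteps >= 1L)
  rows <- lapply(seq_along(arch$layers), function(i) {
    ly <- arch$layers[[i]]
    cnt <- count_layer(ly, coding = (i == 1L))
    data.frame(label = layer_label(ly), kind = ly$kind,
               op_kind = cnt$op_kind, ops = cnt$ops * timesteps,
               weights = cnt$weights, vms = cnt$vms)
  })
  layers <- do.call(rbind, rows)
  conv_rows <- layers$kind %in% c("conv", "dtc")
  totals <- list(
    ACC = sum(layers$ops[layers$op_kind == "ACC"]),
    MAC = sum(layers$ops[layers$op_kind == "MAC"]),
    conv_weights = sum(layers$weights),
    vms = sum(layers$vms),
    conv_vms = sum(layers$vms[conv_rows])
  )
  structure(list(arch = arch$text, input_shape = arch$input_shape,
                 layers = layers, totals = totals,
                 timesteps = timesteps),
            class = "complexity_report")
}

layer_label <- function(ly) {
  switch(ly$kind,
         conv = sprintf("%dc%d", ly$n, ly$k),
         dtc = sprintf("%ddtc%d", ly$n, ly$k),
         pool = sprintf("p%d", ly$k),
         fc = sprintf("%dfc", ly$n),
         fc_out = sprintf("%dfc(out)", ly$n))
}

#' Render a count the way the comparison tables print it
#'
#' `16400` becomes `"16.4K"`, `3640320` becomes `"3.6M"`: the value is
#' scaled by `K = 1e3` or `M = 1e6` and shown to at most three
#' significant digits with trailing zeros trimmed.
#'
#' @param x Nonnegative count(s).
#' @return Character vector.
#' @export
format_count <- function(x) {
  vapply(x, function(v) {
    if (v >= 1e6) {
      paste0(trim_signif(v / 1e6), "M")
    } else if (v >= 1e3) {
      paste0(trim_signif(v / 1e3), "K")
    } else {
      format(v)
    }
  }, character(1))
}

trim_signif <- function(v) {
  # three significant digits, half away from zero (20.65 -> 20.7)
  p <- ceiling(log10(v)) - 3L
  r <- floor(v * 10^(-p) + 0.5 + 1e-9) * 10^p
  s <- format(r, scientific = FALSE)
  if (grepl("\\.", s)) s <- sub("0+$", "", s)
  sub("\\.$", "", s)
}

#' @export
print.complexity_report <- function(x, ...) {
  cat(sprintf("<complexity_report> %s @ %s, T = %d\n", x$arch,
              paste(x$input_shape, collapse = "x"), x$timesteps))
  df <- x$layers
  df$ops <- ifelse(df$op_kind == "none", "-",
                   sprintf("%s(%s)", format_count(df$ops), df$op_kind))
  df$weights <- ifelse(df$kind %in% c("conv", "dtc"),
                       format_count(df$weights), "-")
  df$vms <- ifelse(df$vms > 0, format_count(df$vms), "-")
  print(df[, c("label", "ops", "weights", "vms")], row.names = FALSE)
  with(x$totals, cat(sprintf(
    "totals: %s(ACC) +%s(MAC)  weights %s  Vms %s\n",
    format_count(ACC), format_count(MAC), format_count(conv_weights),
    format_count(vms))))
  invisible(x)
}

#' Report as a plain list for JSON serialisation
#'
#' @param report A `complexity_report`.
#' @return Nested list mirroring the report.
#' @export
report_to_list <- function(report) {
  stopifnot(inherits(report, "complexity_report"))
  list(
    arch = report$arch,
    input_shape = report$input_shape,
    timesteps = report$timesteps,
    layers = lapply(seq_len(nrow(report$layers)), function(i) {
      r <- report$layers[i, ]
      list(label = r$label, kind = r$kind, op_kind = r$op_kind,
           ops = r$ops, weights = r$weights, vms = r$vms)
    }),
    totals = report$totals
  )
}

#' Accuracy-per-operation efficiency ratio
#'
#' `R = accuracy(%) / operations(M)`: how many accuracy percentage points
#' a network buys per million synaptic operations of a full inference
#' (operations already multiplied by the timestep count).
#'
#' @param accuracy_percent Accuracy on the percent scale (e.g. 99.37).
#' @param total_ops_millions Operations in millions (e.g. 2.26).
#' @return The ratio.
#' @examples
#' efficiency_ratio(90, 1)  # 90
#' @export
efficiency_ratio <- function(accuracy_percent, total_ops_millions) {
  if (!is.numeric(total_ops_millions) || any(total_ops_millions <= 0)) {
    stop("operation count must be positive", call. = FALSE)
  }
  accuracy_percent / total_ops_millions
}
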