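#' Neuron configuration
#'
#' Bundles the leak factor and firing threshold(s) of a layer of leaky
#' integrate-and-fire (LIF) neurons. A single threshold describes a plain
#' LIF neuron; an ordered pair `(Vth0, Vth1)` describes a dual-threshold
#' (DT-LIF) neuron, where only threshold 0 triggers the membrane reset.
#' No ordering between `Vth0` and `Vth1` is required: after training either
#' threshold may end up the larger one.
#'
#' @param leak Leakage factor \eqn{\lambda} in `[0, 1]`; the membrane
#'   potential carried over from the previous timestep is multiplied by it.
#' @param thresholds A single positive number (LIF) or a numeric vector of
#'   length 2 `(Vth0, Vth1)` (DT-LIF), in membrane-potential units.
#' @return An object of class `neuron_config`.
#' @examples
#' neuron_config(leak = 0.5, thresholds = 0.5)
#' neuron_config(leak = 0.5, thresholds = c(1.0, 0.6))
#' @export
neuron_config <- function(leak, thresholds) {
  if (!is.numeric(leak) || length(leak) != 1L || is.na(leak) ||
      leak < 0 || leak > 1) {
    stop("`leak` must be a single number in [0, 1]", call. = FALSE)
  }
  if (!is.numeric(thresholds) || !length(thresholds) %in% c(1L, 2L) ||
      anyNA(thresholds) || any(thresholds <= 0)) {
    stop("`thresholds` must be one or two positive numbers", call. = FALSE)
  }
  structure(list(leak = as.numeric(leak),
                 thresholds = as.numeric(thresholds)),
            class = "neuron_config")
}

#' @export
print.neuron_config <- function(x, ...) {
  kind <- if (length(x$thresholds) == 2L) "DT-LIF" else "LIF"
  cat(sprintf("<neuron_config> %s: leak = %g, thresholds = %s\n",
              kind, x$leak, paste(format(x$thresholds), collapse = ", ")))
  invisible(x)
}

new_neuron_state <- function(membrane, spikes, time_index = 1L) {
  structure(list(membrane = membrane, spikes = spikes,
                 time_index = as.integer(time_index)),
            class = "neuron_state")
}

#' @export
print.neuron_state <- function(x, ...) {
  cat(sprintf("<neuron_state> t = %d, %d neuron(s), %d threshold pathway(s)\n",
              x$time_index, length(x$membrane), length(x$spikes)))
  cat("  membrane:", paste(format(utils::head(c(x$membrane), 6)),
                           collapse = " "),
      if (length(x$membrane) > 6) "...\n" else "\n")
  invisible(x)
}

check_congruent <- function(...) {
  args <- list(...)
  d <- lapply(args, function(a) if (is.null(dim(a))) length(a) else dim(a))
  if (!all(vapply(d[-1], identical, logical(1), d[[1]]))) {
    stop("input arrays have mismatched shapes", call. = FALSE)
  }
}

check_binary <- function(x, what = "spike array") {
  if (!is.numeric(x) || anyNA(x) || !all(x == 0 | x == 1)) {
    stop(sprintf("%s must contain only 0 and 1", what), call. = FALSE)
  }
}

#' One LIF membrane update
#'
#' Advances a layer of plain leaky integrate-and-fire neurons by one
#' timestep. The carried membrane potential is first annihilated where the
#' neuron spiked at the previous step (hard reset to 0), then leaked by
#' \eqn{\lambda}, then the synaptic current is integrated, and finally the
#' updated membrane is compared to the threshold:
#' \deqn{v(t) = \lambda\, v(t-1)\,(1 - x(t-1)) + i(t), \qquad
#'       x(t) = [v(t) \ge V_{th}].}
#' The comparison uses `>=`. The membrane is not clamped; negative values
#' are legal.
#'
#' @param v_prev Membrane potentials at `t - 1` (numeric array).
#' @param spike_prev Binary spikes emitted at `t - 1`, congruent with
#'   `v_prev`.
#' @param current Synaptic current at `t`, congruent with `v_prev`.
#' @param cfg A [neuron_config()] holding a single threshold.
#' @param time_index Timestep being produced (defaults to 1).
#' @return A `neuron_state` with fields `membrane`, `spikes` (a list with
#'   one binary array) and `time_index`.
#' @examples
#' cfg <- neuron_config(0.5, 0.5)
#' lif_step(0.4, 0, 0.35, cfg)  # membrane 0.55, spikes
#' @export
lif_step <- function(v_prev, spike_prev, current, cfg, time_index = 1L) {
  stopifnot(inherits(cfg, "neuron_config"))
  if (length(cfg$thresholds) != 1L) {
    stop("lif_step() needs a single-threshold neuron_config", call. = FALSE)
  }
  check_congruent(v_prev, spike_prev, current)
  check_binary(spike_prev, "spike_prev")
  v <- cfg$leak * v_prev * (1 - spike_prev) + current
  s <- (v >= cfg$thresholds[1L]) + 0
  new_neuron_state(v, list(s), time_index)
}

#' One DT-LIF membrane update
#'
#' Advances a layer of dual-threshold LIF neurons by one timestep. One
#' membrane potential is compared against two thresholds, emitting two
#' binary spike maps, but only a pathway-0 spike resets the membrane:
#' \deqn{v(t) = \lambda\, v(t-1)\,(1 - x_0(t-1)) + i(t), \qquad
#'       x_k(t) = [v(t) \ge V_{th,k}],\; k \in \{0, 1\}.}
#' A spike through `Vth1` leaves the membrane untouched, so the pathway-1
#' sequence rides on a membrane evolving as if that threshold did not
#' exist.
#'
#' @inheritParams lif_step
#' @param spike0_prev Binary pathway-0 spikes emitted at `t - 1` (only
#'   these participate in the reset).
#' @param cfg A [neuron_config()] holding the pair `(Vth0, Vth1)`.
#' @return A `neuron_state`; `spikes` is a list of two binary arrays,
#'   pathway 0 first.
#' @examples
#' cfg <- neuron_config(0.5, c(1.0, 0.6))
#' st <- dtlif_step(0.8, 0, 0.3, cfg)      # membrane 0.7, spikes (0, 1)
#' dtlif_step(st$membrane, st$spikes[[1]], 0.4, cfg, 2L)  # no reset occurred
#' @export
dtlif_step <- function(v_prev, spike0_prev, current, cfg, time_index = 1L) {
  stopifnot(inherits(cfg, "neuron_config"))
  if (length(cfg$thresholds) != 2L) {
    stop("dtlif_step() needs a neuron_config with a threshold pair",
         call. = FALSE)
  }
  check_congruent(v_prev, spike0_prev, current)
  check_binary(spike0_prev, "spike0_prev")
  v <- cfg$leak * v_prev * (1 - spike0_prev) + current
  s0 <- (v >= cfg$thresholds[1L]) + 0
  s1 <- (v >= cfg$thresholds[2L]) + 0
  new_neuron_state(v, list(s0, s1), time_index)
}

#' Rectangular surrogate gradient
#'
#' The spike-generation step function has zero derivative almost
#' everywhere, so backpropagation substitutes a rectangular window
#' \deqn{h(u) = [\,|u - 1| < 1/2\,]}
#' for the derivative of the spike with respect to the normalised membrane
#' potential \eqn{u = v / V_{th}}. The window has width 1, is centred on
#' the firing point `u = 1`, and uses a strict inequality, so `u = 0.5` and
#' `u = 1.5` both give 0.
#'
#' @param u Normalised membrane potential(s), finite.
#' @return An array of 0/1 values congruent with `u`.
#' @examples
#' surrogate_gradient(c(-3, 0.6, 1, 1.5))  # 0 1 1 0
#' @export
surrogate_gradient <- function(u) {
  if (!is.numeric(u) || any(!is.finite(u))) {
    stop("`u` must be finite numeric", call. = FALSE)
  }
  (abs(u - 1) < 0.5) + 0
}
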