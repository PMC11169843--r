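#' Specification of a synthetic image classification set
#'
#' A controllable stand-in for small grayscale benchmarks: each class is
#' a fixed geometric pattern (an oriented bar through the image centre,
#' or a Gaussian blob at a class-specific position), perturbed per sample
#' by an intensity draw and additive Gaussian pixel noise, with values
#' clipped to `[0, 1]`. Bar supports are pairwise disjoint by
#' construction (a central disk whose radius grows with the bar thickness
#' and shrinking angular separation is blanked), so at zero noise the
#' class mean images are orthogonal.
#'
#' @param n_classes Number of classes (>= 2).
#' @param samples_per_class Samples generated per class.
#' @param image_size `(h, w)` in pixels (default 16 x 16).
#' @param family `"bars"` or `"blobs"`.
#' @param noise_std Standard deviation of additive pixel noise (default
#'   0.1, a visible but easily separable level).
#' @param seed Integer seed; identical specs generate identical data.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_classes = 2L, samples_per_class = 100L,
                           image_size = c(16L, 16L),
                           family = c("bars", "blobs"), noise_std = 0.1,
                           seed = 1L) {
  family <- match.arg(family)
  stopifnot(n_classes >= 2, samples_per_class >= 1, noise_std >= 0,
            length(image_size) == 2, all(image_size >= 1))
  structure(list(n_classes = as.integer(n_classes),
                 samples_per_class = as.integer(samples_per_class),
                 image_size = as.integer(image_size), family = family,
                 noise_std = noise_std, seed = as.integer(seed)),
            class = "synthetic_spec")
}

class_pattern <- function(spec, k) {
  h <- spec$image_size[1]
  w <- spec$image_size[2]
  ci <- (h + 1) / 2
  cj <- (w + 1) / 2
  ii <- matrix(seq_len(h), h, w) - ci
  jj <- matrix(seq_len(w), h, w, byrow = TRUE) - cj
  if (spec$family == "bars") {
    thickness <- 1.6
    dtheta <- pi / spec$n_classes
    # two half-width t/2 strips crossing at angle dtheta overlap inside a
    # rhombus of circumradius (t/2)/sin(dtheta/2); blank a disk past it
    r0 <- thickness / (2 * sin(dtheta / 2)) + 0.5
    rmax <- min(h, w) / 2 - 0.5
    if (rmax <= r0 + 1) {
      stop(sprintf(
        "image %dx%d too small for %d disjoint oriented bars", h, w,
        spec$n_classes), call. = FALSE)
    }
    theta <- (k - 1) * dtheta
    # distance from the line through the centre at angle theta
    dist_line <- abs(-sin(theta) * ii + cos(theta) * jj)
    r <- sqrt(ii^2 + jj^2)
    (dist_line <= thickness / 2 & r > r0 & r <= rmax) + 0
  } else {
    sigma <- min(h, w) / 8
    rad <- min(h, w) / 4
    ang <- 2 * pi * (k - 1) / spec$n_classes
    bi <- rad * sin(ang)
    bj <- rad * cos(ang)
    if (min(h, w) < 8) {
      stop(sprintf("image %dx%d too small for positioned blobs", h, w),
           call. = FALSE)
    }
    exp(-((ii - bi)^2 + (jj - bj)^2) / (2 * sigma^2))
  }
}

#' Generate a synthetic labelled image set
#'
#' @param spec A [synthetic_spec()].
#' @return List with `images` (`(h, w, 1, n)` array in `[0, 1]`),
#'   `labels` (1-based integers, balanced across classes) and `spec`.
#' @examples
#' d <- generate_synthetic_dataset(synthetic_spec(2, 10))
#' table(d$labels)
#' @export
generate_synthetic_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  h <- spec$image_size[1]
  w <- spec$image_size[2]
  patterns <- lapply(seq_len(spec$n_classes), function(k) {
    class_pattern(spec, k)
  })
  n <- spec$n_classes * spec$samples_per_class
  set.seed(spec$seed)
  images <- array(0, c(h, w, 1L, n))
  labels <- rep(seq_len(spec$n_classes), each = spec$samples_per_class)
  for (s in seq_len(n)) {
    amp <- stats::runif(1, 0.7, 1)
    img <- amp * patterns[[labels[s]]]
    if (spec$noise_std > 0) {
      img <- img + matrix(stats::rnorm(h * w, 0, spec$noise_std), h, w)
    }
    images[, , 1L, s] <- pmin(pmax(img, 0), 1)
  }
  list(images = images, labels = labels, spec = spec)
}
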