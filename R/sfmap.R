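#' Pairwise similarity of spiking feature maps
#'
#' Dual-threshold layers exist because many channels of a spiking
#' convolutional layer fire nearly the same map. This quantifies that:
#' for every channel pair the fraction of positions where the two binary
#' maps agree (Hamming similarity; Jaccard — agreement restricted to
#' positions where at least one map fires — is available, but is
#' undefined for a pair of silent maps, which are common early in
#' training).
#'
#' @param maps Binary array with channels in the last dimension:
#'   `(h, w, channels)` or `(positions, channels)`; a `(h, w, c, batch)`
#'   stack is accepted and pooled over samples.
#' @param method `"hamming"` (default) or `"jaccard"`.
#' @param cutoff Similarity above which a pair is listed as "similar"
#'   (default 0.9).
#' @return A `sfmap_similarity` object: `similarity` (symmetric
#'   `channels x channels` matrix with unit diagonal), `pairs` (data
#'   frame of all pairs, descending similarity, ties by channel index)
#'   and `similar_pairs` (the subset above `cutoff`).
#' @examples
#' m <- array(c(1, 0, 0, 1, 1, 1, 0, 1), c(2, 2, 2))
#' sfmap_similarity(m)$similarity[1, 2]  # 0.75
#' @export
sfmap_similarity <- function(maps, method = c("hamming", "jaccard"),
                             cutoff = 0.9) {
  method <- match.arg(method)
  d <- dim(maps)
  if (is.null(d) || length(d) < 2L) {
    stop("`maps` must be an array with channels in a trailing dimension",
         call. = FALSE)
  }
  check_binary(maps, "spiking feature maps")
  if (length(d) == 4L) {                    # (h, w, c, batch): pool samples
    maps <- aperm(maps, c(1, 2, 4, 3))
    d <- dim(maps)
  }
  nc <- d[length(d)]
  if (nc < 2L) stop("need at least two channels", call. = FALSE)
  m <- matrix(maps, ncol = nc)
  npos <- nrow(m)
  sim <- matrix(1, nc, nc)
  for (a in seq_len(nc - 1L)) {
    for (b in (a + 1L):nc) {
      sim[a, b] <- sim[b, a] <- if (method == "hamming") {
        mean(m[, a] == m[, b])
      } else {
        un <- sum(m[, a] | m[, b])
        if (un == 0) 1 else sum(m[, a] & m[, b]) / un
      }
    }
  }
  pr <- which(upper.tri(sim), arr.ind = TRUE)
  pairs <- data.frame(a = pr[, 1], b = pr[, 2],
                      similarity = sim[pr])
  pairs <- pairs[order(-pairs$similarity, pairs$a, pairs$b), ]
  rownames(pairs) <- NULL
  structure(list(similarity = sim, pairs = pairs,
                 similar_pairs = pairs[pairs$similarity >= cutoff, ],
                 method = method, cutoff = cutoff, positions = npos),
            class = "sfmap_similarity")
}

#' @export
print.sfmap_similarity <- function(x, ...) {
  cat(sprintf("<sfmap_similarity> %d channels, %s over %d positions\n",
              nrow(x$similarity), x$method, x$positions))
  cat(sprintf("  %d pair(s) at or above cutoff %.2f\n",
              nrow(x$similar_pairs), x$cutoff))
  invisible(x)
}

#' Signed difference of two spiking feature maps
#'
#' The elementwise difference `a - b` of two binary maps, taking values
#' in `{-1, 0, 1}`: the small residual that distinguishes two similar
#' maps. The number of nonzero entries equals
#' `(1 - hamming similarity) * positions`.
#'
#' @param map_a,map_b Congruent binary arrays.
#' @return Array of the same shape with values in `{-1, 0, 1}`.
#' @export
delta_sfmap <- function(map_a, map_b) {
  check_congruent(map_a, map_b)
  check_binary(map_a, "map_a")
  check_binary(map_b, "map_b")
  map_a - map_b
}

#' Normalise trained threshold pairs for reporting
#'
#' Scales each layer's `(Vth0, Vth1)` pair by `1/Vth0`, so the
#' reset-carrying threshold reads 1 and the second threshold becomes a
#' ratio, directly comparable across layers. Ratios above 1 are legal:
#' training can push `Vth1` past `Vth0`.
#'
#' @param pairs A numeric pair, a list of pairs, or a `2 x layers`/
#'   `layers x 2` matrix.
#' @return Same structure with each pair scaled to `(1, Vth1/Vth0)`.
#' @examples
#' normalize_thresholds(c(0.5, 0.35))  # 1.0 0.7
#' @export
normalize_thresholds <- function(pairs) {
  scale_one <- function(p) {
    if (length(p) != 2L || anyNA(p)) {
      stop("each threshold pair must hold two values", call. = FALSE)
    }
    if (p[1] <= 0) stop("Vth0 must be positive", call. = FALSE)
    p / p[1]
  }
  if (is.list(pairs)) return(lapply(pairs, scale_one))
  if (is.matrix(pairs)) {
    if (nrow(pairs) == 2L) return(apply(pairs, 2, scale_one))
    if (ncol(pairs) == 2L) return(t(apply(pairs, 1, scale_one)))
    stop("threshold matrix must have a dimension of length 2",
         call. = FALSE)
  }
  scale_one(pairs)
}
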