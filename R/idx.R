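# IDX container format (the standard MNIST on-disk layout): a big-endian
# header of two zero bytes, an element-type byte, a dimension-count byte,
# then one 4-byte big-endian size per dimension, then the elements in
# C (row-major, last index fastest) order.

idx_type_codes <- c(ubyte = 0x08L, byte = 0x09L, short = 0x0BL,
                    int = 0x0CL, float = 0x0DL, double = 0x0EL)

#' Read an IDX-format array
#'
#' Supports the unsigned-byte tensors used for image and label sets; the
#' magic number is validated (`2051` for a 3-dimensional unsigned-byte
#' image tensor, `2049` for a 1-dimensional label vector) and truncated
#' files are rejected with the offending byte offset.
#'
#' @param path File path.
#' @return Integer vector (1-D) or array with the file's dimensions;
#'   indexing matches the logical order (first dimension slowest on
#'   disk), e.g. `x[i, , ]` is image `i` of an image tensor.
#' @export
read_idx <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("no such file: %s", path), call. = FALSE)
  }
  con <- file(path, "rb")
  on.exit(close(con))
  fsize <- file.size(path)
  hdr <- readBin(con, "integer", n = 4L, size = 1L, signed = FALSE)
  if (length(hdr) < 4L) {
    stop("IDX header truncated at offset 0", call. = FALSE)
  }
  if (hdr[1] != 0L || hdr[2] != 0L) {
    stop("bad IDX magic at offset 0 (first two bytes must be zero)",
         call. = FALSE)
  }
  type <- hdr[3]
  ndim <- hdr[4]
  if (type != idx_type_codes[["ubyte"]]) {
    stop(sprintf("unsupported IDX element type 0x%02X at offset 2", type),
         call. = FALSE)
  }
  if (ndim < 1L) stop("IDX dimension count is zero", call. = FALSE)
  need <- 4L + 4L * ndim
  if (fsize < need) {
    stop(sprintf("IDX file truncated at offset %d (incomplete sizes)",
                 fsize), call. = FALSE)
  }
  dims <- readBin(con, "integer", n = ndim, size = 4L, endian = "big")
  if (any(dims < 0L)) stop("negative IDX dimension size", call. = FALSE)
  n <- prod(dims)
  data <- readBin(con, "integer", n = n, size = 1L, signed = FALSE)
  if (length(data) < n) {
    stop(sprintf("IDX file truncated at offset %d (expected %d bytes)",
                 need + length(data), need + n), call. = FALSE)
  }
  if (ndim == 1L) return(data)
  # disk order is row-major: fill reversed dims, then transpose back
  arr <- array(data, rev(dims))
  aperm(arr, rev(seq_len(ndim)))
}

#' Write an array in IDX format
#'
#' @param x Integer or numeric vector/array with values in `0..255`.
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_idx <- function(x, path) {
  vals <- as.integer(round(x))
  if (anyNA(vals) || any(vals < 0L) || any(vals > 255L)) {
    stop("IDX unsigned-byte data must lie in 0..255", call. = FALSE)
  }
  dims <- if (is.null(dim(x))) length(x) else dim(x)
  ndim <- length(dims)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0L, 0L, idx_type_codes[["ubyte"]], ndim)), con)
  writeBin(as.integer(dims), con, size = 4L, endian = "big")
  if (ndim > 1L) {
    x <- array(vals, dims)
    vals <- as.integer(aperm(x, rev(seq_len(ndim))))
  }
  writeBin(as.raw(vals), con)
  invisible(path)
}

#' Write a labelled image set as IDX files
#'
#' Stores `images.idx` (samples x h x w unsigned bytes, pixel values
#' scaled from `[0, 1]` to `0..255`) and `labels.idx` (0-based class
#' bytes) under a prefix, the layout MNIST tooling expects.
#'
#' @param data List with `images` (`(h, w, c, n)`, single channel) and
#'   1-based `labels`.
#' @param prefix Path prefix, e.g. `"dir/train"`.
#' @return Character vector of the two paths written.
#' @export
write_idx_dataset <- function(data, prefix) {
  d <- dim(data$images)
  if (d[3] != 1L) {
    stop("IDX image export supports single-channel images", call. = FALSE)
  }
  imgs <- data$images[, , 1L, , drop = FALSE]
  dim(imgs) <- c(d[1], d[2], d[4])
  imgs <- aperm(imgs, c(3, 1, 2))
  ipath <- paste0(prefix, "-images.idx")
  lpath <- paste0(prefix, "-labels.idx")
  write_idx(round(imgs * 255), ipath)
  write_idx(as.integer(data$labels) - 1L, lpath)
  c(ipath, lpath)
}

#' Read a labelled image set from IDX files
#'
#' @param prefix Path prefix used by [write_idx_dataset()].
#' @return List with `images` (`(h, w, 1, n)` in `[0, 1]`) and 1-based
#'   `labels`.
#' @export
read_idx_dataset <- function(prefix) {
  imgs <- read_idx(paste0(prefix, "-images.idx"))
  labels <- read_idx(paste0(prefix, "-labels.idx")) + 1L
  d <- dim(imgs)
  images <- array(aperm(imgs, c(2, 3, 1)) / 255, c(d[2], d[3], 1L, d[1]))
  list(images = images, labels = labels)
}
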