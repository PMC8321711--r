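#' Grayscale 8-bit image container
#'
#' A `gray_image` is an integer matrix of intensities in `[0, 255]`, rows
#' indexing image height (y) and columns width (x). It is the pixel
#' container used throughout the package.
#'
#' @param x numeric matrix of intensities in `[0, 255]` (fractional values
#'   are rounded half-up).
#' @return A `gray_image` object.
#' @examples
#' img <- gray_image(matrix(0:255, 16, 16))
#' dim(img)
#' @export
gray_image <- function(x) {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop_param("`x` must be a numeric matrix", field = "pixels")
  }
  if (nrow(x) < 1L || ncol(x) < 1L) {
    stop_dim("image must have at least one row and one column")
  }
  if (anyNA(x) || any(x < 0) || any(x > 255)) {
    stop_param("intensities must be finite and within [0, 255]", field = "pixels")
  }
  v <- matrix(as.integer(round_half_up(x)), nrow(x), ncol(x))
  structure(v, class = c("gray_image", "matrix", "array"))
}

is_gray_image <- function(x) inherits(x, "gray_image")

as_pixel_matrix <- function(img) {
  matrix(as.numeric(img), nrow(img), ncol(img))
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf(
    "<gray_image %d x %d, range [%d, %d], mean %.1f>\n",
    nrow(x), ncol(x), min(x), max(x), mean(x)
  ))
  invisible(x)
}

#' Read / write 8-bit grayscale PNG images
#'
#' Thin wrappers over the png package; multichannel inputs are averaged to
#' one channel on read.
#'
#' @param path file path.
#' @param img a [gray_image()].
#' @return `read_gray_png()` a `gray_image`; `write_gray_png()` the path,
#'   invisibly.
#' @export
read_gray_png <- function(path) {
  if (!file.exists(path)) stop_data(paste0("no such image file: ", path))
  a <- png::readPNG(path)
  if (length(dim(a)) == 3L) a <- apply(a[, , seq_len(min(3L, dim(a)[3])), drop = FALSE], c(1, 2), mean)
  gray_image(round_half_up(a * 255))
}

#' @rdname read_gray_png
#' @export
write_gray_png <- function(img, path) {
  stopifnot(is_gray_image(img))
  png::writePNG(as_pixel_matrix(img) / 255, target = path)
  invisible(path)
}

#' Resize a grayscale image to a square side length
#'
#' Bilinear resampling (via EBImage) to `side x side` pixels, used to give
#' every image a common geometry before fixed-length feature extraction.
#'
#' @param img a [gray_image()].
#' @param side target side length in pixels.
#' @return A `gray_image` of dimension `side x side`.
#' @export
resize_image <- function(img, side = 128L) {
  stopifnot(is_gray_image(img))
  side <- as.integer(side)
  if (side < 8L) stop_param("`side` must be at least 8", field = "side")
  if (nrow(img) == side && ncol(img) == side) return(img)
  out <- EBImage::resize(as_pixel_matrix(img), w = side, h = side)
  gray_image(clip255(round_half_up(out)))
}

# 90-degree-step rotations and horizontal flip, used by training-set
# augmentation. k is the number of counter-clockwise quarter turns.
rotate_image <- function(img, k) {
  stopifnot(is_gray_image(img))
  k <- as.integer(k) %% 4L
  m <- unclass(img)
  for (i in seq_len(k)) m <- t(m)[ncol(m):1, , drop = FALSE]
  gray_image(m)
}

flip_image_horizontal <- function(img) {
  stopifnot(is_gray_image(img))
  gray_image(unclass(img)[, ncol(img):1, drop = FALSE])
}

image_digest <- function(img) {
  digest::digest(as.integer(img), algo = "xxhash64")
}
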