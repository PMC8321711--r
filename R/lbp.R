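#' LBP configuration
#'
#' @param radius circle radius in pixels (>= 1).
#' @param n_points number of circularly sampled neighbors (>= 4; 8 and 16
#'   are the usual choices).
#' @param interpolate sample off-grid neighbors by bilinear interpolation
#'   (the standard convention). With `FALSE`, neighbor offsets are rounded
#'   to the nearest pixel; only then is the code an exact function of
#'   intensity order, so invariance under arbitrary monotone remappings is
#'   exact (bilinear sampling guarantees it only for affine remaps, because
#'   interpolation mixes intensity values before the comparison).
#' @return An `lbp_config` list. The histogram uses uniform-pattern binning:
#'   patterns with at most two 0/1 transitions around the circle each get
#'   their own bin and all others share one, giving
#'   `n_points * (n_points - 1) + 3` bins (59 for `n_points = 8`, 243 for
#'   `n_points = 16`).
#' @export
lbp_config <- function(radius = 2L, n_points = 16L, interpolate = TRUE) {
  radius <- as.integer(radius); n_points <- as.integer(n_points)
  if (radius < 1L) stop_param("radius must be >= 1", field = "radius")
  if (n_points < 4L || n_points > 24L) stop_param("n_points must be in [4, 24]", field = "n_points")
  structure(list(radius = radius, n_points = n_points,
                 interpolate = isTRUE(interpolate),
                 histogram_bins = n_points * (n_points - 1L) + 3L),
            class = "lbp_config")
}

# Number of 0/1 transitions around the circular code (including wraparound).
lbp_transitions <- function(codes, p) {
  rot <- bitwOr(bitwShiftR(codes, 1L), bitwShiftL(bitwAnd(codes, 1L), p - 1L))
  x <- bitwXor(codes, rot)
  cnt <- integer(length(codes))
  for (b in seq_len(p) - 1L) cnt <- cnt + bitwAnd(bitwShiftR(x, b), 1L)
  cnt
}

# Map raw codes -> uniform-pattern bin index (1-based). Uniform codes get
# consecutive bins in increasing code order; all non-uniform codes share the
# last bin. Cached per n_points.
lbp_uniform_lut <- local({
  cache <- list()
  function(p) {
    key <- as.character(p)
    if (is.null(cache[[key]])) {
      codes <- 0:(2^p - 1)
      uni <- lbp_transitions(codes, p) <= 2L
      lut <- integer(2^p)
      lut[uni] <- seq_len(sum(uni))
      lut[!uni] <- sum(uni) + 1L
      cache[[key]] <<- lut
    }
    cache[[key]]
  }
})

# Bilinearly sample m at (y + dy, x + dx) for every valid centre position.
# yr/xr are the row/col ranges of the centres.
sample_shifted <- function(m, yr, xr, dy, dx) {
  y0 <- floor(dy); x0 <- floor(dx)
  fy <- dy - y0; fx <- dx - x0
  # at exact integer offsets the +1 neighbor has weight 0; reuse the base
  # index so the lookup stays in bounds
  y1 <- if (fy > 0) y0 + 1 else y0
  x1 <- if (fx > 0) x0 + 1 else x0
  g <- function(ay, ax) m[yr + ay, xr + ax, drop = FALSE]
  (1 - fy) * (1 - fx) * g(y0, x0) +
    (1 - fy) * fx * g(y0, x1) +
    fy * (1 - fx) * g(y1, x0) +
    fy * fx * g(y1, x1)
}

#' Local-binary-pattern histogram feature
#'
#' For every pixel far enough from the border, samples `n_points` neighbors
#' on a circle of the given radius (bilinear interpolation at non-integer
#' positions), sets bit `p` when neighbor `p` is greater than or equal to
#' the centre, and histograms the resulting codes under uniform-pattern
#' binning. The histogram is L1-normalized to sum to 1. Because each bit is
#' a comparison, the feature is invariant under any strictly increasing
#' remapping of intensities.
#'
#' Neighbor `p` sits at angle `2 * pi * p / n_points` with offsets
#' `(radius * sin, radius * cos)` in (row, column); offsets are rounded to
#' 9 decimals so axis-aligned neighbors are sampled exactly.
#'
#' @param img a [gray_image()] with both dims > `2 * radius + 1`.
#' @param config an [lbp_config()].
#' @return A numeric histogram of length `config$histogram_bins` summing
#'   to 1.
#' @export
lbp_features <- function(img, config = lbp_config()) {
  stopifnot(is_gray_image(img), inherits(config, "lbp_config"))
  r <- config$radius; p <- config$n_points
  if (nrow(img) <= 2L * r + 1L || ncol(img) <= 2L * r + 1L) {
    stop_dim("image too small for the requested LBP radius")
  }
  m <- as_pixel_matrix(img)
  yr <- (r + 1L):(nrow(m) - r)
  xr <- (r + 1L):(ncol(m) - r)
  centre <- m[yr, xr, drop = FALSE]
  codes <- matrix(0L, length(yr), length(xr))
  for (pt in seq_len(p) - 1L) {
    a <- 2 * pi * pt / p
    dy <- round(r * sin(a), 9)
    dx <- round(r * cos(a), 9)
    if (!config$interpolate) {
      dy <- round(dy); dx <- round(dx)
    }
    nb <- sample_shifted(m, yr, xr, dy, dx)
    codes <- codes + bitwShiftL(as.integer(nb >= centre - 1e-9), pt)
  }
  lut <- lbp_uniform_lut(p)
  h <- tabulate(lut[codes + 1L], nbins = config$histogram_bins)
  h / sum(h)
}
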