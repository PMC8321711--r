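#' HOG configuration
#'
#' @param cell cell size in pixels, length-2 `(height, width)`.
#' @param block block size in cells, length-2 `(height, width)`; blocks
#'   stride by one cell.
#' @param n_bins number of orientation bins (>= 2).
#' @param signed use signed orientations over `[0, 360)` instead of the
#'   default unsigned `[0, 180)`.
#' @return A `hog_config` list.
#' @export
hog_config <- function(cell = c(8L, 8L), block = c(1L, 1L), n_bins = 9L,
                       signed = FALSE) {
  cell <- as.integer(cell); block <- as.integer(block); n_bins <- as.integer(n_bins)
  if (length(cell) != 2L || any(cell < 1L)) stop_param("cell dims must be >= 1", field = "cell")
  if (length(block) != 2L || any(block < 1L)) stop_param("block dims must be >= 1", field = "block")
  if (n_bins < 2L) stop_param("n_bins must be >= 2", field = "n_bins")
  structure(list(cell = cell, block = block, n_bins = n_bins, signed = isTRUE(signed)),
            class = "hog_config")
}

# Central-difference gradients with edge replication (the replicated border
# makes the boundary gradient zero in the replicated direction).
image_gradients <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  right <- m[, c(2:nc, nc), drop = FALSE]; left <- m[, c(1, 1:(nc - 1)), drop = FALSE]
  down <- m[c(2:nr, nr), , drop = FALSE]; up <- m[c(1, 1:(nr - 1)), , drop = FALSE]
  list(gx = right - left, gy = down - up)
}

#' Histogram-of-oriented-gradients feature
#'
#' Computes central-difference gradients, accumulates gradient magnitude
#' into per-cell orientation histograms (hard assignment of each pixel's
#' orientation to its bin), groups cells into blocks strided by one cell,
#' L2-hys normalizes each block (L2, clip at 0.2, renormalize; all-zero
#' blocks stay zero) and concatenates blocks in row-major order.
#'
#' Output length is
#' `n_blocks_y * n_blocks_x * block_h * block_w * n_bins` where
#' `n_blocks = n_cells - block + 1` and `n_cells = floor(dim / cell)`
#' (trailing pixels that do not fill a cell are ignored). The feature is
#' invariant to a global additive intensity offset since only gradients
#' enter.
#'
#' @param img a [gray_image()], at least one cell in each dimension.
#' @param config a [hog_config()].
#' @return A numeric feature vector.
#' @export
hog_features <- function(img, config = hog_config()) {
  stopifnot(is_gray_image(img), inherits(config, "hog_config"))
  ch <- config$cell[1]; cw <- config$cell[2]
  ncy <- nrow(img) %/% ch; ncx <- ncol(img) %/% cw
  if (ncy < 1L || ncx < 1L) stop_dim("image smaller than one HOG cell")
  m <- as_pixel_matrix(img)[seq_len(ncy * ch), seq_len(ncx * cw), drop = FALSE]
  g <- image_gradients(m)
  mag <- sqrt(g$gx^2 + g$gy^2)
  theta <- atan2(g$gy, g$gx) * 180 / pi
  span <- if (config$signed) 360 else 180
  theta <- theta %% span
  nb <- config$n_bins
  bin <- pmin(floor(theta / (span / nb)), nb - 1)

  row_cell <- (row(m) - 1L) %/% ch
  col_cell <- (col(m) - 1L) %/% cw
  # cell index row-major: cells scanned along a row of the image first
  cell_id <- row_cell * ncx + col_cell
  flat <- cell_id * nb + bin + 1L
  acc <- rowsum(as.vector(mag), group = as.vector(flat))
  hist <- numeric(ncy * ncx * nb)
  hist[as.integer(rownames(acc))] <- acc
  cells <- matrix(hist, nrow = nb)  # nb x (ncy*ncx), cell-major columns

  bh <- config$block[1]; bw <- config$block[2]
  nby <- ncy - bh + 1L; nbx <- ncx - bw + 1L
  if (nby < 1L || nbx < 1L) stop_dim("image has fewer cells than one HOG block")
  out <- numeric(nby * nbx * bh * bw * nb)
  pos <- 0L
  for (by in seq_len(nby)) {
    for (bx in seq_len(nbx)) {
      v <- numeric(0)
      for (iy in seq_len(bh)) {
        for (ix in seq_len(bw)) {
          cid <- (by + iy - 2L) * ncx + (bx + ix - 1L)  # 1-based column index
          v <- c(v, cells[, cid])
        }
      }
      nrm <- sqrt(sum(v^2))
      if (nrm > 1e-12) {
        v <- pmin(v / nrm, 0.2)
        nrm2 <- sqrt(sum(v^2))
        if (nrm2 > 1e-12) v <- v / nrm2
      }
      out[pos + seq_along(v)] <- v
      pos <- pos + length(v)
    }
  }
  out
}
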