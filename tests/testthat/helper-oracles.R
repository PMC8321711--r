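# Independent brute-force oracles used by the transform and feature tests.
# These re-derive each operation from its scalar definition with plain
# loops, deliberately sharing no code with the package implementation.

oracle_round <- function(x) floor(x + 0.5)

# Empirical-CDF histogram equalization, pixel by pixel.
oracle_hist_eq <- function(m) {
  out <- m
  n <- length(m)
  for (i in seq_along(m)) {
    out[i] <- oracle_round(255 * sum(m <= m[i]) / n)
  }
  out
}

# Eq-style log transform evaluated per pixel.
oracle_log <- function(m) {
  l <- log(m + 1)
  oracle_round(255 * (l - min(l)) / (max(l) - min(l)))
}

# Power-law remap evaluated per pixel.
oracle_gamma <- function(m, gamma) {
  oracle_round(255 * (m / max(m))^(1 / gamma))
}

# Direct 3x3 convolution with edge replication, scalar loops.
oracle_conv3 <- function(m, k) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0, nr, nc)
  for (y in seq_len(nr)) {
    for (x in seq_len(nc)) {
      acc <- 0
      for (dy in -1:1) {
        for (dx in -1:1) {
          yy <- min(max(y + dy, 1), nr)
          xx <- min(max(x + dx, 1), nc)
          acc <- acc + k[dy + 2, dx + 2] * m[yy, xx]
        }
      }
      out[y, x] <- acc
    }
  }
  out
}

# Per-pixel LBP codes: circular neighbors at (radius*sin, radius*cos)
# offsets, bilinear interpolation, neighbor >= center (1e-9 slack) sets the
# bit. Returns the matrix of raw codes for the valid interior.
oracle_lbp_codes <- function(m, radius, n_points) {
  nr <- nrow(m); nc <- ncol(m)
  ys <- (radius + 1):(nr - radius)
  xs <- (radius + 1):(nc - radius)
  codes <- matrix(0L, length(ys), length(xs))
  for (iy in seq_along(ys)) {
    for (ix in seq_along(xs)) {
      y <- ys[iy]; x <- xs[ix]
      code <- 0L
      for (p in 0:(n_points - 1)) {
        a <- 2 * pi * p / n_points
        dy <- round(radius * sin(a), 9)
        dx <- round(radius * cos(a), 9)
        yy <- y + dy; xx <- x + dx
        y0 <- floor(yy); x0 <- floor(xx)
        fy <- yy - y0; fx <- xx - x0
        y1 <- if (fy > 0) y0 + 1 else y0
        x1 <- if (fx > 0) x0 + 1 else x0
        v <- m[y0, x0] * (1 - fy) * (1 - fx) + m[y0, x1] * (1 - fy) * fx +
          m[y1, x0] * fy * (1 - fx) + m[y1, x1] * fy * fx
        if (v >= m[y, x] - 1e-9) code <- code + bitwShiftL(1L, p)
      }
      codes[iy, ix] <- code
    }
  }
  codes
}

# Map raw LBP codes to uniform-pattern bins exactly as documented: uniform
# codes (<= 2 circular transitions) take consecutive bins in increasing
# code order, all others share the final bin.
oracle_lbp_hist <- function(codes, n_points) {
  all_codes <- 0:(2^n_points - 1)
  transitions <- vapply(all_codes, function(cd) {
    bits <- as.integer(intToBits(cd))[1:n_points]
    sum(bits != c(bits[-1], bits[1]))
  }, integer(1))
  uniform <- transitions <= 2
  lut <- integer(length(all_codes))
  lut[uniform] <- seq_len(sum(uniform))
  lut[!uniform] <- sum(uniform) + 1L
  h <- tabulate(lut[codes + 1L], nbins = sum(uniform) + 1L)
  h / sum(h)
}

random_test_image <- function(n = 16L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  gray_image(matrix(sample(0:255, n * n, replace = TRUE), n, n))
}

# A tiny fast GAN configuration shared by the training smoke tests.
tiny_gan_config <- function(seed = 1L, epochs = 1L, image_size = 32L) {
  gan_train_config(epochs = epochs, batch_size = 8L, latent_dim = 16L,
                   image_size = image_size, base_channels = 8L,
                   max_train_images = 16L, seed = seed)
}

tiny_dataset <- function(n = 10L, seed = 1L, image_size = 64L, ...) {
  generate_dataset(n, n, train_fraction = 0.6, seed = seed,
                   image_size = image_size, ...)
}
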