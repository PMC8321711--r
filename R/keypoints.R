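#' Keypoint detector configurations
#'
#' `sift_config()` parameterizes the difference-of-Gaussians detector
#' (Gaussian scale pyramid, 3 intermediate scales per octave, 3x3x3 extrema
#' of the DoG stack) with upright 4x4x8 gradient-orientation descriptors
#' (128 values). `surf_config()` parameterizes the box-filter
#' Hessian-determinant detector on an integral image with upright Haar
#' descriptors (4x4 subregions x 4 statistics = 64 values).
#'
#' @param contrast_threshold minimum absolute DoG response at an extremum
#'   (images are scaled to `[0, 1]`).
#' @param det_threshold minimum normalized Hessian determinant at an
#'   extremum.
#' @param filter_sizes box-filter side lengths for the SURF-like scale
#'   stack; must be odd multiples of 3.
#' @param max_keypoints keep at most this many strongest keypoints.
#' @return A config list.
#' @export
sift_config <- function(contrast_threshold = 0.006, max_keypoints = 200L,
                        upsample_first = TRUE) {
  if (contrast_threshold <= 0) stop_param("contrast_threshold must be > 0", field = "contrast_threshold")
  structure(list(contrast_threshold = contrast_threshold,
                 max_keypoints = as.integer(max_keypoints),
                 upsample_first = isTRUE(upsample_first),
                 descriptor_length = 128L),
            class = "sift_config")
}

#' @rdname sift_config
#' @export
surf_config <- function(det_threshold = 5e-5, filter_sizes = c(9L, 15L, 21L, 27L),
                        max_keypoints = 200L) {
  filter_sizes <- as.integer(filter_sizes)
  if (any(filter_sizes %% 6L != 3L)) stop_param("filter_sizes must be odd multiples of 3", field = "filter_sizes")
  if (length(filter_sizes) < 3L) stop_param("need at least 3 filter sizes", field = "filter_sizes")
  if (det_threshold <= 0) stop_param("det_threshold must be > 0", field = "det_threshold")
  structure(list(det_threshold = det_threshold, filter_sizes = filter_sizes,
                 max_keypoints = as.integer(max_keypoints),
                 descriptor_length = 64L),
            class = "surf_config")
}

# ---- shared helpers --------------------------------------------------------

# S[i+1, j+1] = sum(m[1:i, 1:j]); one guard row/column of zeros.
integral_image <- function(m) {
  s <- apply(m, 2L, cumsum)
  s <- t(apply(s, 1L, cumsum))
  cbind(0, rbind(0, s))
}

# Sum of m over rows y+a1 .. y+a2, cols x+b1 .. x+b2 for all (y, x) in
# (yr, xr), via the integral image S (dim (nr+1) x (nc+1)).
box_sum <- function(S, yr, xr, a1, a2, b1, b2) {
  S[yr + a2 + 1L, xr + b2 + 1L, drop = FALSE] -
    S[yr + a1, xr + b2 + 1L, drop = FALSE] -
    S[yr + a2 + 1L, xr + b1, drop = FALSE] +
    S[yr + a1, xr + b1, drop = FALSE]
}

shift_mat <- function(m, dy, dx, fill = -Inf) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  ys <- max(1L, 1L - dy):min(nr, nr - dy)
  xs <- max(1L, 1L - dx):min(nc, nc - dx)
  out[ys, xs] <- m[ys + dy, xs + dx]
  out
}

# 3x3x3 local maxima of a scale stack (list of equally sized matrices).
# Returns a data.frame with y, x, level, value for interior levels.
stack_maxima <- function(maps, threshold) {
  hits <- list()
  for (lev in 2:(length(maps) - 1L)) {
    centre <- maps[[lev]]
    best <- matrix(-Inf, nrow(centre), ncol(centre))
    for (dl in -1:1) {
      m <- maps[[lev + dl]]
      for (dy in -1:1) {
        for (dx in -1:1) {
          if (dl == 0L && dy == 0L && dx == 0L) next
          best <- pmax(best, shift_mat(m, dy, dx))
        }
      }
    }
    ok <- which(centre > best & centre > threshold & is.finite(centre), arr.ind = TRUE)
    if (nrow(ok)) {
      hits[[length(hits) + 1L]] <- data.frame(
        y = ok[, 1L], x = ok[, 2L], level = lev, value = centre[ok]
      )
    }
  }
  if (!length(hits)) {
    return(data.frame(y = integer(), x = integer(), level = integer(), value = numeric()))
  }
  do.call(rbind, hits)
}

bilinear_at <- function(m, y, x) {
  y0 <- floor(y); x0 <- floor(x)
  y0 <- pmin(pmax(y0, 1L), nrow(m) - 1L)
  x0 <- pmin(pmax(x0, 1L), ncol(m) - 1L)
  fy <- y - y0; fx <- x - x0
  m[cbind(y0, x0)] * (1 - fy) * (1 - fx) +
    m[cbind(y0, x0 + 1L)] * (1 - fy) * fx +
    m[cbind(y0 + 1L, x0)] * fy * (1 - fx) +
    m[cbind(y0 + 1L, x0 + 1L)] * fy * fx
}

new_descriptor_set <- function(descriptors, locations, method) {
  structure(list(descriptors = descriptors, locations = locations, method = method),
            class = "keypoint_descriptor_set")
}

#' @export
print.keypoint_descriptor_set <- function(x, ...) {
  cat(sprintf("<%s descriptor set: %d keypoints x %d dims>\n",
              x$method, nrow(x$descriptors), ncol(x$descriptors)))
  invisible(x)
}

# ---- SIFT-like: DoG pyramid ------------------------------------------------

#' Detect keypoints and compute local descriptors
#'
#' `method = "sift_like"`: difference-of-Gaussians extrema over a Gaussian
#' scale pyramid (octaves downsampled by 2, scale step `2^(1/3)`), with an
#' upright 128-dimensional descriptor (16x16 scale-adapted sample grid,
#' gradients binned into a 4x4 spatial grid of 8-bin orientation
#' histograms, Gaussian-weighted, L2-normalized with 0.2 clipping).
#'
#' `method = "surf_like"`: extrema of the box-filter approximation of the
#' Hessian determinant (`Dxx * Dyy - (0.9 * Dxy)^2`, filters normalized by
#' area, computed on an integral image at several filter sizes), with an
#' upright 64-dimensional descriptor (4x4 subregions of Haar-wavelet
#' responses, statistics `sum dx, sum |dx|, sum dy, sum |dy|`,
#' Gaussian-weighted, L2-normalized).
#'
#' Neither descriptor normalizes for dominant orientation (upright
#' variants); ultrasound probes impose an approximately fixed orientation,
#' and the augmentation stage covers the 90-degree rotation group.
#'
#' @param img a [gray_image()], at least 32x32.
#' @param method `"sift_like"` or `"surf_like"`.
#' @param config a [sift_config()] or [surf_config()] matching `method`.
#' @return A `keypoint_descriptor_set`: list with `descriptors` (n x d
#'   matrix, possibly 0-row), `locations` (n x 3 matrix `y, x, scale`) and
#'   `method`.
#' @export
detect_and_describe <- function(img, method = c("sift_like", "surf_like"),
                                config = NULL) {
  method <- match.arg(method)
  stopifnot(is_gray_image(img))
  if (nrow(img) < 32L || ncol(img) < 32L) stop_dim("image must be at least 32x32 for keypoint detection")
  if (method == "sift_like") {
    detect_sift_like(img, config %||% sift_config())
  } else {
    detect_surf_like(img, config %||% surf_config())
  }
}

detect_sift_like <- function(img, config) {
  stopifnot(inherits(config, "sift_config"))
  m <- as_pixel_matrix(img) / 255
  k <- 2^(1 / 3)
  sigma0 <- 1.6
  kp <- list(); desc <- list()
  octave <- 0L
  if (config$upsample_first) {
    # standard "-1 octave": double the image so fine texture blobs survive
    # the base smoothing
    m <- m[rep(seq_len(nrow(m)), each = 2L), rep(seq_len(ncol(m)), each = 2L)]
    octave <- -1L
  }
  while (min(dim(m)) >= 32L) {
    gs <- vector("list", 5L)
    for (i in 1:5) gs[[i]] <- EBImage::gblur(m, sigma = sigma0 * k^(i - 1))
    dog <- lapply(1:4, function(i) gs[[i + 1L]] - gs[[i]])
    for (sgn in c(1, -1)) {
      ex <- stack_maxima(lapply(dog, function(d) sgn * d), config$contrast_threshold)
      if (nrow(ex)) {
        for (r in seq_len(nrow(ex))) {
          lev <- ex$level[r]
          s_oct <- sigma0 * k^(lev - 1)
          d <- sift_descriptor(gs[[lev]], ex$y[r], ex$x[r], s_oct)
          if (!is.null(d)) {
            kp[[length(kp) + 1L]] <- c(
              y = (ex$y[r] - 1) * 2^octave + 1,
              x = (ex$x[r] - 1) * 2^octave + 1,
              scale = s_oct * 2^octave,
              value = ex$value[r]
            )
            desc[[length(desc) + 1L]] <- d
          }
        }
      }
    }
    m <- m[seq(1L, nrow(m), by = 2L), seq(1L, ncol(m), by = 2L), drop = FALSE]
    octave <- octave + 1L
  }
  finish_descriptor_set(kp, desc, config, "sift_like")
}

sift_descriptor <- function(g, y, x, s_oct) {
  spacing <- max(0.8, s_oct)
  off <- (seq_len(16L) - 8.5) * spacing
  ys <- y + off; xs <- x + off
  if (min(ys) < 2 || min(xs) < 2 || max(ys) > nrow(g) - 1 || max(xs) > ncol(g) - 1) {
    return(NULL)
  }
  yy <- matrix(ys, 16L, 16L)
  xx <- matrix(xs, 16L, 16L, byrow = TRUE)
  v <- function(dy, dx) {
    matrix(bilinear_at(g, as.vector(yy) + dy, as.vector(xx) + dx), 16L, 16L)
  }
  gx <- (v(0, 1) - v(0, -1)) / 2
  gy <- (v(1, 0) - v(-1, 0)) / 2
  mag <- sqrt(gx^2 + gy^2)
  theta <- (atan2(gy, gx) * 180 / pi) %% 360
  bin <- pmin(floor(theta / 45), 7)
  w <- exp(-((row(mag) - 8.5)^2 + (col(mag) - 8.5)^2) / (2 * 6^2))
  cell <- (pmin((row(mag) - 1L) %/% 4L, 3L)) * 4L + pmin((col(mag) - 1L) %/% 4L, 3L)
  flat <- cell * 8L + bin + 1L
  acc <- rowsum(as.vector(mag * w), group = as.vector(flat))
  d <- numeric(128L)
  d[as.integer(rownames(acc))] <- acc
  nrm <- sqrt(sum(d^2))
  if (nrm < 1e-12) return(NULL)
  d <- pmin(d / nrm, 0.2)
  d / max(1e-12, sqrt(sum(d^2)))
}

# ---- SURF-like: integral-image Hessian determinant -------------------------

surf_det_map <- function(S, L, nr, nc) {
  l <- L %/% 3L
  m2 <- (l - 1L) %/% 2L
  border <- l + m2 + 1L
  yr <- (border + 1L):(nr - border)
  xr <- (border + 1L):(nc - border)
  # Dyy: three stacked (l rows x 2l-1 cols) bands, weights +1 / -2 / +1
  dyy <- box_sum(S, yr, xr, -m2 - l, -m2 - 1L, -(l - 1L), l - 1L) -
    2 * box_sum(S, yr, xr, -m2, m2, -(l - 1L), l - 1L) +
    box_sum(S, yr, xr, m2 + 1L, m2 + l, -(l - 1L), l - 1L)
  dxx <- box_sum(S, yr, xr, -(l - 1L), l - 1L, -m2 - l, -m2 - 1L) -
    2 * box_sum(S, yr, xr, -(l - 1L), l - 1L, -m2, m2) +
    box_sum(S, yr, xr, -(l - 1L), l - 1L, m2 + 1L, m2 + l)
  # Dxy: four l x l quadrant blocks
  dxy <- box_sum(S, yr, xr, -l, -1L, 1L, l) +
    box_sum(S, yr, xr, 1L, l, -l, -1L) -
    box_sum(S, yr, xr, -l, -1L, -l, -1L) -
    box_sum(S, yr, xr, 1L, l, 1L, l)
  area <- as.numeric(L)^2
  dyy <- dyy / area; dxx <- dxx / area; dxy <- dxy / area
  det <- dxx * dyy - (0.9 * dxy)^2
  full <- matrix(-Inf, nr, nc)
  full[yr, xr] <- det
  full
}

detect_surf_like <- function(img, config) {
  stopifnot(inherits(config, "surf_config"))
  m <- as_pixel_matrix(img) / 255
  nr <- nrow(m); nc <- ncol(m)
  S <- integral_image(m)
  maps <- lapply(config$filter_sizes, function(L) surf_det_map(S, L, nr, nc))
  ex <- stack_maxima(maps, config$det_threshold)
  kp <- list(); desc <- list()
  if (nrow(ex)) {
    for (r in seq_len(nrow(ex))) {
      L <- config$filter_sizes[ex$level[r]]
      s <- 1.2 * L / 9
      d <- surf_descriptor(S, nr, nc, ex$y[r], ex$x[r], s)
      if (!is.null(d)) {
        kp[[length(kp) + 1L]] <- c(y = ex$y[r], x = ex$x[r], scale = s, value = ex$value[r])
        desc[[length(desc) + 1L]] <- d
      }
    }
  }
  finish_descriptor_set(kp, desc, config, "surf_like")
}

# Haar responses via the integral image: filter side 2h, split vertically
# (dx) or horizontally (dy).
haar_xy <- function(S, ys, xs, h, nr, nc) {
  ys <- round(ys); xs <- round(xs)
  dx <- box_sum(S, ys, xs, -h + 1L, h, 1L, h) - box_sum(S, ys, xs, -h + 1L, h, -h + 1L, 0L)
  dy <- box_sum(S, ys, xs, 1L, h, -h + 1L, h) - box_sum(S, ys, xs, -h + 1L, 0L, -h + 1L, h)
  list(dx = dx / (2 * h * h), dy = dy / (2 * h * h))
}

surf_descriptor <- function(S, nr, nc, y, x, s) {
  step <- max(1L, as.integer(round(s)))
  h <- max(1L, as.integer(round(s)))
  off <- (seq_len(20L) - 10.5) * step
  ys <- round(y + off); xs <- round(x + off)
  lo <- h; hi_y <- nr - h; hi_x <- nc - h
  if (min(ys) <= lo || min(xs) <= lo || max(ys) > hi_y || max(xs) > hi_x) return(NULL)
  hr <- haar_xy(S, ys, xs, h, nr, nc)
  w <- exp(-((row(hr$dx) - 10.5)^2 + (col(hr$dx) - 10.5)^2) / (2 * 6.6^2))
  dxw <- hr$dx * w; dyw <- hr$dy * w
  sub <- (pmin((row(dxw) - 1L) %/% 5L, 3L)) * 4L + pmin((col(dxw) - 1L) %/% 5L, 3L) + 1L
  d <- numeric(64L)
  for (sr in 1:16) {
    sel <- sub == sr
    d[(sr - 1L) * 4L + 1:4] <- c(sum(dxw[sel]), sum(abs(dxw[sel])),
                                 sum(dyw[sel]), sum(abs(dyw[sel])))
  }
  nrm <- sqrt(sum(d^2))
  if (nrm < 1e-12) return(NULL)
  d / nrm
}

finish_descriptor_set <- function(kp, desc, config, method) {
  if (!length(kp)) {
    return(new_descriptor_set(
      matrix(numeric(), 0L, config$descriptor_length),
      matrix(numeric(), 0L, 3L, dimnames = list(NULL, c("y", "x", "scale"))),
      method
    ))
  }
  locs <- do.call(rbind, kp)
  D <- do.call(rbind, desc)
  ord <- order(-locs[, "value"])
  if (length(ord) > config$max_keypoints) ord <- ord[seq_len(config$max_keypoints)]
  new_descriptor_set(
    D[ord, , drop = FALSE],
    locs[ord, c("y", "x", "scale"), drop = FALSE],
    method
  )
}
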