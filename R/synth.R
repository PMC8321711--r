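#' Nodule phantom parameters
#'
#' Parameters controlling the morphology of one synthetic thyroid-nodule
#' ultrasound phantom. The class presets encode the classic sonographic
#' cues: benign nodules are round-to-wide (aspect ratio at most 1), sharply
#' marginated and hyperechoic (brighter than the surrounding parenchyma);
#' malignant nodules are taller than wide, blur-margined, hypoechoic and
#' carry punctate microcalcifications.
#'
#' @param class_label `"benign"` or `"malignant"`.
#' @param aspect_ratio nodule height / width (dimensionless, > 0).
#' @param margin_blur_sigma Gaussian blur width of the lesion boundary, in
#'   pixels (>= 0); 0 gives a hard margin.
#' @param echogenicity_offset mean interior intensity minus background, in
#'   8-bit intensity units (may be negative).
#' @param calcification_count number of bright specks inside the nodule.
#' @param interior_texture_sigma spatial smoothing (pixels) of the speckle
#'   field inside the nodule: benign nodules tend to cystic, homogeneous
#'   interiors (coarse, correlated texture), malignant ones to solid
#'   fine-grained speckle. 0 leaves the interior texture identical to the
#'   background.
#' @param image_size side length of the square image in pixels (>= 32).
#' @return A `nodule_params` list.
#' @examples
#' nodule_params("malignant")
#' @export
nodule_params <- function(class_label = c("benign", "malignant"),
                          aspect_ratio = NULL,
                          margin_blur_sigma = NULL,
                          echogenicity_offset = NULL,
                          calcification_count = NULL,
                          interior_texture_sigma = NULL,
                          image_size = 128L) {
  class_label <- match.arg(class_label)
  preset <- if (class_label == "benign") {
    list(aspect_ratio = 0.8, margin_blur_sigma = 0.5, echogenicity_offset = 40,
         calcification_count = 0L, interior_texture_sigma = 1.5)
  } else {
    list(aspect_ratio = 1.5, margin_blur_sigma = 4, echogenicity_offset = -40,
         calcification_count = 6L, interior_texture_sigma = 0)
  }
  p <- list(
    class_label = class_label,
    aspect_ratio = aspect_ratio %||% preset$aspect_ratio,
    margin_blur_sigma = margin_blur_sigma %||% preset$margin_blur_sigma,
    echogenicity_offset = echogenicity_offset %||% preset$echogenicity_offset,
    calcification_count = as.integer(calcification_count %||% preset$calcification_count),
    interior_texture_sigma = interior_texture_sigma %||% preset$interior_texture_sigma,
    image_size = as.integer(image_size)
  )
  validate_nodule_params(p)
  structure(p, class = "nodule_params")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

validate_nodule_params <- function(p) {
  if (!p$class_label %in% c("benign", "malignant")) {
    stop_param("class_label must be 'benign' or 'malignant'", field = "class_label")
  }
  if (!is.numeric(p$aspect_ratio) || p$aspect_ratio <= 0) {
    stop_param("aspect_ratio must be > 0", field = "aspect_ratio")
  }
  if (!is.numeric(p$margin_blur_sigma) || p$margin_blur_sigma < 0) {
    stop_param("margin_blur_sigma must be >= 0", field = "margin_blur_sigma")
  }
  if (!is.numeric(p$echogenicity_offset)) {
    stop_param("echogenicity_offset must be numeric", field = "echogenicity_offset")
  }
  if (is.na(p$calcification_count) || p$calcification_count < 0) {
    stop_param("calcification_count must be >= 0", field = "calcification_count")
  }
  if (!is.numeric(p$interior_texture_sigma) || p$interior_texture_sigma < 0) {
    stop_param("interior_texture_sigma must be >= 0", field = "interior_texture_sigma")
  }
  if (is.na(p$image_size) || p$image_size < 32L) {
    stop_param("image_size must be >= 32", field = "image_size")
  }
  invisible(p)
}

# Smooth pseudo-anatomic background: mid-gray base plus a low-frequency
# random field (heavily blurred white noise, rescaled to a gentle amplitude).
synth_background <- function(size, base = 110, amplitude = 12) {
  field <- matrix(rnorm(size * size), size, size)
  field <- EBImage::gblur(field, sigma = size / 10)
  field <- field / max(1e-12, stats::sd(field))
  base + amplitude * field
}

#' Generate one synthetic nodule ultrasound phantom
#'
#' Draws a speckled ultrasound-like image containing a single elliptical
#' nodule with the requested morphology: an ellipse of the given aspect
#' ratio placed uniformly at random but fully inside the frame (margin at
#' least 10% of the image side), its boundary softened by a Gaussian blur of
#' `margin_blur_sigma` pixels, its interior shifted by
#' `echogenicity_offset`, and `calcification_count` bright specks scattered
#' in the interior. Multiplicative speckle (gamma-distributed with unit
#' mean, the standard fully-developed-speckle model) is applied last, then
#' intensities are clipped to `[0, 255]` and quantized.
#'
#' @param params a [nodule_params()] object.
#' @param seed integer seed; identical `(params, seed)` give byte-identical
#'   images.
#' @return A [gray_image()] with attributes `nodule_mask` (the hard,
#'   pre-blur, pre-noise ellipse mask as a logical matrix) and `params`.
#' @examples
#' img <- generate_nodule_image(nodule_params("benign"), seed = 1)
#' mean(img[attr(img, "nodule_mask")]) > mean(img[!attr(img, "nodule_mask")])
#' @export
generate_nodule_image <- function(params, seed) {
  validate_nodule_params(params)
  n <- params$image_size
  with_seed(seed, {
    base <- synth_background(n)

    # Ellipse geometry: nominal radius ~18% of the side; the aspect ratio is
    # height/width so semi_y/semi_x = aspect_ratio exactly.
    r0 <- 0.18 * n
    semi_y <- r0 * sqrt(params$aspect_ratio)
    semi_x <- r0 / sqrt(params$aspect_ratio)
    margin <- 0.1 * n
    cy <- runif(1, margin + semi_y, n - margin - semi_y)
    cx <- runif(1, margin + semi_x, n - margin - semi_x)

    yy <- matrix(seq_len(n), n, n)
    xx <- matrix(seq_len(n), n, n, byrow = TRUE)
    ell <- ((yy - cy) / semi_y)^2 + ((xx - cx) / semi_x)^2
    mask <- ell <= 1

    soft <- mask * 1.0
    if (params$margin_blur_sigma > 0) {
      soft <- EBImage::gblur(soft, sigma = params$margin_blur_sigma)
      soft <- clip01(soft)
    }

    clean <- base + params$echogenicity_offset * soft

    if (params$calcification_count > 0L) {
      # Rejection-sample speck centres from the inner 80% of the ellipse.
      specks <- matrix(0, n, n)
      placed <- 0L
      while (placed < params$calcification_count) {
        py <- round(runif(1, cy - semi_y, cy + semi_y))
        px <- round(runif(1, cx - semi_x, cx + semi_x))
        if (((py - cy) / (0.8 * semi_y))^2 + ((px - cx) / (0.8 * semi_x))^2 <= 1) {
          specks[py, px] <- specks[py, px] + 1
          placed <- placed + 1L
        }
      }
      k <- outer(c(0.35, 0.8, 0.35), c(0.35, 0.8, 0.35))
      bump <- conv3_replicate(specks, k)
      clean <- clean + 140 * bump
    }

    # Multiplicative speckle: gamma(shape = L, rate = L) has mean 1 and
    # sd 1/sqrt(L); L = 16 gives the grainy texture of B-mode imaging.
    speckle <- matrix(stats::rgamma(n * n, shape = 16, rate = 16), n, n)
    if (params$interior_texture_sigma > 0) {
      # cystic interiors: spatially smoothed (coarse, correlated) speckle
      # inside the nodule, blended by the soft mask; renormalized so the
      # mean stays 1 and only the texture scale changes
      sm <- EBImage::gblur(speckle, sigma = params$interior_texture_sigma)
      sm <- 1 + (sm - mean(sm))
      speckle <- speckle * (1 - soft) + sm * soft
    }
    img <- gray_image(clip255(round_half_up(clean * speckle)))
    attr(img, "nodule_mask") <- mask
    attr(img, "clean") <- clean     # pre-speckle render, for diagnostics
    attr(img, "params") <- params
    img
  })
}

#' Generate a labeled synthetic nodule dataset
#'
#' Produces a tibble of phantoms with class-dependent morphology and a
#' stratified train/test split, fully determined by `seed`.
#'
#' @param n_benign,n_malignant per-class image counts (each >= 2 so both
#'   splits are populated).
#' @param train_fraction fraction assigned to the training split, in (0, 1);
#'   applied per class, rounded to the nearest integer.
#' @param preset_overrides optional named list of parameter overrides;
#'   either flat (applied to both classes) or a list with elements `benign`
#'   and/or `malignant` for class-specific overrides. Names must be
#'   [nodule_params()] arguments.
#' @param seed integer seed.
#' @param image_size image side length in pixels.
#' @return A `us_dataset`: a tibble with columns `path`, `label`, `split`
#'   and a list-column `image` of [gray_image()] objects.
#' @examples
#' ds <- generate_dataset(4, 4, train_fraction = 0.5, seed = 1, image_size = 64)
#' dplyr::count(ds, label, split)
#' @export
generate_dataset <- function(n_benign, n_malignant, train_fraction = 0.6,
                             preset_overrides = NULL, seed = 1L,
                             image_size = 128L) {
  n_benign <- as.integer(n_benign); n_malignant <- as.integer(n_malignant)
  if (n_benign + n_malignant < 2L) {
    stop_config("need at least 2 images in total")
  }
  if (!(train_fraction > 0 && train_fraction < 1)) {
    stop_config("train_fraction must be strictly between 0 and 1")
  }
  counts <- c(benign = n_benign, malignant = n_malignant)
  rows <- list()
  for (lab in names(counts)) {
    n_c <- counts[[lab]]
    n_tr <- as.integer(round_half_up(train_fraction * n_c))
    if (n_c < 2L || n_tr < 1L || n_tr >= n_c) {
      stop_config(sprintf(
        "class '%s': %d images cannot populate both splits at train_fraction %.2f",
        lab, n_c, train_fraction
      ))
    }
    idx_tr <- with_seed(
      derive_seed(seed, paste0("split-", lab)),
      sort(sample.int(n_c, n_tr))
    )
    split <- rep("test", n_c)
    split[idx_tr] <- "train"
    over <- resolve_overrides(preset_overrides, lab)
    imgs <- vector("list", n_c)
    for (i in seq_len(n_c)) {
      p <- do.call(nodule_params, c(list(class_label = lab, image_size = image_size), over))
      imgs[[i]] <- generate_nodule_image(p, derive_seed(seed, sprintf("image-%s-%d", lab, i)))
    }
    rows[[lab]] <- tibble::tibble(
      path = sprintf("%s_%04d.png", lab, seq_len(n_c)),
      label = lab,
      split = split,
      image = imgs
    )
  }
  ds <- dplyr::bind_rows(rows)
  attr(ds, "seed") <- as.integer(seed)
  attr(ds, "image_size") <- as.integer(image_size)
  class(ds) <- c("us_dataset", class(ds))
  ds
}

resolve_overrides <- function(over, lab) {
  if (is.null(over)) return(list())
  if (!is.list(over)) stop_config("preset_overrides must be a list")
  if (any(names(over) %in% c("benign", "malignant"))) {
    over <- over[[lab]] %||% list()
  }
  allowed <- c("aspect_ratio", "margin_blur_sigma", "echogenicity_offset",
               "calcification_count", "interior_texture_sigma")
  bad <- setdiff(names(over), allowed)
  if (length(bad)) stop_config(paste0("unknown preset override: ", paste(bad, collapse = ", ")))
  over
}

#' Write a dataset to disk as PNG files plus a manifest
#'
#' @param dataset a `us_dataset` tibble (see [generate_dataset()]).
#' @param dir output directory, created if missing.
#' @return The manifest path, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "us_dataset") || all(c("path", "label", "split", "image") %in% names(dataset)))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_len(nrow(dataset))) {
    write_gray_png(dataset$image[[i]], file.path(dir, dataset$path[i]))
  }
  manifest <- file.path(dir, "manifest.csv")
  utils::write.csv(
    data.frame(path = dataset$path, label = dataset$label, split = dataset$split),
    manifest, row.names = FALSE, quote = FALSE
  )
  invisible(manifest)
}

# Tiny exact 3x3 convolution with edge replication, shared by the
# calcification stamp and the Laplacian transform (and their test oracles
# reimplement it independently).
conv3_replicate <- function(m, k) {
  stopifnot(all(dim(k) == c(3L, 3L)))
  nr <- nrow(m); nc <- ncol(m)
  p <- rbind(m[1, , drop = FALSE], m, m[nr, , drop = FALSE])
  p <- cbind(p[, 1, drop = FALSE], p, p[, nc, drop = FALSE])
  out <- matrix(0, nr, nc)
  for (dy in -1:1) {
    for (dx in -1:1) {
      out <- out + k[dy + 2, dx + 2] * p[(2 + dy):(nr + 1 + dy), (2 + dx):(nc + 1 + dx), drop = FALSE]
    }
  }
  out
}
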