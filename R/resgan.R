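# Dual-head residual GAN: a class-conditional residual generator and a
# residual discriminator whose pooled multi-scale activations provide a
# 960-dimensional deep feature for downstream fusion.

DISC_CHANNELS <- c(64L, 64L, 128L, 128L, 256L, 512L)
DISC_STRIDES <- c(1L, 1L, 2L, 1L, 2L, 2L)
# Feature taps sit after the LAST residual module of each distinct channel
# width; their pooled outputs concatenate to 64 + 128 + 256 + 512 = 960.
DISC_TAPS <- c(2L, 4L, 5L, 6L)

#' Discriminator architecture specification
#'
#' The fixed architecture: a 7x7 stride-2 convolution with 64 channels plus
#' batch normalization, a 2x2 max-pool, then six 3x3 residual modules with
#' channel widths 64, 64, 128, 128, 256, 512 (stride 2 at each width
#' increase), global average pooling, and two fully connected heads — a
#' 1-unit sigmoid authenticity head and a 2-unit softmax benign/malignant
#' head (label 1 = malignant). Global-average-pool taps after the last
#' module of each distinct width give the spliced deep feature of
#' dimension 960.
#'
#' @param channels residual-module channel widths; must equal the fixed
#'   sequence above.
#' @return A `discriminator_spec` list.
#' @export
discriminator_spec <- function(channels = DISC_CHANNELS) {
  if (!identical(as.integer(channels), DISC_CHANNELS)) {
    stop_config(paste0(
      "discriminator channel sequence is fixed to [",
      paste(DISC_CHANNELS, collapse = ", "), "]"
    ))
  }
  structure(
    list(stem_kernel = 7L, stem_channels = 64L, channels = DISC_CHANNELS,
         strides = DISC_STRIDES, taps = DISC_TAPS,
         feature_length = sum(DISC_CHANNELS[DISC_TAPS])),
    class = "discriminator_spec"
  )
}

#' Build the dual-head residual discriminator
#'
#' @param spec a [discriminator_spec()].
#' @param seed integer seed for weight initialization.
#' @return A `resgan_discriminator` model handle. Run images through it
#'   with [discriminator_forward()] / [extract_deep_features()].
#' @examples
#' d <- build_discriminator(seed = 1)
#' img <- array(runif(64 * 64), c(1, 64, 64, 1))
#' length(discriminator_forward(d, img, training = FALSE)$feature)  # 960
#' @export
build_discriminator <- function(spec = discriminator_spec(), seed = 1L) {
  stopifnot(inherits(spec, "discriminator_spec"))
  with_seed(seed, {
    m <- new.env(parent = emptyenv())
    m$spec <- spec
    m$stem <- nn_conv(1L, spec$stem_channels, spec$stem_kernel, stride = 2L, pad = 3L)
    m$stem_bn <- nn_bn(spec$stem_channels)
    m$stem_relu <- nn_relu()
    m$pool <- nn_maxpool2()
    cin <- spec$stem_channels
    m$blocks <- vector("list", length(spec$channels))
    for (i in seq_along(spec$channels)) {
      m$blocks[[i]] <- nn_resblock(cin, spec$channels[i], stride = spec$strides[i])
      cin <- spec$channels[i]
    }
    m$gaps <- lapply(spec$taps, function(i) nn_gap())
    m$head_auth <- nn_dense(512L, 1L)
    m$head_class <- nn_dense(512L, 2L)
    m$trained <- FALSE
    class(m) <- "resgan_discriminator"
    m
  })
}

disc_params <- function(m) {
  ps <- list(m$stem$W, m$stem$b, m$stem_bn$gamma, m$stem_bn$beta)
  for (b in m$blocks) ps <- c(ps, resblock_params(b))
  c(ps, list(m$head_auth$W, m$head_auth$b, m$head_class$W, m$head_class$b))
}

#' Run the discriminator forward
#'
#' @param m a [build_discriminator()] handle.
#' @param x input batch: array `(1, H, W, N)` (channel-first) of pixels
#'   scaled to `[0, 1]`.
#' @param training use batch statistics and keep backward caches.
#' @return List with `auth` (authenticity probabilities, length N, strictly
#'   inside (0, 1)), `auth_logit`, `class_probs` (2 x N, columns sum to 1;
#'   rows ordered benign, malignant), `class_logits`, and `feature`
#'   (960 x N spliced deep feature).
#' @export
discriminator_forward <- function(m, x, training = TRUE) {
  stopifnot(inherits(m, "resgan_discriminator"))
  h <- conv_forward(m$stem, x, training)
  h <- bn_forward(m$stem_bn, h, training)
  h <- relu_forward(m$stem_relu, h, training)
  h <- maxpool2_forward(m$pool, h, training)
  taps <- list()
  ti <- 1L
  for (i in seq_along(m$blocks)) {
    h <- resblock_forward(m$blocks[[i]], h, training)
    if (ti <= length(m$spec$taps) && i == m$spec$taps[ti]) {
      taps[[ti]] <- gap_forward(m$gaps[[ti]], h, training)
      ti <- ti + 1L
    }
  }
  feat <- do.call(rbind, taps)               # 960 x N
  pooled <- taps[[length(taps)]]             # 512 x N, feeds both heads
  auth_logit <- dense_forward(m$head_auth, pooled, training)
  class_logits <- dense_forward(m$head_class, pooled, training)
  list(
    auth = as.numeric(sigmoid(auth_logit)),
    auth_logit = auth_logit,
    class_probs = softmax_cols(class_logits),
    class_logits = class_logits,
    feature = feat
  )
}

# Backpropagate head-logit gradients through the discriminator; gradients
# accumulate into the parameters. Returns d(loss)/d(input batch).
discriminator_backward <- function(m, d_auth_logit, d_class_logits) {
  d_pooled <- dense_backward(m$head_auth, d_auth_logit) +
    dense_backward(m$head_class, d_class_logits)
  # Only the last tap feeds the heads; the earlier taps are feature-only
  # outputs and carry no loss gradient.
  nt <- length(m$spec$taps)
  dh <- gap_backward(m$gaps[[nt]], d_pooled)
  for (i in rev(seq_along(m$blocks))) {
    dh <- resblock_backward(m$blocks[[i]], dh)
  }
  dh <- maxpool2_backward(m$pool, dh)
  dh <- relu_backward(m$stem_relu, dh)
  dh <- bn_backward(m$stem_bn, dh)
  conv_backward(m$stem, dh, need_dx = TRUE)
}

#' Build the class-conditional residual generator
#'
#' Maps a latent vector concatenated with a one-hot class label through a
#' dense projection to a 4x4 feature map, then through residual upsampling
#' blocks (nearest-neighbor x2 upsample, 3x3 convolution + batch norm on
#' the main path, 1x1 convolution shortcut, ReLU) up to the target
#' resolution, and finally a 3x3 convolution to one channel with a sigmoid,
#' so pixels live in (0, 1).
#'
#' @param latent_dim latent dimension (>= 1).
#' @param image_size output side length; a power of 2 times 4 (32, 64, 128).
#' @param base_channels channel width of the last upsampling stage.
#' @param seed integer seed for weight initialization.
#' @return A `resgan_generator` handle.
#' @export
build_generator <- function(latent_dim = 64L, image_size = 64L,
                            base_channels = 16L, seed = 1L) {
  latent_dim <- as.integer(latent_dim)
  if (latent_dim < 1L) stop_param("latent_dim must be >= 1", field = "latent_dim")
  stages <- as.integer(round(log2(image_size / 4)))
  if (stages < 1L || 4L * 2L^stages != image_size) {
    stop_param("image_size must be 4 * 2^k for integer k >= 1", field = "image_size")
  }
  with_seed(seed, {
    g <- new.env(parent = emptyenv())
    g$latent_dim <- latent_dim; g$image_size <- as.integer(image_size)
    g$stages <- stages
    chans <- base_channels * 2L^(stages:1 - 1L)    # wide -> narrow
    g$c0 <- chans[1L]
    g$fc <- nn_dense(latent_dim + 2L, 4L * 4L * g$c0)
    g$fc_relu <- nn_relu()
    g$ups <- vector("list", stages)
    cin <- g$c0
    for (i in seq_len(stages)) {
      cout <- chans[min(i + 1L, stages)]
      st <- new.env(parent = emptyenv())
      st$up <- nn_upsample2()
      st$conv <- nn_conv(cin, cout, 3L)
      st$bn <- nn_bn(cout)
      st$short <- nn_conv(cin, cout, 1L, pad = 0L)
      st$relu <- nn_relu()
      g$ups[[i]] <- st
      cin <- cout
    }
    g$out_conv <- nn_conv(cin, 1L, 3L)
    class(g) <- "resgan_generator"
    g
  })
}

gen_params <- function(g) {
  ps <- list(g$fc$W, g$fc$b)
  for (st in g$ups) {
    ps <- c(ps, list(st$conv$W, st$conv$b, st$bn$gamma, st$bn$beta,
                     st$short$W, st$short$b))
  }
  c(ps, list(g$out_conv$W, g$out_conv$b))
}

#' Generate images from latent vectors and class labels
#'
#' @param g a [build_generator()] handle.
#' @param z latent matrix `(latent_dim x N)`.
#' @param labels character or integer labels (`"benign"`/`"malignant"` or
#'   1/2 class indices with 2 = malignant).
#' @param training keep backward caches / use batch statistics.
#' @return Array `(1, image_size, image_size, N)` with values in (0, 1).
#' @export
generator_forward <- function(g, z, labels, training = TRUE) {
  stopifnot(inherits(g, "resgan_generator"))
  idx <- label_index(labels)
  n <- ncol(z)
  onehot <- matrix(0, 2L, n)
  onehot[cbind(idx, seq_len(n))] <- 1
  inp <- rbind(z, onehot)
  h <- dense_forward(g$fc, inp, training)
  h <- relu_forward(g$fc_relu, h, training)
  h <- array(h, c(g$c0, 4L, 4L, n))
  for (st in g$ups) {
    u <- upsample2_forward(st$up, h, training)
    main <- bn_forward(st$bn, conv_forward(st$conv, u, training), training)
    short <- conv_forward(st$short, u, training)
    h <- relu_forward(st$relu, main + short, training)
  }
  logits <- conv_forward(g$out_conv, h, training)
  g$last_logits <- if (training) logits else NULL
  sigmoid(logits)
}

generator_backward <- function(g, d_img) {
  # back through the output sigmoid
  s <- sigmoid(g$last_logits)
  dh <- conv_backward(g$out_conv, d_img * s * (1 - s))
  for (st in rev(g$ups)) {
    d <- relu_backward(st$relu, dh)
    du <- conv_backward(st$conv, bn_backward(st$bn, d)) +
      conv_backward(st$short, d)
    dh <- upsample2_backward(st$up, du)
  }
  dflat <- matrix(dh, nrow = 4L * 4L * g$c0)
  dflat <- relu_backward(g$fc_relu, dflat)
  dense_backward(g$fc, dflat, need_dx = FALSE)
  invisible(NULL)
}

label_index <- function(labels) {
  if (is.character(labels) || is.factor(labels)) {
    labels <- as.character(labels)
    bad <- setdiff(unique(labels), c("benign", "malignant"))
    if (length(bad)) stop_data(paste0("unknown label: ", paste(bad, collapse = ", ")))
    ifelse(labels == "malignant", 2L, 1L)
  } else {
    idx <- as.integer(labels)
    if (any(!idx %in% c(1L, 2L))) stop_data("integer labels must be 1 (benign) or 2 (malignant)")
    idx
  }
}

#' Add seeded Gaussian pixel noise
#'
#' Both real and generated images are corrupted with i.i.d. zero-mean
#' Gaussian noise before entering the discriminator; this regularizes the
#' adversarial game. `sigma = 0` is the identity. Output is clipped back to
#' `[0, 1]`.
#'
#' @param img numeric matrix or array with values in `[0, 1]`.
#' @param sigma noise standard deviation, >= 0 (intensity units on the
#'   `[0, 1]` scale).
#' @param seed integer seed.
#' @return An object of the same shape.
#' @export
add_gaussian_noise <- function(img, sigma, seed = 1L) {
  if (!is.numeric(sigma) || length(sigma) != 1L || is.na(sigma) || sigma < 0) {
    stop_param("sigma must be a single number >= 0", field = "sigma")
  }
  if (sigma == 0) return(img)
  with_seed(seed, {
    out <- img + rnorm(length(img), sd = sigma)
    out[] <- clip01(out)
    out
  })
}

#' GAN training configuration
#'
#' @param epochs training epochs (full passes over the training split).
#' @param batch_size images per discriminator batch.
#' @param latent_dim generator input dimension.
#' @param image_size training resolution (square; images are resized).
#' @param lr_g,lr_d Adam learning rates (beta1 = 0.5, beta2 = 0.999, the
#'   usual DCGAN setting).
#' @param noise_sigma Gaussian input-noise standard deviation on
#'   `[0, 1]`-scaled pixels at epoch 1; annealed linearly to 0 over the
#'   remaining epochs.
#' @param adv_loss_weight,class_loss_weight loss-term weights. Setting
#'   `adv_loss_weight = 0` turns off the adversarial game entirely (no
#'   generator): the discriminator trains as a plain classifier through its
#'   class head.
#' @param class_loss_on_fake include generated images (with their
#'   conditioning label) in the discriminator's class loss, the
#'   auxiliary-classifier convention.
#' @param base_channels generator width multiplier.
#' @param max_train_images cap on the number of training images the GAN
#'   fits on (a class-stratified seeded subsample when the training split
#'   is larger); `Inf` uses all. Feature extraction is unaffected.
#' @param seed integer seed fixing initialization, batch order and noise.
#' @return A `gan_train_config` list.
#' @export
gan_train_config <- function(epochs = 2L, batch_size = 16L, latent_dim = 64L,
                             image_size = 64L, lr_g = 2e-4, lr_d = 2e-4,
                             noise_sigma = 0.05, adv_loss_weight = 1,
                             class_loss_weight = 1, class_loss_on_fake = TRUE,
                             base_channels = 16L, max_train_images = Inf,
                             seed = 1L) {
  cfg <- list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
              latent_dim = as.integer(latent_dim), image_size = as.integer(image_size),
              lr_g = lr_g, lr_d = lr_d, noise_sigma = noise_sigma,
              adv_loss_weight = adv_loss_weight, class_loss_weight = class_loss_weight,
              class_loss_on_fake = isTRUE(class_loss_on_fake),
              base_channels = as.integer(base_channels),
              max_train_images = max_train_images, seed = as.integer(seed))
  if (cfg$epochs < 1L || cfg$batch_size < 2L || cfg$latent_dim < 1L) {
    stop_config("epochs >= 1, batch_size >= 2 and latent_dim >= 1 are required")
  }
  if (cfg$noise_sigma < 0 || cfg$adv_loss_weight < 0 || cfg$class_loss_weight < 0) {
    stop_config("noise_sigma and loss weights must be >= 0")
  }
  structure(cfg, class = "gan_train_config")
}

# Stack a list of gray_images into a [0, 1] array (1, H, W, N), resizing to
# `side` where needed.
images_to_batch <- function(images, side) {
  n <- length(images)
  out <- array(0, c(1L, side, side, n))
  for (i in seq_len(n)) {
    im <- resize_image(images[[i]], side)
    out[1L, , , i] <- as_pixel_matrix(im) / 255
  }
  out
}

#' Train the residual GAN
#'
#' Alternating updates: the discriminator minimizes adversarial binary
#' cross-entropy on its authenticity head (real images labeled 1, generated
#' 0, both corrupted with Gaussian noise) plus class cross-entropy on real
#' images (and, under the auxiliary-classifier convention, on generated
#' images with their conditioning labels); the generator minimizes the
#' adversarial term with flipped targets plus the class term for its
#' conditioned label. Adam on both, fully seeded. With
#' `adv_loss_weight = 0` only the discriminator's class head trains (no
#' generator is built).
#'
#' @param dataset a dataset tibble with `label`, `split`, `image`; only the
#'   training split is used, and both classes must be present in it.
#' @param config a [gan_train_config()].
#' @return A `resgan_model`: list with `discriminator`, `generator` (NULL
#'   when adversarial training is off), `config` and `history` (tibble with
#'   per-epoch mean losses; all finite on successful training).
#' @export
train_resgan <- function(dataset, config = gan_train_config()) {
  stopifnot(inherits(config, "gan_train_config"))
  tr <- dataset[dataset$split == "train", ]
  if (!nrow(tr)) stop_data("training split is empty")
  if (length(unique(tr$label)) < 2L && config$class_loss_weight > 0) {
    stop_data("training split must contain both classes")
  }
  if (is.finite(config$max_train_images) && nrow(tr) > config$max_train_images) {
    keep <- with_seed(derive_seed(config$seed, "subsample"), {
      unlist(lapply(split(seq_len(nrow(tr)), tr$label), function(idx) {
        n_keep <- max(1L, round(config$max_train_images * length(idx) / nrow(tr)))
        sample(idx, min(length(idx), n_keep))
      }), use.names = FALSE)
    })
    tr <- tr[sort(keep), ]
  }
  side <- config$image_size
  X <- images_to_batch(tr$image, side)
  y <- label_index(tr$label)
  n <- length(y)
  adversarial <- config$adv_loss_weight > 0

  disc <- build_discriminator(seed = derive_seed(config$seed, "disc-init"))
  gen <- if (adversarial) {
    build_generator(config$latent_dim, side, config$base_channels,
                    seed = derive_seed(config$seed, "gen-init"))
  } else {
    NULL
  }
  opt_d <- adam_state(lr = config$lr_d)
  opt_g <- adam_state(lr = config$lr_g)
  pd <- disc_params(disc)
  pg <- if (adversarial) gen_params(gen) else NULL

  hist <- vector("list", config$epochs)
  with_seed(derive_seed(config$seed, "train"), {
    for (epoch in seq_len(config$epochs)) {
      sigma <- if (config$epochs > 1L) {
        config$noise_sigma * (config$epochs - epoch) / (config$epochs - 1L)
      } else {
        config$noise_sigma
      }
      ord <- sample.int(n)
      starts <- seq(1L, n, by = config$batch_size)
      dl <- gl <- numeric(0)
      for (s in starts) {
        idx <- ord[s:min(s + config$batch_size - 1L, n)]
        if (length(idx) < 2L) next
        xb <- X[, , , idx, drop = FALSE]
        yb <- y[idx]
        nb <- length(idx)
        if (sigma > 0) xb <- xb + array(rnorm(length(xb), sd = sigma), dim(xb))

        # ---- discriminator step ----
        zero_grads(pd)
        loss_d <- 0
        out_r <- discriminator_forward(disc, xb, training = TRUE)
        ce_r <- ce_logits(out_r$class_logits, yb)
        d_auth_r <- matrix(0, 1L, nb)
        if (adversarial) {
          bce_r <- bce_logits(out_r$auth_logit, rep(1, nb))
          loss_d <- loss_d + config$adv_loss_weight * bce_r$loss
          d_auth_r <- config$adv_loss_weight * matrix(bce_r$grad, 1L)
        }
        loss_d <- loss_d + config$class_loss_weight * ce_r$loss
        discriminator_backward(disc, d_auth_r, config$class_loss_weight * ce_r$grad)

        if (adversarial) {
          zf <- matrix(rnorm(config$latent_dim * nb), config$latent_dim)
          yf <- sample(1:2, nb, replace = TRUE)
          # batch statistics, but no generator backward: detached fake batch
          xf <- generator_forward(gen, zf, yf, training = TRUE)
          if (sigma > 0) xf <- xf + array(rnorm(length(xf), sd = sigma), dim(xf))
          out_f <- discriminator_forward(disc, xf, training = TRUE)
          bce_f <- bce_logits(out_f$auth_logit, rep(0, nb))
          loss_d <- loss_d + config$adv_loss_weight * bce_f$loss
          d_auth_f <- config$adv_loss_weight * matrix(bce_f$grad, 1L)
          d_class_f <- matrix(0, 2L, nb)
          if (config$class_loss_on_fake && config$class_loss_weight > 0) {
            ce_f <- ce_logits(out_f$class_logits, yf)
            loss_d <- loss_d + config$class_loss_weight * ce_f$loss
            d_class_f <- config$class_loss_weight * ce_f$grad
          }
          discriminator_backward(disc, d_auth_f, d_class_f)
        }
        if (!is.finite(loss_d)) {
          stop_data(sprintf("discriminator loss diverged (non-finite) at epoch %d", epoch))
        }
        adam_step(opt_d, pd)
        dl <- c(dl, loss_d)

        # ---- generator step ----
        if (adversarial) {
          zero_grads(pd); zero_grads(pg)
          zg <- matrix(rnorm(config$latent_dim * nb), config$latent_dim)
          yg <- sample(1:2, nb, replace = TRUE)
          xg <- generator_forward(gen, zg, yg, training = TRUE)
          xin <- xg
          if (sigma > 0) xin <- xin + array(rnorm(length(xin), sd = sigma), dim(xin))
          out_g <- discriminator_forward(disc, xin, training = TRUE)
          bce_g <- bce_logits(out_g$auth_logit, rep(1, nb))
          ce_g <- ce_logits(out_g$class_logits, yg)
          loss_g <- config$adv_loss_weight * bce_g$loss +
            config$class_loss_weight * ce_g$loss
          if (!is.finite(loss_g)) {
            stop_data(sprintf("generator loss diverged (non-finite) at epoch %d", epoch))
          }
          dxf <- discriminator_backward(
            disc,
            config$adv_loss_weight * matrix(bce_g$grad, 1L),
            config$class_loss_weight * ce_g$grad
          )
          generator_backward(gen, dxf)
          adam_step(opt_g, pg)
          zero_grads(pd)
          gl <- c(gl, loss_g)
        }
      }
      hist[[epoch]] <- tibble::tibble(
        epoch = epoch,
        d_loss = mean(dl),
        g_loss = if (adversarial) mean(gl) else NA_real_,
        noise_sigma = sigma
      )
    }
  })
  disc$trained <- TRUE
  structure(
    list(discriminator = disc, generator = gen, config = config,
         history = dplyr::bind_rows(hist)),
    class = "resgan_model"
  )
}

#' @export
print.resgan_model <- function(x, ...) {
  cat(sprintf(
    "<resgan_model: %d epoch(s) at %dx%d, final d_loss %.3f%s>\n",
    nrow(x$history), x$config$image_size, x$config$image_size,
    x$history$d_loss[nrow(x$history)],
    if (!is.null(x$generator)) sprintf(", g_loss %.3f", x$history$g_loss[nrow(x$history)]) else ""
  ))
  invisible(x)
}

#' Predict class membership and authenticity for images
#'
#' Runs images through the trained discriminator in evaluation mode.
#'
#' @param object a `resgan_model`.
#' @param images list of [gray_image()] objects or a dataset tibble.
#' @param ... unused.
#' @return A tibble with `prob_malignant` (softmax class head), `pred`
#'   (threshold 0.5, ties to benign) and `authenticity` (sigmoid head).
#' @export
predict.resgan_model <- function(object, images, ...) {
  if (is.data.frame(images)) images <- images$image
  side <- object$config$image_size
  probs <- numeric(0); auth <- numeric(0)
  starts <- seq(1L, length(images), by = 32L)
  for (s in starts) {
    idx <- s:min(s + 31L, length(images))
    xb <- images_to_batch(images[idx], side)
    fwd <- discriminator_forward(object$discriminator, xb, training = FALSE)
    probs <- c(probs, fwd$class_probs[2L, ])
    auth <- c(auth, fwd$auth)
  }
  tibble::tibble(
    prob_malignant = probs,
    pred = ifelse(probs > 0.5, "malignant", "benign"),
    authenticity = auth
  )
}

#' Extract the 960-dimensional spliced deep feature
#'
#' Runs images through the (trained or initialized) discriminator in
#' evaluation mode and returns, per image, the concatenation of the
#' globally average-pooled outputs of the last residual module at each
#' distinct channel width (64, 128, 256, 512), in increasing-width order.
#'
#' @param model a `resgan_model` or a `resgan_discriminator`.
#' @param images list of [gray_image()] objects (or a dataset tibble with
#'   an `image` column).
#' @param image_size resolution at which images enter the network; taken
#'   from the training config when `model` is a `resgan_model`.
#' @param batch_size forward batch size.
#' @return A numeric matrix, one row per image, 960 columns.
#' @export
extract_deep_features <- function(model, images, image_size = NULL,
                                  batch_size = 32L) {
  if (inherits(model, "resgan_model")) {
    disc <- model$discriminator
    image_size <- image_size %||% model$config$image_size
  } else if (inherits(model, "resgan_discriminator")) {
    disc <- model
    image_size <- image_size %||% 64L
  } else {
    stop_data("model must be a resgan_model or resgan_discriminator handle")
  }
  if (is.data.frame(images)) images <- images$image
  if (!length(images)) return(matrix(numeric(), 0L, disc$spec$feature_length))
  out <- matrix(NA_real_, length(images), disc$spec$feature_length)
  starts <- seq(1L, length(images), by = batch_size)
  for (s in starts) {
    idx <- s:min(s + batch_size - 1L, length(images))
    xb <- images_to_batch(images[idx], image_size)
    fwd <- discriminator_forward(disc, xb, training = FALSE)
    out[idx, ] <- t(fwd$feature)
  }
  stopifnot(all(is.finite(out)))
  out
}
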