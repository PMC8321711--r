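# Minimal seeded neural-network layer library with manual backpropagation.
#
# Activations are column-major arrays of dim (C, H, W, N) — channel first,
# so a length-C vector recycles per channel without sweeps, and matmul
# outputs reshape into activations without aperm. Convolutions run through
# compiled im2col/col2im plus BLAS matrix multiplies; every layer is an
# environment caching what its backward pass needs. Gradients accumulate
# (+=) so a step may backpropagate several batches before an optimizer
# update; zero_grads() resets them.

new_param <- function(value) {
  p <- new.env(parent = emptyenv())
  p$value <- value
  p$grad <- 0 * value   # same shape AND class (vector stays vector)
  p$m <- p$grad
  p$v <- p$grad
  p
}

zero_grads <- function(params) {
  for (p in params) p$grad[] <- 0
  invisible(NULL)
}

adam_state <- function(lr = 2e-4, beta1 = 0.5, beta2 = 0.999, eps = 1e-8) {
  s <- new.env(parent = emptyenv())
  s$lr <- lr; s$beta1 <- beta1; s$beta2 <- beta2; s$eps <- eps; s$t <- 0L
  s
}

adam_step <- function(state, params) {
  state$t <- state$t + 1L
  b1 <- state$beta1; b2 <- state$beta2
  c1 <- 1 - b1^state$t; c2 <- 1 - b2^state$t
  for (p in params) {
    p$m <- b1 * p$m + (1 - b1) * p$grad
    p$v <- b2 * p$v + (1 - b2) * p$grad^2
    p$value <- p$value - state$lr * (p$m / c1) / (sqrt(p$v / c2) + state$eps)
  }
  invisible(NULL)
}

# ---- conv ------------------------------------------------------------------

nn_conv <- function(c_in, c_out, k, stride = 1L, pad = (k - 1L) %/% 2L,
                    use_bias = TRUE) {
  l <- new.env(parent = emptyenv())
  l$type <- "conv"; l$c_in <- c_in; l$c_out <- c_out
  l$k <- as.integer(k); l$stride <- as.integer(stride); l$pad <- as.integer(pad)
  sd <- sqrt(2 / (k * k * c_in))
  l$W <- new_param(matrix(rnorm(k * k * c_in * c_out, sd = sd), k * k * c_in, c_out))
  l$b <- if (use_bias) new_param(numeric(c_out)) else NULL
  l
}

conv_forward <- function(l, x, training = TRUE) {
  d <- dim(x)  # (C, H, W, N)
  cols <- im2col_cpp(x, d[1], d[2], d[3], d[4], l$k, l$k, l$stride, l$pad)
  oh <- (d[2] + 2L * l$pad - l$k) %/% l$stride + 1L
  ow <- (d[3] + 2L * l$pad - l$k) %/% l$stride + 1L
  out <- crossprod(l$W$value, cols)            # c_out x (oh*ow*N)
  if (!is.null(l$b)) out <- out + l$b$value    # recycles down channels
  l$cache <- if (training) list(cols = cols, in_dim = d) else list(in_dim = d)
  array(out, c(l$c_out, oh, ow, d[4]))
}

conv_backward <- function(l, dy, need_dx = TRUE) {
  cc <- l$cache
  dm <- matrix(dy, nrow = l$c_out)
  l$W$grad <- l$W$grad + tcrossprod(cc$cols, dm)
  if (!is.null(l$b)) l$b$grad <- l$b$grad + rowSums(dm)
  if (!need_dx) return(NULL)
  dcols <- l$W$value %*% dm
  col2im_cpp(dcols, cc$in_dim[1], cc$in_dim[2], cc$in_dim[3], cc$in_dim[4],
             l$k, l$k, l$stride, l$pad)
}

# ---- batch norm (per channel over H, W, N) --------------------------------

nn_bn <- function(c, momentum = 0.1, eps = 1e-5) {
  l <- new.env(parent = emptyenv())
  l$type <- "bn"; l$c <- c; l$momentum <- momentum; l$eps <- eps
  l$gamma <- new_param(rep(1, c))
  l$beta <- new_param(numeric(c))
  l$run_mean <- numeric(c)
  l$run_var <- rep(1, c)
  l
}

bn_forward <- function(l, x, training = TRUE) {
  d <- dim(x)
  xm <- matrix(x, nrow = d[1])       # channels x (H*W*N)
  if (training) {
    mu <- rowMeans(xm)
    ctr <- xm - mu
    va <- rowMeans(ctr^2)
    l$run_mean <- (1 - l$momentum) * l$run_mean + l$momentum * mu
    l$run_var <- (1 - l$momentum) * l$run_var + l$momentum * va
  } else {
    mu <- l$run_mean
    va <- l$run_var
    ctr <- xm - mu
  }
  invstd <- 1 / sqrt(va + l$eps)
  xhat <- ctr * invstd
  out <- xhat * l$gamma$value + l$beta$value
  l$cache <- if (training) list(xhat = xhat, invstd = invstd, d = d) else list(d = d)
  array(out, d)
}

bn_backward <- function(l, dy) {
  cc <- l$cache
  d <- cc$d
  dym <- matrix(dy, nrow = d[1])
  l$gamma$grad <- l$gamma$grad + rowSums(dym * cc$xhat)
  l$beta$grad <- l$beta$grad + rowSums(dym)
  dxhat <- dym * l$gamma$value
  dxm <- (dxhat - rowMeans(dxhat) - cc$xhat * rowMeans(dxhat * cc$xhat)) * cc$invstd
  array(dxm, d)
}

# ---- activations / pooling -------------------------------------------------

nn_relu <- function() {
  l <- new.env(parent = emptyenv()); l$type <- "relu"; l
}

relu_forward <- function(l, x, training = TRUE) {
  if (training) l$cache <- x > 0
  x * (x > 0)
}

relu_backward <- function(l, dy) dy * l$cache

nn_maxpool2 <- function() {
  l <- new.env(parent = emptyenv()); l$type <- "maxpool2"; l
}

maxpool2_forward <- function(l, x, training = TRUE) {
  d <- dim(x)
  ro <- seq(1L, d[2], by = 2L); re <- ro + 1L
  co <- seq(1L, d[3], by = 2L); ce <- co + 1L
  s1 <- x[, ro, co, , drop = FALSE]; s2 <- x[, re, co, , drop = FALSE]
  s3 <- x[, ro, ce, , drop = FALSE]; s4 <- x[, re, ce, , drop = FALSE]
  out <- pmax(s1, s2, s3, s4)
  if (training) {
    t1 <- s1 == out
    t2 <- (s2 == out) & !t1
    t3 <- (s3 == out) & !t1 & !t2
    t4 <- !(t1 | t2 | t3)
    l$cache <- list(t1 = t1, t2 = t2, t3 = t3, t4 = t4, d = d)
  }
  out
}

maxpool2_backward <- function(l, dy) {
  cc <- l$cache; d <- cc$d
  dx <- array(0, d)
  ro <- seq(1L, d[2], by = 2L); re <- ro + 1L
  co <- seq(1L, d[3], by = 2L); ce <- co + 1L
  dx[, ro, co, ] <- dy * cc$t1
  dx[, re, co, ] <- dy * cc$t2
  dx[, ro, ce, ] <- dy * cc$t3
  dx[, re, ce, ] <- dy * cc$t4
  dx
}

nn_gap <- function() {
  l <- new.env(parent = emptyenv()); l$type <- "gap"; l
}

gap_forward <- function(l, x, training = TRUE) {
  d <- dim(x)
  l$cache <- d
  hw <- d[2] * d[3]
  xm <- matrix(x, nrow = d[1])
  out <- matrix(0, d[1], d[4])
  for (n in seq_len(d[4])) {
    out[, n] <- rowMeans(xm[, ((n - 1L) * hw + 1L):(n * hw), drop = FALSE])
  }
  out
}

gap_backward <- function(l, dy) {
  d <- l$cache
  hw <- d[2] * d[3]
  array(dy[, rep(seq_len(d[4]), each = hw), drop = FALSE] / hw, d)
}

nn_upsample2 <- function() {
  l <- new.env(parent = emptyenv()); l$type <- "upsample2"; l
}

upsample2_forward <- function(l, x, training = TRUE) {
  d <- dim(x)
  l$cache <- d
  x[, rep(seq_len(d[2]), each = 2L), rep(seq_len(d[3]), each = 2L), , drop = FALSE]
}

upsample2_backward <- function(l, dy) {
  d <- l$cache
  ro <- seq(1L, 2L * d[2], by = 2L); co <- seq(1L, 2L * d[3], by = 2L)
  dy[, ro, co, , drop = FALSE] + dy[, ro + 1L, co, , drop = FALSE] +
    dy[, ro, co + 1L, , drop = FALSE] + dy[, ro + 1L, co + 1L, , drop = FALSE]
}

# ---- dense -----------------------------------------------------------------

nn_dense <- function(d_in, d_out) {
  l <- new.env(parent = emptyenv())
  l$type <- "dense"; l$d_in <- d_in; l$d_out <- d_out
  sd <- sqrt(2 / d_in)
  l$W <- new_param(matrix(rnorm(d_in * d_out, sd = sd), d_in, d_out))
  l$b <- new_param(numeric(d_out))
  l
}

dense_forward <- function(l, x, training = TRUE) {
  if (training) l$cache <- x
  crossprod(l$W$value, x) + l$b$value
}

dense_backward <- function(l, dy, need_dx = TRUE) {
  l$W$grad <- l$W$grad + tcrossprod(l$cache, dy)
  l$b$grad <- l$b$grad + rowSums(dy)
  if (!need_dx) return(NULL)
  l$W$value %*% dy
}

# ---- residual block (ResNet-v1 basic) -------------------------------------

nn_resblock <- function(c_in, c_out, stride = 1L) {
  l <- new.env(parent = emptyenv())
  l$type <- "resblock"; l$c_in <- c_in; l$c_out <- c_out; l$stride <- stride
  l$conv1 <- nn_conv(c_in, c_out, 3L, stride = stride)
  l$bn1 <- nn_bn(c_out)
  l$relu1 <- nn_relu()
  l$conv2 <- nn_conv(c_out, c_out, 3L)
  l$bn2 <- nn_bn(c_out)
  l$project <- stride != 1L || c_in != c_out
  if (l$project) {
    l$convs <- nn_conv(c_in, c_out, 1L, stride = stride, pad = 0L)
    l$bns <- nn_bn(c_out)
  }
  l$relu_out <- nn_relu()
  l
}

resblock_forward <- function(l, x, training = TRUE) {
  h <- conv_forward(l$conv1, x, training)
  h <- bn_forward(l$bn1, h, training)
  h <- relu_forward(l$relu1, h, training)
  h <- conv_forward(l$conv2, h, training)
  h <- bn_forward(l$bn2, h, training)
  s <- if (l$project) {
    bn_forward(l$bns, conv_forward(l$convs, x, training), training)
  } else {
    x
  }
  relu_forward(l$relu_out, h + s, training)
}

resblock_backward <- function(l, dy) {
  d <- relu_backward(l$relu_out, dy)
  dh <- bn_backward(l$bn2, d)
  dh <- conv_backward(l$conv2, dh)
  dh <- relu_backward(l$relu1, dh)
  dh <- bn_backward(l$bn1, dh)
  dx_main <- conv_backward(l$conv1, dh, need_dx = TRUE)
  dx_short <- if (l$project) {
    conv_backward(l$convs, bn_backward(l$bns, d), need_dx = TRUE)
  } else {
    d
  }
  dx_main + dx_short
}

resblock_params <- function(l) {
  ps <- list(l$conv1$W, l$conv1$b, l$bn1$gamma, l$bn1$beta,
             l$conv2$W, l$conv2$b, l$bn2$gamma, l$bn2$beta)
  if (l$project) ps <- c(ps, list(l$convs$W, l$convs$b, l$bns$gamma, l$bns$beta))
  ps
}

# ---- losses ----------------------------------------------------------------

sigmoid <- function(x) 1 / (1 + exp(-x))

softmax_cols <- function(z) {
  z <- sweep(z, 2L, apply(z, 2L, max))
  e <- exp(z)
  sweep(e, 2L, colSums(e), `/`)
}

# Binary cross-entropy on logits; target is 0/1. Returns mean loss and the
# gradient wrt the logit (already divided by N).
bce_logits <- function(logit, target) {
  p <- sigmoid(logit)
  eps <- 1e-12
  loss <- -mean(target * log(p + eps) + (1 - target) * log(1 - p + eps))
  list(loss = loss, grad = (p - target) / length(logit))
}

# Softmax cross-entropy on logits (classes x N); target is a 1-based class
# index vector.
ce_logits <- function(logits, target_idx) {
  p <- softmax_cols(logits)
  n <- ncol(logits)
  eps <- 1e-12
  picked <- p[cbind(target_idx, seq_len(n))]
  onehot <- matrix(0, nrow(logits), n)
  onehot[cbind(target_idx, seq_len(n))] <- 1
  list(loss = -mean(log(picked + eps)), grad = (p - onehot) / n, probs = p)
}
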