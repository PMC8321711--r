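# Finite-difference verification of the hand-written backpropagation.
# Analytic gradients are checked against central differences along random
# directions of whole parameter tensors: the directional derivative
# averages over many coordinates, so isolated ReLU-kink crossings cannot
# produce false alarms the way single-coordinate probes can.

rel_err <- function(a, b) abs(a - b) / max(1e-8, abs(a) + abs(b))

# Returns TRUE when the directional finite difference agrees with the
# analytic directional derivative: relatively to 1e-3, or absolutely to
# 1e-6 (a conv bias feeding batch norm has an exactly-zero derivative, so
# its relative error is 0/0 noise).
dir_check <- function(p, loss_fn, eps = 1e-5) {
  v <- p$value * 0
  v[] <- rnorm(length(v))
  v <- v / sqrt(sum(v^2))
  old <- p$value
  p$value <- old + eps * v; fp <- loss_fn()
  p$value <- old - eps * v; fm <- loss_fn()
  p$value <- old
  num <- (fp - fm) / (2 * eps)
  ana <- sum(p$grad * v)
  abs(num - ana) < 1e-6 || rel_err(num, ana) < 1e-3
}

test_that("discriminator gradients match finite differences layer by layer", {
  set.seed(42)
  d <- build_discriminator(seed = 3)
  x <- array(runif(1 * 32 * 32 * 3), c(1, 32, 32, 3))
  y <- c(1L, 2L, 1L)
  tgt <- c(1, 0, 1)
  loss_parts <- function() {
    out <- thyrocad:::discriminator_forward(d, x, training = TRUE)
    b <- thyrocad:::bce_logits(out$auth_logit, tgt)
    ce <- thyrocad:::ce_logits(out$class_logits, y)
    list(loss = b$loss + ce$loss, b = b, ce = ce)
  }
  loss_fn <- function() loss_parts()$loss
  ps <- thyrocad:::disc_params(d)
  thyrocad:::zero_grads(ps)
  f0 <- loss_parts()
  dx <- thyrocad:::discriminator_backward(d, matrix(f0$b$grad, 1), f0$ce$grad)
  # probe the stem, several residual blocks, a projection and both heads
  for (pi in c(1, 2, 3, 8, 20, 33, 40, length(ps) - 1, length(ps))) {
    expect_true(dir_check(ps[[pi]], loss_fn))
  }
  # gradient with respect to the input image (the path the generator needs)
  eps <- 1e-5
  v <- array(rnorm(length(x)), dim(x)); v <- v / sqrt(sum(v^2))
  xold <- x
  x <- xold + eps * v; fp <- loss_fn()
  x <- xold - eps * v; fm <- loss_fn()
  x <- xold
  expect_lt(rel_err((fp - fm) / (2 * eps), sum(dx * v)), 1e-3)
})

test_that("generator gradients match finite differences", {
  set.seed(7)
  g <- build_generator(latent_dim = 8, image_size = 32, base_channels = 8, seed = 2)
  z <- matrix(rnorm(8 * 3), 8)
  lab <- c(1L, 2L, 2L)
  tgt <- array(runif(1 * 32 * 32 * 3), c(1, 32, 32, 3))
  loss_fn <- function() {
    img <- generator_forward(g, z, lab, training = TRUE)
    0.5 * mean((img - tgt)^2)
  }
  ps <- thyrocad:::gen_params(g)
  thyrocad:::zero_grads(ps)
  img <- generator_forward(g, z, lab, training = TRUE)
  thyrocad:::generator_backward(g, (img - tgt) / length(img))
  for (pi in c(1, 2, 5, 9, length(ps))) {
    expect_true(dir_check(ps[[pi]], loss_fn))
  }
})

test_that("pooling layers route values and gradients exactly", {
  set.seed(11)
  x <- array(rnorm(2 * 4 * 4 * 2), c(2, 4, 4, 2))
  mp <- thyrocad:::nn_maxpool2()
  out <- thyrocad:::maxpool2_forward(mp, x, training = TRUE)
  expect_identical(dim(out), c(2L, 2L, 2L, 2L))
  for (c_ in 1:2) for (n_ in 1:2) for (i in 1:2) for (j in 1:2) {
    expect_equal(out[c_, i, j, n_],
                 max(x[c_, (2 * i - 1):(2 * i), (2 * j - 1):(2 * j), n_]))
  }
  dy <- array(1, dim(out))
  dx <- thyrocad:::maxpool2_backward(mp, dy)
  expect_equal(sum(dx), sum(dy))  # one winner per window

  gap <- thyrocad:::nn_gap()
  og <- thyrocad:::gap_forward(gap, x, training = TRUE)
  expect_equal(og[1, 2], mean(x[1, , , 2]))
  dg <- thyrocad:::gap_backward(gap, matrix(1, 2, 2))
  expect_true(all(abs(dg - 1 / 16) < 1e-12))

  up <- thyrocad:::nn_upsample2()
  ou <- thyrocad:::upsample2_forward(up, x, training = TRUE)
  expect_identical(dim(ou), c(2L, 8L, 8L, 2L))
  expect_equal(ou[1, 1, 1, 1], x[1, 1, 1, 1])
  expect_equal(ou[1, 2, 2, 1], x[1, 1, 1, 1])
  du <- thyrocad:::upsample2_backward(up, array(1, dim(ou)))
  expect_true(all(du == 4))
})
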