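test_that("discriminator architecture matches the fixed specification", {
  spec <- discriminator_spec()
  expect_identical(spec$channels, c(64L, 64L, 128L, 128L, 256L, 512L))
  expect_identical(spec$feature_length, 960L)
  expect_error(discriminator_spec(channels = c(64, 128, 256, 512)),
               class = "thyrocad_config_error")

  d <- build_discriminator(seed = 1)
  # walk the graph: one stem conv + six residual modules with the stated widths
  expect_equal(d$stem$k, 7L)
  expect_equal(d$stem$c_out, 64L)
  expect_length(d$blocks, 6L)
  widths <- vapply(d$blocks, function(b) b$c_out, integer(1))
  expect_identical(widths, c(64L, 64L, 128L, 128L, 256L, 512L))
  kernels <- vapply(d$blocks, function(b) b$conv1$k, integer(1))
  expect_true(all(kernels == 3L))
  # taps at the last module of each distinct width
  expect_identical(d$spec$taps, c(2L, 4L, 5L, 6L))
  expect_equal(sum(widths[d$spec$taps]), 960L)
})

test_that("the spliced deep feature has 960 dimensions and the heads are proper", {
  d <- build_discriminator(seed = 2)
  for (side in c(32L, 64L)) {
    x <- array(runif(side * side * 3), c(1, side, side, 3))
    out <- discriminator_forward(d, x, training = FALSE)
    expect_equal(nrow(out$feature), 960)
    expect_true(all(is.finite(out$feature)))
    expect_true(all(out$auth > 0 & out$auth < 1))
    expect_equal(colSums(out$class_probs), rep(1, 3), tolerance = 1e-6)
  }
})

test_that("generator output obeys the shape and range contract", {
  g <- build_generator(latent_dim = 16, image_size = 32, base_channels = 8, seed = 3)
  z <- matrix(rnorm(16 * 4), 16)
  img <- generator_forward(g, z, c("benign", "malignant", "benign", "malignant"),
                           training = FALSE)
  expect_identical(dim(img), c(1L, 32L, 32L, 4L))
  expect_true(all(img > 0 & img < 1))
  img2 <- generator_forward(g, z, c("benign", "malignant", "benign", "malignant"),
                            training = FALSE)
  expect_identical(img, img2)
  expect_error(build_generator(latent_dim = 0), class = "thyrocad_parameter_error")
  expect_error(build_generator(image_size = 48), class = "thyrocad_parameter_error")
})

test_that("gaussian input noise is seeded, unbiased and bounded by the identity at sigma 0", {
  x <- array(0.5, c(1, 16, 16, 2))
  expect_identical(add_gaussian_noise(x, 0, seed = 1), x)
  n1 <- add_gaussian_noise(x, 0.1, seed = 4)
  n2 <- add_gaussian_noise(x, 0.1, seed = 4)
  expect_identical(n1, n2)
  expect_false(identical(n1, add_gaussian_noise(x, 0.1, seed = 5)))
  # CLT bound on the sample mean
  expect_lt(abs(mean(n1) - 0.5), 3 * 0.1 / sqrt(length(x)))
  expect_true(all(n1 >= 0 & n1 <= 1))
  expect_error(add_gaussian_noise(x, -0.1), class = "thyrocad_parameter_error")
})

test_that("adversarial training runs, stays finite and is seed-reproducible", {
  ds <- tiny_dataset(n = 8, seed = 31, image_size = 32)
  cfg <- tiny_gan_config(seed = 5, epochs = 2)
  m1 <- train_resgan(ds, cfg)
  expect_true(all(is.finite(m1$history$d_loss)))
  expect_true(all(is.finite(m1$history$g_loss)))
  expect_equal(nrow(m1$history), 2)

  m2 <- train_resgan(ds, cfg)
  expect_identical(m1$history, m2$history)
  f1 <- extract_deep_features(m1, ds$image[1:3])
  f2 <- extract_deep_features(m2, ds$image[1:3])
  expect_identical(f1, f2)

  only_benign <- ds[ds$label == "benign" | ds$split == "test", ]
  expect_error(train_resgan(only_benign, cfg), class = "thyrocad_data_error")
})

test_that("class conditioning reaches the generated images after one step", {
  ds <- tiny_dataset(n = 6, seed = 9, image_size = 32)
  m <- train_resgan(ds, tiny_gan_config(seed = 2, epochs = 1))
  z <- matrix(rnorm(16 * 1), 16)
  a <- generator_forward(m$generator, z, "benign", training = FALSE)
  b <- generator_forward(m$generator, z, "malignant", training = FALSE)
  expect_false(identical(a, b))
})

test_that("deep features are 960-long, deterministic and image-sensitive", {
  ds <- tiny_dataset(n = 6, seed = 13, image_size = 32)
  m <- train_resgan(ds, tiny_gan_config(seed = 7, epochs = 1))
  F1 <- extract_deep_features(m, ds$image[1:4])
  expect_identical(dim(F1), c(4L, 960L))
  expect_identical(F1, extract_deep_features(m, ds$image[1:4]))
  # a benign and a malignant phantom must not collapse to one vector
  i_b <- which(ds$label == "benign")[1]; i_m <- which(ds$label == "malignant")[1]
  F2 <- extract_deep_features(m, ds$image[c(i_b, i_m)])
  expect_gt(max(abs(F2[1, ] - F2[2, ])), 0)
})

test_that("the class head alone learns the synthetic classes", {
  ds <- generate_dataset(40, 40, train_fraction = 0.6, seed = 7, image_size = 128)
  cfg <- gan_train_config(epochs = 12, batch_size = 16, image_size = 32,
                          adv_loss_weight = 0, lr_d = 1e-3, seed = 3)
  m <- train_resgan(ds, cfg)
  expect_null(m$generator)
  te <- ds[ds$split == "test", ]
  pred <- predict(m, te)
  expect_gte(mean(pred$pred == te$label), 0.8)
})

test_that("discriminator training accuracy on real vs generated exceeds chance", {
  ds <- tiny_dataset(n = 10, seed = 17, image_size = 32)
  # a deliberately slow generator: the property under test is that the
  # discriminator learns authenticity, not that the game reaches balance
  cfg <- gan_train_config(epochs = 10, batch_size = 8, latent_dim = 16,
                          image_size = 32, base_channels = 8,
                          lr_d = 1e-3, lr_g = 1e-4, seed = 21)
  m <- train_resgan(ds, cfg)
  te <- ds[ds$split == "test", ]
  Xr <- thyrocad:::images_to_batch(te$image, 32)
  fr <- discriminator_forward(m$discriminator, Xr, training = FALSE)
  set.seed(33)
  z <- matrix(rnorm(16 * nrow(te)), 16)
  Xf <- generator_forward(m$generator, z, te$label, training = FALSE)
  ff <- discriminator_forward(m$discriminator, Xf, training = FALSE)
  acc <- (sum(fr$auth > 0.5) + sum(ff$auth <= 0.5)) / (2 * nrow(te))
  expect_gte(acc, 0.6)
})
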