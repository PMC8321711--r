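test_that("histogram equalization follows the empirical CDF", {
  he <- histogram_equalize(gray_image(matrix(c(0, 0, 255, 255), 2, 2)))
  expect_identical(as.integer(he), c(128L, 128L, 255L, 255L))

  # a perfectly uniform histogram is a fixed point within one gray level
  u <- gray_image(matrix(0:255, 16, 16))
  expect_lte(max(abs(as.integer(histogram_equalize(u)) - 0:255)), 1)
})

test_that("log and gamma transforms match their scalar definitions", {
  lg <- log_transform(gray_image(matrix(c(0, 9, 99), 1, 3)))
  expect_identical(as.integer(lg), c(0L, 128L, 255L))  # 255*log(10)/log(100) = 127.5

  gm <- gamma_correct(gray_image(matrix(c(64, 255), 1, 2)), gamma = 2)
  expect_identical(as.integer(gm), c(128L, 255L))      # 255*sqrt(64/255) = 127.75

  # gamma = 1 is the identity when the maximum intensity is 255
  set.seed(31)
  m31 <- matrix(sample(0:255, 256, replace = TRUE), 16, 16); m31[1, 1] <- 255
  img <- gray_image(m31)
  expect_identical(unclass(gamma_correct(img, 1)), unclass(img))
  const <- gray_image(matrix(37, 4, 4))
  expect_true(all(gamma_correct(const, 2.2) == 255))
  expect_error(log_transform(const), class = "thyrocad_degenerate_error")
  expect_error(gamma_correct(gray_image(matrix(0, 3, 3)), 2), class = "thyrocad_degenerate_error")
})

test_that("each monotone transform matches its brute-force oracle on random images", {
  set.seed(91)
  for (i in 1:100) {
    m <- matrix(sample(0:255, 256, replace = TRUE), 16, 16)
    img <- gray_image(m)
    expect_identical(as.integer(histogram_equalize(img)), as.integer(oracle_hist_eq(m)))
    if (length(unique(as.vector(m))) > 1) {
      expect_identical(as.integer(log_transform(img)), as.integer(oracle_log(m)))
    }
    g <- runif(1, 0.3, 3)
    expect_identical(as.integer(gamma_correct(img, g)), as.integer(oracle_gamma(m, g)))
  }
})

test_that("monotone transforms preserve intensity ordering", {
  set.seed(14)
  for (i in 1:20) {
    img <- random_test_image(12)
    for (out in list(histogram_equalize(img), log_transform(img),
                     gamma_correct(img, runif(1, 0.5, 2)))) {
      o <- order(as.integer(img))
      expect_true(all(diff(as.integer(out)[o]) >= 0))
      expect_true(all(out >= 0 & out <= 255))
    }
  }
})

test_that("Laplacian response matches direct convolution and its sign symmetry", {
  mask_pos <- matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0), 3, 3)
  m <- matrix(0, 7, 7); m[4, 4] <- 255
  img <- gray_image(m)
  resp <- laplacian_response(img, "positive")
  expect_equal(resp[4, 4], -4 * 255)
  expect_equal(resp[3, 4], 255)
  expect_equal(resp, oracle_conv3(m, mask_pos))

  set.seed(8)
  for (i in 1:100) {
    mm <- matrix(sample(0:255, 256, replace = TRUE), 16, 16)
    im <- gray_image(mm)
    rp <- laplacian_response(im, "positive")
    expect_equal(rp, oracle_conv3(mm, mask_pos))
    expect_equal(laplacian_response(im, "negative"), -rp)
  }

  const <- gray_image(matrix(120, 8, 8))
  expect_identical(unclass(laplacian_enhance(const, "positive")), unclass(const))
  expect_identical(unclass(laplacian_enhance(const, "negative")), unclass(const))
  expect_error(laplacian_enhance(gray_image(matrix(1, 2, 2))), class = "thyrocad_dimension_error")
})

test_that("selective enhancement policies touch exactly the targeted records", {
  ds <- tiny_dataset(n = 3, seed = 21, image_size = 32)
  snapshot <- lapply(ds$image, unclass)

  none <- apply_policy(ds, enhancement_config("hist_eq", policy = "none"))
  expect_identical(lapply(none$image, unclass), snapshot)

  mal <- apply_policy(ds, enhancement_config("hist_eq", policy = "malignant_train_only"))
  for (i in seq_len(nrow(ds))) {
    hit <- ds$label[i] == "malignant" && ds$split[i] == "train"
    if (hit) {
      expect_identical(unclass(mal$image[[i]]), unclass(histogram_equalize(ds$image[[i]])))
    } else {
      expect_identical(unclass(mal$image[[i]]), snapshot[[i]])
    }
  }

  all_tr <- apply_policy(ds, enhancement_config("hist_eq", policy = "all_train"))
  for (i in seq_len(nrow(ds))) {
    if (ds$split[i] == "train") {
      expect_identical(unclass(all_tr$image[[i]]), unclass(histogram_equalize(ds$image[[i]])))
    } else {
      expect_identical(unclass(all_tr$image[[i]]), snapshot[[i]])
    }
  }

  # labels and splits are never altered by any policy
  expect_identical(mal[c("path", "label", "split")], ds[c("path", "label", "split")])
  expect_identical(all_tr[c("path", "label", "split")], ds[c("path", "label", "split")])
})
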