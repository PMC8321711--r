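test_that("phantom generation is byte-deterministic in (params, seed)", {
  p <- nodule_params("malignant", image_size = 64)
  a <- generate_nodule_image(p, seed = 7)
  b <- generate_nodule_image(p, seed = 7)
  expect_identical(unclass(a), unclass(b))
  expect_false(identical(unclass(a), unclass(generate_nodule_image(p, seed = 8))))
  expect_true(all(a >= 0 & a <= 255))
})

test_that("zero-effect parameters leave the nodule invisible up to background variation", {
  p <- nodule_params("benign", margin_blur_sigma = 0, echogenicity_offset = 0,
                     calcification_count = 0, interior_texture_sigma = 0,
                     image_size = 96)
  for (s in 1:5) {
    img <- generate_nodule_image(p, seed = s)
    mask <- attr(img, "nodule_mask")
    clean <- attr(img, "clean")
    # the nodule must add nothing beyond the smooth background field:
    # the observed interior/exterior contrast equals the background's own
    # contrast up to the speckle standard error
    obs <- mean(img[mask]) - mean(img[!mask])
    bg <- mean(clean[mask]) - mean(clean[!mask])
    se <- sd(as.numeric(img) - as.numeric(clean)) / sqrt(sum(mask))
    expect_lt(abs(obs - bg), 5 * se + 1)
  }
})

test_that("nodule mask honors the requested aspect ratio", {
  for (ar in c(0.8, 1.4, 2.0)) {
    p <- nodule_params("malignant", aspect_ratio = ar, image_size = 128)
    img <- generate_nodule_image(p, seed = 11)
    bb <- which(attr(img, "nodule_mask"), arr.ind = TRUE)
    measured <- (diff(range(bb[, 1])) + 1) / (diff(range(bb[, 2])) + 1)
    expect_lt(abs(measured - ar) / ar, 0.15)
  }
})

test_that("invalid phantom parameters name the offending field", {
  expect_error(nodule_params("benign", aspect_ratio = -1), class = "thyrocad_parameter_error")
  err <- tryCatch(nodule_params("benign", aspect_ratio = 0), error = identity)
  expect_identical(err$field, "aspect_ratio")
  expect_error(nodule_params("benign", image_size = 16), class = "thyrocad_parameter_error")
  expect_error(nodule_params("benign", calcification_count = -2), class = "thyrocad_parameter_error")
})

test_that("dataset generation splits exactly and deterministically", {
  ds <- generate_dataset(10, 10, train_fraction = 0.6, seed = 5, image_size = 64)
  tab <- table(ds$label, ds$split)
  expect_equal(unname(tab["benign", "train"]), 6)
  expect_equal(unname(tab["malignant", "train"]), 6)
  expect_equal(unname(tab["benign", "test"]), 4)
  expect_equal(unname(tab["malignant", "test"]), 4)

  ds2 <- generate_dataset(10, 10, train_fraction = 0.6, seed = 5, image_size = 64)
  expect_identical(lapply(ds$image, unclass), lapply(ds2$image, unclass))

  ds3 <- generate_dataset(10, 10, train_fraction = 0.6, seed = 6, image_size = 64)
  expect_identical(ds3$path, ds$path)
  expect_identical(ds3$label, ds$label)
  expect_false(identical(matrix(as.integer(ds$image[[1]]), 64),
                         matrix(as.integer(ds3$image[[1]]), 64)))

  expect_error(generate_dataset(1, 10, seed = 1), class = "thyrocad_config_error")
  expect_error(generate_dataset(10, 10, train_fraction = 1.2), class = "thyrocad_config_error")
})

test_that("class presets encode hyper- vs hypoechogenicity", {
  ds <- tiny_dataset(n = 12, seed = 2)
  interior_mean <- function(img) mean(img[attr(img, "nodule_mask")])
  mb <- vapply(ds$image[ds$label == "benign"], interior_mean, numeric(1))
  mm <- vapply(ds$image[ds$label == "malignant"], interior_mean, numeric(1))
  expect_gt(mean(mb), mean(mm))
  # every benign interior is brighter than every malignant interior at the
  # default +/-40 offset
  expect_gt(min(mb), max(mm))
})

test_that("equal presets make the classes statistically indistinguishable", {
  over <- list(malignant = list(aspect_ratio = 0.8, margin_blur_sigma = 0.5,
                                echogenicity_offset = 40, calcification_count = 0,
                                interior_texture_sigma = 1.5))
  ds <- generate_dataset(50, 50, train_fraction = 0.5, preset_overrides = over,
                         seed = 13, image_size = 64)
  stat <- vapply(ds$image, function(im) mean(im), numeric(1))
  p <- t.test(stat[ds$label == "benign"], stat[ds$label == "malignant"])$p.value
  expect_gt(p, 0.01)
})

test_that("datasets round-trip to disk as PNG plus manifest", {
  dir <- withr::local_tempdir()
  ds <- tiny_dataset(n = 3, seed = 4, image_size = 32)
  write_dataset(ds, dir)
  mf <- load_manifest(file.path(dir, "manifest.csv"), check_paths = TRUE)
  expect_identical(mf$path, ds$path)
  back <- read_dataset(file.path(dir, "manifest.csv"))
  expect_identical(matrix(as.integer(back$image[[1]]), 32),
                   matrix(as.integer(ds$image[[1]]), 32))
})
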