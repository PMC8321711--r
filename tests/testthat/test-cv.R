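test_that("augmentation multiplies the training split and preserves labels", {
  ds <- tiny_dataset(n = 8, seed = 3, image_size = 32)  # 10 train / 6 test
  n_tr <- sum(ds$split == "train")
  aug <- augment_training(ds)
  expect_equal(sum(aug$split == "train"), 8 * n_tr)
  expect_equal(sum(aug$split == "test"), sum(ds$split == "test"))
  expect_equal(unname(table(aug$label[aug$split == "train"])),
               unname(8 * table(ds$label[ds$split == "train"])))
  expect_false(any(duplicated(aug$path)))

  expect_identical(augment_training(ds, rotations = c(), horizontal_flip = FALSE), ds)
  expect_error(augment_training(ds, split = "test"), class = "thyrocad_config_error")
  expect_error(augment_training(ds, rotations = 45), class = "thyrocad_config_error")
})

test_that("right-angle rotations compose as the dihedral group requires", {
  px <- function(im) matrix(as.integer(im), nrow(im))
  img <- tiny_dataset(n = 2, seed = 5, image_size = 32)$image[[1]]
  r180 <- thyrocad:::rotate_image(img, 2)
  expect_identical(px(thyrocad:::rotate_image(r180, 2)), px(img))
  expect_identical(px(thyrocad:::flip_image_horizontal(thyrocad:::flip_image_horizontal(img))),
                   px(img))
  r90 <- thyrocad:::rotate_image(img, 1)
  expect_identical(px(thyrocad:::rotate_image(r90, 3)), px(img))
})

test_that("stratified folds partition each class almost evenly", {
  labels <- rep(c("benign", "malignant"), c(23, 27))
  folds <- thyrocad:::assign_folds(labels, 5, seed = 2)
  expect_length(folds, 50)
  expect_true(all(folds %in% 1:5))
  for (lab in c("benign", "malignant")) {
    sizes <- table(folds[labels == lab])
    expect_lte(diff(range(sizes)), 1)
  }
  expect_error(thyrocad:::assign_folds(rep(c("benign", "malignant"), c(3, 30)), 5, 1),
               class = "thyrocad_config_error")
})

test_that("cross-validation partitions the data and pools counts additively", {
  ds <- generate_dataset(25, 25, train_fraction = 0.5, seed = 6, image_size = 64)
  rep_ <- cross_validate(
    ds,
    fusion_config("lbp", use_deep = FALSE, cv_folds = 5, seed = 4),
    features = feature_extraction_config(side = 64)
  )
  td <- tidy(rep_)
  expect_equal(nrow(td), 5)
  expect_equal(sum(td$TP + td$TN + td$FP + td$FN), 50)
  # every fold holds out 10 samples, 5 per class
  expect_true(all(td$TP + td$TN + td$FP + td$FN == 10))
  g <- glance(rep_)
  expect_equal(g$TP, sum(td$TP)); expect_equal(g$TN, sum(td$TN))
  expect_equal(g$accuracy, (g$TP + g$TN) / 50)
  # pooled metrics equal metrics recomputed from summed per-fold counts
  summed <- structure(list(TP = sum(td$TP), TN = sum(td$TN),
                           FP = sum(td$FP), FN = sum(td$FN)),
                      class = "confusion_counts")
  expect_equal(g[, c("accuracy", "specificity", "sensitivity")],
               compute_metrics(summed)[, c("accuracy", "specificity", "sensitivity")])
  # texture separates the default presets even at this reduced size
  expect_gt(g$accuracy, 0.7)
})

test_that("arms evaluated together share folds and reproduce exactly", {
  ds <- generate_dataset(12, 12, train_fraction = 0.5, seed = 8, image_size = 64)
  arms <- list(a = fusion_config("lbp", use_deep = FALSE),
               b = fusion_config("hog", use_deep = FALSE))
  r1 <- cross_validate_arms(ds, arms, features = feature_extraction_config(side = 64),
                            cv_folds = 2, seed = 3)
  r2 <- cross_validate_arms(ds, arms, features = feature_extraction_config(side = 64),
                            cv_folds = 2, seed = 3)
  expect_identical(tidy(r1$a), tidy(r2$a))
  expect_identical(tidy(r1$b), tidy(r2$b))
  # single-arm wrapper agrees with the engine
  single <- cross_validate(ds, fusion_config("lbp", use_deep = FALSE,
                                             cv_folds = 2, seed = 3),
                           features = feature_extraction_config(side = 64))
  expect_identical(tidy(single), tidy(r1$a))
})

test_that("report accessors expose tidy/glance/autoplot surfaces", {
  ds <- generate_dataset(8, 8, train_fraction = 0.5, seed = 10, image_size = 64)
  rep_ <- cross_validate(ds, fusion_config("lbp", use_deep = FALSE,
                                           cv_folds = 2, seed = 1),
                         features = feature_extraction_config(side = 64))
  expect_s3_class(tidy(rep_), "tbl_df")
  expect_s3_class(glance(rep_), "tbl_df")
  p <- ggplot2::autoplot(rep_)
  expect_s3_class(p, "ggplot")
})
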