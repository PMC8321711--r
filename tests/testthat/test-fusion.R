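test_that("fusion concatenates standardized blocks in fixed order", {
  set.seed(1)
  conv <- matrix(rnorm(20 * 5, mean = 100, sd = 10), 20, 5)
  deep <- matrix(rnorm(20 * 7, mean = -3, sd = 0.01), 20, 7)
  tr <- rep(c(TRUE, FALSE), 10)
  fused <- fuse_features(conv, deep, train_mask = tr)
  expect_identical(ncol(fused), 12L)
  expect_identical(unname(attr(fused, "block_lengths")), c(5L, 7L))
  # training rows of each block are standardized to mean 0 / sd 1
  expect_equal(colMeans(fused[tr, ]), rep(0, 12), tolerance = 1e-10)
  expect_equal(apply(fused[tr, ], 2, sd), rep(1, 12), tolerance = 1e-10)
  # first-block coordinates recover the standardized conventional block
  expect_equal(fused[, 1:5], thyrocad:::standardize_block(conv, tr), ignore_attr = TRUE)
  # single-block fusion is the standardized block itself
  expect_equal(fuse_features(deep = deep, train_mask = tr),
               thyrocad:::standardize_block(deep, tr), ignore_attr = TRUE)

  expect_error(fuse_features(NULL, NULL), class = "thyrocad_config_error")
  bad <- conv; bad[1, 1] <- NaN
  expect_error(fuse_features(bad, deep), class = "thyrocad_data_error")
  # constant columns become zeros, never NaN
  conv[, 2] <- 7
  f2 <- fuse_features(conv, deep, train_mask = tr)
  expect_true(all(f2[, 2] == 0))
})

test_that("classifiers separate a separable toy problem and are seed-stable", {
  set.seed(3)
  X <- rbind(matrix(rnorm(40, mean = 0), 20, 2), matrix(rnorm(40, mean = 6), 20, 2))
  y <- rep(c("benign", "malignant"), each = 20)
  for (kind in c("random_forest", "adaboost")) {
    clf <- train_classifier(X, y, kind = kind, seed = 5)
    pred <- predict(clf, X)
    expect_equal(mean(pred$pred == y), 1)
    clf2 <- train_classifier(X, y, kind = kind, seed = 5)
    probe <- matrix(rnorm(20, mean = 3), 10, 2)
    expect_identical(predict(clf, probe), predict(clf2, probe))
  }
  expect_error(train_classifier(X, rep("benign", 40)), class = "thyrocad_data_error")
  expect_error(train_classifier(X, rep(c("benign", "evil"), 20)), class = "thyrocad_data_error")
})

test_that("shuffled labels yield held-out accuracy near chance", {
  set.seed(17)
  accs <- replicate(20, {
    X <- matrix(rnorm(60 * 4), 60, 4)
    y <- sample(rep(c("benign", "malignant"), 30))
    clf <- train_classifier(X[1:40, ], y[1:40], "random_forest",
                            params = list(num_trees = 100), seed = 1)
    mean(predict(clf, X[41:60, ])$pred == y[41:60])
  })
  # binomial null around 0.5: the mean of 20 repeats of n=20 draws
  expect_lt(abs(mean(accs) - 0.5), 3 * sqrt(0.25 / (20 * 20)) + 0.02)
})

test_that("confusion counts and the Eq-style metrics agree with hand arithmetic", {
  cc <- confusion_counts(c("malignant", "benign"), c("malignant", "benign"))
  expect_equal(unlist(cc[c("TP", "TN", "FP", "FN")]), c(TP = 1, TN = 1, FP = 0, FN = 0))
  m <- compute_metrics(cc)
  expect_equal(c(m$accuracy, m$specificity, m$sensitivity), c(1, 1, 1))

  cc2 <- confusion_counts(c("malignant", "malignant", "benign"),
                          rep("malignant", 3))
  expect_equal(unlist(cc2[c("TP", "FP", "TN", "FN")]), c(TP = 2, FP = 1, TN = 0, FN = 0))

  cc3 <- structure(list(TP = 3, TN = 2, FP = 2, FN = 1), class = "confusion_counts")
  m3 <- compute_metrics(cc3)
  expect_equal(m3$sensitivity, 0.75)
  expect_equal(m3$specificity, 0.5)
  expect_equal(m3$accuracy, 0.625)

  # degenerate denominators are flagged, not silently zeroed
  cc4 <- structure(list(TP = 0, TN = 5, FP = 0, FN = 0), class = "confusion_counts")
  m4 <- compute_metrics(cc4)
  expect_true(is.na(m4$sensitivity))
  expect_match(m4$undefined, "sensitivity")
  expect_error(compute_metrics(structure(list(TP = 0, TN = 0, FP = 0, FN = 0),
                                         class = "confusion_counts")),
               class = "thyrocad_data_error")
  expect_error(confusion_counts("malignant", "Malignant"), class = "thyrocad_data_error")
})

test_that("counts always sum to the sample size on random label vectors", {
  set.seed(23)
  for (i in 1:25) {
    n <- sample(1:40, 1)
    yt <- sample(c("benign", "malignant"), n, replace = TRUE)
    yp <- sample(c("benign", "malignant"), n, replace = TRUE)
    cc <- confusion_counts(yt, yp)
    expect_equal(cc$TP + cc$TN + cc$FP + cc$FN, n)
    if (cc$TP + cc$FN > 0 && cc$TN + cc$FP > 0) {
      m <- compute_metrics(cc)
      P <- cc$TP + cc$FN; N <- cc$TN + cc$FP
      expect_equal(m$accuracy, (P * m$sensitivity + N * m$specificity) / (P + N))
    }
  }
})
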