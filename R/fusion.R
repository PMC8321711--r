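#' Fuse conventional and deep feature blocks
#'
#' Concatenates the conventional block and the deep block, in that fixed
#' order, after standardizing each block column-wise with training-split
#' statistics. Per-block standardization keeps the 960-dimensional deep
#' block from numerically dominating shorter classical blocks. Columns
#' whose training standard deviation is (near) zero are set to zero rather
#' than divided by it.
#'
#' @param conventional numeric matrix (images x d1) or NULL.
#' @param deep numeric matrix (images x 960) or NULL.
#' @param train_mask logical vector marking the rows whose mean/sd
#'   standardize each column; defaults to all rows.
#' @return Fused matrix with `ncol(conventional) + ncol(deep)` columns and
#'   attribute `block_lengths`.
#' @export
fuse_features <- function(conventional = NULL, deep = NULL, train_mask = NULL) {
  if (is.null(conventional) && is.null(deep)) {
    stop_config("at least one of conventional and deep features must be given")
  }
  blocks <- Filter(Negate(is.null), list(conventional = conventional, deep = deep))
  n <- unique(vapply(blocks, nrow, integer(1)))
  if (length(n) != 1L) stop_data("feature blocks disagree on the number of images")
  if (is.null(train_mask)) train_mask <- rep(TRUE, n)
  std <- lapply(blocks, function(b) {
    if (anyNA(b) || any(!is.finite(b))) stop_data("non-finite feature values")
    standardize_block(b, train_mask)
  })
  out <- do.call(cbind, std)
  attr(out, "block_lengths") <- vapply(std, ncol, integer(1))
  out
}

standardize_block <- function(b, train_mask) {
  tr <- b[train_mask, , drop = FALSE]
  mu <- colMeans(tr)
  sg <- apply(tr, 2L, stats::sd)
  out <- sweep(b, 2L, mu)
  keep <- sg > 1e-12
  out[, keep] <- sweep(out[, keep, drop = FALSE], 2L, sg[keep], `/`)
  out[, !keep] <- 0
  out
}

#' Train an ensemble classifier
#'
#' `kind = "random_forest"` fits a probability forest (ranger backend,
#' single thread, seeded; 500 trees and sqrt(d) candidate features per
#' split by default). `kind = "adaboost"` fits discrete AdaBoost (SAMME)
#' over decision stumps (depth-1 rpart trees; 200 rounds by default).
#'
#' @param features numeric matrix, one row per sample.
#' @param labels character vector in `{benign, malignant}`.
#' @param kind `"random_forest"` or `"adaboost"`.
#' @param params optional list: `num_trees` (forest), `n_rounds`
#'   (AdaBoost).
#' @param seed integer seed.
#' @return A `thyro_classifier` handle with a [predict()] method returning
#'   a tibble with `prob_malignant` and `pred`. The decision threshold is
#'   0.5 on the malignant probability; exact ties go to benign.
#' @export
train_classifier <- function(features, labels, kind = c("random_forest", "adaboost"),
                             params = list(), seed = 1L) {
  kind <- match.arg(kind)
  labels <- as.character(labels)
  bad <- setdiff(unique(labels), c("benign", "malignant"))
  if (length(bad)) stop_data(paste0("unknown label: ", paste(bad, collapse = ", ")))
  if (length(unique(labels)) < 2L) stop_data("training labels contain a single class")
  if (min(table(labels)) < 2L) stop_data("need at least 2 samples per class")
  features <- as.matrix(features)
  colnames(features) <- paste0("f", seq_len(ncol(features)))
  fit <- if (kind == "random_forest") {
    n_trees <- params$num_trees %||% 500L
    ranger::ranger(
      x = features, y = factor(labels, levels = c("benign", "malignant")),
      num.trees = n_trees, probability = TRUE,
      mtry = max(1L, floor(sqrt(ncol(features)))),
      seed = as.integer(seed), num.threads = 1L
    )
  } else {
    adaboost_fit(features, labels, n_rounds = params$n_rounds %||% 200L)
  }
  structure(list(kind = kind, fit = fit, n_features = ncol(features)),
            class = "thyro_classifier")
}

#' @export
predict.thyro_classifier <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$n_features) {
    stop_dim(sprintf("classifier expects %d features, got %d",
                     object$n_features, ncol(newdata)))
  }
  colnames(newdata) <- paste0("f", seq_len(ncol(newdata)))
  p <- if (object$kind == "random_forest") {
    pr <- predict(object$fit, data = as.data.frame(newdata), num.threads = 1L)$predictions
    pr[, "malignant"]
  } else {
    adaboost_prob(object$fit, newdata)
  }
  tibble::tibble(
    prob_malignant = as.numeric(p),
    pred = ifelse(p > 0.5, "malignant", "benign")
  )
}

# ---- discrete AdaBoost (SAMME, two classes) over rpart stumps -------------

adaboost_fit <- function(X, labels, n_rounds = 200L) {
  y <- ifelse(labels == "malignant", 1, -1)
  n <- length(y)
  w <- rep(1 / n, n)
  df <- as.data.frame(X)
  stumps <- list(); alphas <- numeric(0)
  ctrl <- rpart::rpart.control(maxdepth = 1L, cp = -1, minsplit = 2L,
                               minbucket = 1L, xval = 0L, maxsurrogate = 0L,
                               usesurrogate = 0L)
  for (r in seq_len(n_rounds)) {
    df$.y <- factor(y, levels = c(-1, 1))
    fit <- rpart::rpart(.y ~ ., data = df, weights = w, method = "class",
                        control = ctrl)
    pred <- ifelse(predict(fit, df, type = "class") == "1", 1, -1)
    err <- sum(w[pred != y])
    if (err >= 0.5) break
    err <- max(err, 1e-10)
    alpha <- 0.5 * log((1 - err) / err)
    stumps[[length(stumps) + 1L]] <- fit
    alphas <- c(alphas, alpha)
    w <- w * exp(-alpha * y * pred)
    w <- w / sum(w)
    if (err <= 1e-10) break
  }
  if (!length(stumps)) stop_data("AdaBoost found no stump better than chance")
  list(stumps = stumps, alphas = alphas)
}

adaboost_prob <- function(model, X) {
  df <- as.data.frame(X)
  score <- numeric(nrow(df))
  for (i in seq_along(model$stumps)) {
    pred <- ifelse(predict(model$stumps[[i]], df, type = "class") == "1", 1, -1)
    score <- score + model$alphas[i] * pred
  }
  # margin -> [0, 1] score: weighted fraction of votes for malignant
  (score / sum(model$alphas) + 1) / 2
}
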