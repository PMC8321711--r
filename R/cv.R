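#' Augment the training split by right-angle rotations and flips
#'
#' Appends transformed copies of every training image with inherited
#' labels; with the default rotations \{90, 180, 270\} plus horizontal
#' flip, every training image yields 8 copies (4 rotations including
#' identity x 2 flip states), so the training split grows eightfold. The
#' test split is never touched; requesting augmentation of it is a
#' configuration error.
#'
#' @param dataset a dataset tibble.
#' @param rotations subset of `c(90, 180, 270)` in degrees.
#' @param horizontal_flip also add horizontally mirrored copies.
#' @param split the split to augment; only `"train"` is allowed.
#' @return The augmented dataset; augmented rows carry suffixed paths.
#' @export
augment_training <- function(dataset, rotations = c(90, 180, 270),
                             horizontal_flip = TRUE, split = "train") {
  if (!identical(split, "train")) {
    stop_config("augmentation may only be applied to the training split")
  }
  if (!all(rotations %in% c(90, 180, 270))) {
    stop_config("rotations must be drawn from {90, 180, 270}")
  }
  if (!length(rotations) && !horizontal_flip) return(dataset)
  tr <- dataset[dataset$split == "train", ]
  extra <- list()
  variants <- c(0, rotations)
  for (rot in variants) {
    for (fl in c(FALSE, if (horizontal_flip) TRUE else NULL)) {
      if (rot == 0 && !fl) next  # identity already present
      tag <- paste0(if (rot > 0) paste0("_rot", rot) else "", if (fl) "_flip" else "")
      aug <- tr
      aug$path <- paste0(tools::file_path_sans_ext(tr$path), tag, ".png")
      aug$image <- lapply(tr$image, function(im) {
        out <- if (rot > 0) rotate_image(im, rot %/% 90L) else im
        if (fl) out <- flip_image_horizontal(out)
        out
      })
      extra[[length(extra) + 1L]] <- aug
    }
  }
  dplyr::bind_rows(c(list(dataset), extra))
}

#' Fusion / evaluation configuration
#'
#' Selects the feature arms and classifier for cross-validated evaluation.
#'
#' @param conventional classical feature block: `"hog"`, `"lbp"`,
#'   `"sift_bow"`, `"surf_bow"` or `"none"`.
#' @param use_deep append the 960-dimensional discriminator feature.
#' @param classifier `"random_forest"` or `"adaboost"`.
#' @param classifier_params list passed to [train_classifier()].
#' @param cv_folds number of stratified folds (>= 2).
#' @param seed integer seed governing folds, model fits and the GAN.
#' @return A `fusion_config` list. At least one feature source must be
#'   enabled.
#' @export
fusion_config <- function(conventional = c("surf_bow", "hog", "lbp", "sift_bow", "none"),
                          use_deep = TRUE,
                          classifier = c("random_forest", "adaboost"),
                          classifier_params = list(),
                          cv_folds = 5L, seed = 1L) {
  conventional <- match.arg(conventional)
  classifier <- match.arg(classifier)
  if (conventional == "none" && !use_deep) {
    stop_config("at least one feature source (conventional or deep) must be enabled")
  }
  if (cv_folds < 2L) stop_config("cv_folds must be >= 2")
  structure(list(conventional = conventional, use_deep = isTRUE(use_deep),
                 classifier = classifier, classifier_params = classifier_params,
                 cv_folds = as.integer(cv_folds), seed = as.integer(seed)),
            class = "fusion_config")
}

# Stratified fold assignment: within each class, a seeded permutation is
# dealt round-robin across folds, so fold sizes differ by at most one per
# class and every sample is held out exactly once.
assign_folds <- function(labels, k, seed) {
  folds <- integer(length(labels))
  for (lab in unique(labels)) {
    idx <- which(labels == lab)
    if (length(idx) < k) {
      stop_config(sprintf("class '%s' has %d samples, fewer than %d folds",
                          lab, length(idx), k))
    }
    perm <- with_seed(derive_seed(seed, paste0("folds-", lab)), sample(idx))
    folds[perm] <- rep_len(seq_len(k), length(perm))
  }
  folds
}

#' Cross-validate a feature-fusion pipeline
#'
#' Runs stratified k-fold cross-validation over the dataset. Within each
#' fold, everything that is fitted — the enhancement policy's targets, the
#' bag-of-visual-words codebook, feature standardization statistics, the
#' GAN and the classifier — sees only that fold's training portion; the
#' held-out images enter only at prediction time (a leakage guard asserts
#' this on image digests). Per-fold confusion counts are pooled for the
#' aggregate metrics.
#'
#' @param dataset a dataset tibble (`path`, `label`, `split`, `image`); the
#'   manifest's own split column is advisory here — the fold assignment
#'   governs.
#' @param config a [fusion_config()].
#' @param features a [feature_extraction_config()].
#' @param enhance an [enhancement_config()] applied within each fold.
#' @param gan a [gan_train_config()] (used when `use_deep = TRUE`); its
#'   seed is re-derived per fold.
#' @param augment optional list with elements `rotations` and
#'   `horizontal_flip` for training-split augmentation within each fold.
#' @return A `metrics_report`.
#' @export
cross_validate <- function(dataset, config = fusion_config(),
                           features = feature_extraction_config(),
                           enhance = enhancement_config(),
                           gan = gan_train_config(),
                           augment = NULL) {
  reports <- cross_validate_arms(dataset, list(main = config), features,
                                 enhance, gan, augment,
                                 cv_folds = config$cv_folds, seed = config$seed)
  reports$main
}

#' Cross-validate several feature arms over shared folds
#'
#' Evaluates multiple [fusion_config()] arms on identical stratified folds,
#' refitting shared components (codebooks, the GAN) once per fold and
#' reusing them across arms — the natural design for comparing classical,
#' deep and fused feature spaces under the same resampling.
#'
#' @inheritParams cross_validate
#' @param arms named list of [fusion_config()] objects.
#' @param cv_folds,seed fold count and seed governing the shared folds.
#' @param cache optional per-image feature cache (from
#'   [feature_cache()]); pass the same cache across repeated evaluations of
#'   one dataset to avoid recomputing per-image descriptors, which depend
#'   only on pixels, never on folds.
#' @return A named list of `metrics_report` objects, one per arm.
#' @export
cross_validate_arms <- function(dataset, arms,
                                features = feature_extraction_config(),
                                enhance = enhancement_config(),
                                gan = gan_train_config(),
                                augment = NULL,
                                cv_folds = 5L, seed = 1L,
                                cache = NULL) {
  stopifnot(length(arms) >= 1L, all(vapply(arms, inherits, logical(1), "fusion_config")))
  if (is.null(names(arms))) names(arms) <- paste0("arm", seq_along(arms))
  n <- nrow(dataset)
  folds <- assign_folds(dataset$label, cv_folds, seed)
  kinds <- unique(unlist(lapply(arms, function(a) {
    c(if (a$conventional != "none") a$conventional, if (a$use_deep) "deep")
  })))
  if (is.null(cache)) cache <- feature_cache_new()
  counts <- lapply(arms, function(a) vector("list", cv_folds))

  for (f in seq_len(cv_folds)) {
    ds <- dataset
    ds$split <- ifelse(folds == f, "test", "train")
    ds <- apply_policy(ds, enhance)
    if (!is.null(augment)) {
      ds <- augment_training(ds,
                             rotations = augment$rotations %||% c(90, 180, 270),
                             horizontal_flip = augment$horizontal_flip %||% TRUE)
    }
    is_tr <- ds$split == "train"
    guard_fit <- vapply(ds$image[is_tr], image_digest, character(1))
    guard_test <- vapply(ds$image[!is_tr], image_digest, character(1))
    if (length(intersect(guard_fit, guard_test))) {
      stop_data("leakage guard: a held-out image appeared among fit-time inputs")
    }

    blocks <- list()
    for (kind in kinds) {
      blocks[[kind]] <- fold_feature_block(ds, kind, features, gan, cache,
                                           seed = derive_seed(seed, sprintf("fold%d-%s", f, kind)))
    }
    for (an in names(arms)) {
      a <- arms[[an]]
      conv <- if (a$conventional != "none") blocks[[a$conventional]] else NULL
      deep <- if (a$use_deep) blocks[["deep"]] else NULL
      X <- fuse_features(conv, deep, train_mask = is_tr)
      clf <- train_classifier(X[is_tr, , drop = FALSE], ds$label[is_tr],
                              kind = a$classifier, params = a$classifier_params,
                              seed = derive_seed(seed, sprintf("fold%d-%s-clf", f, an)))
      pred <- predict(clf, X[!is_tr, , drop = FALSE])
      counts[[an]][[f]] <- confusion_counts(ds$label[!is_tr], pred$pred)
    }
  }
  out <- lapply(names(arms), function(an) {
    new_metrics_report(counts[[an]], config = arms[[an]])
  })
  names(out) <- names(arms)
  out
}

fold_feature_block <- function(ds, kind, features, gan, cache, seed) {
  is_tr <- ds$split == "train"
  if (kind %in% c("hog", "lbp")) {
    rows <- lapply(ds$image, single_image_feature, method = kind,
                   cfg = features, cache = cache)
    return(do.call(rbind, rows))
  }
  if (kind %in% c("sift_bow", "surf_bow")) {
    sets <- lapply(ds$image, single_image_descriptors, method = kind,
                   cfg = features, cache = cache)
    cb <- build_codebook(sets[is_tr], k = features$bow_k,
                         iterations = features$bow_iterations, seed = seed,
                         max_descriptors = features$bow_max_descriptors)
    return(do.call(rbind, lapply(sets, bow_encode, codebook = cb)))
  }
  if (kind == "deep") {
    g <- gan
    g$seed <- seed
    model <- train_resgan(ds, g)
    # extract at the common analysis resolution: the early taps then pool
    # speckle-scale texture statistics even when the GAN trained smaller
    return(extract_deep_features(model, ds$image, image_size = features$side))
  }
  stop_config(paste0("unknown feature kind: ", kind))
}
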