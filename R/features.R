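# Dataset-level feature extraction: every image is resized to a common
# square side before fixed-length descriptors are computed, so feature
# length is constant across a dataset. Per-image results are memoized by
# image digest because cross-validation re-enhances only a subset of images
# per fold.

feature_cache_new <- function() new.env(parent = emptyenv())

#' Create a per-image feature cache
#'
#' Memoizes per-image descriptors and fixed-length features by image
#' digest; share one cache across repeated cross-validations of the same
#' images (different folds or seeds) to skip recomputation.
#'
#' @return An environment usable as the `cache` argument of
#'   [cross_validate_arms()].
#' @export
feature_cache <- function() feature_cache_new()

cached_image_value <- function(cache, img, key, fn) {
  if (is.null(cache)) return(fn(img))
  id <- paste0(key, ":", image_digest(img))
  if (is.null(cache[[id]])) cache[[id]] <- fn(img)
  cache[[id]]
}

#' Default feature configurations
#'
#' The defaults mirror the best-performing settings of the method's
#' parameter sweep: HOG with cell (8, 8), block (1, 1) and 9 unsigned bins;
#' LBP with radius 2 and 16 neighbors (uniform-pattern histogram, 243
#' bins); bag-of-visual-words vocabularies of size `k = 1000` built with a
#' single Lloyd pass (`iterations = 1`).
#'
#' @param side common resize side for feature extraction, pixels.
#' @param hog,lbp,sift,surf per-extractor configs.
#' @param bow_k vocabulary size.
#' @param bow_iterations k-means Lloyd pass budget.
#' @param bow_max_descriptors cap on the pooled descriptor count entering
#'   k-means (a seeded subsample when more are available — the usual
#'   practice for visual vocabularies; encoding still uses every
#'   descriptor).
#' @return A `feature_extraction_config` list.
#' @export
feature_extraction_config <- function(side = 128L,
                                      hog = hog_config(),
                                      lbp = lbp_config(),
                                      sift = sift_config(),
                                      surf = surf_config(),
                                      bow_k = 1000L,
                                      bow_iterations = 1L,
                                      bow_max_descriptors = 4000L) {
  structure(list(side = as.integer(side), hog = hog, lbp = lbp,
                 sift = sift, surf = surf, bow_k = as.integer(bow_k),
                 bow_iterations = as.integer(bow_iterations),
                 bow_max_descriptors = as.integer(bow_max_descriptors)),
            class = "feature_extraction_config")
}

single_image_feature <- function(img, method, cfg, cache = NULL) {
  img <- resize_image(img, cfg$side)
  switch(method,
    hog = cached_image_value(cache, img, "hog", function(im) hog_features(im, cfg$hog)),
    lbp = cached_image_value(cache, img, "lbp", function(im) lbp_features(im, cfg$lbp)),
    stop_config(paste0("unknown per-image feature method: ", method))
  )
}

single_image_descriptors <- function(img, method, cfg, cache = NULL) {
  img <- resize_image(img, cfg$side)
  switch(method,
    sift_bow = cached_image_value(cache, img, "sift", function(im) {
      detect_and_describe(im, "sift_like", cfg$sift)
    }),
    surf_bow = cached_image_value(cache, img, "surf", function(im) {
      detect_and_describe(im, "surf_like", cfg$surf)
    }),
    stop_config(paste0("unknown keypoint method: ", method))
  )
}

#' Extract a feature table from a dataset
#'
#' Computes one fixed-length feature vector per image. For the
#' bag-of-visual-words methods the codebook is fit on the training split
#' only (or pass a prebuilt `codebook`), so the vocabulary never sees test
#' images.
#'
#' @param dataset a dataset tibble with columns `path`, `label`, `split`,
#'   `image`.
#' @param method `"hog"`, `"lbp"`, `"sift_bow"` or `"surf_bow"`.
#' @param config a [feature_extraction_config()].
#' @param codebook optional prebuilt [build_codebook()] result for the BoW
#'   methods.
#' @param seed seed for the codebook k-means.
#' @return A tibble `path`, `label`, `split`, `features` (matrix column,
#'   one row per image). For BoW methods the fitted codebook is attached as
#'   attribute `codebook`.
#' @export
extract_features <- function(dataset, method = c("hog", "lbp", "sift_bow", "surf_bow"),
                             config = feature_extraction_config(),
                             codebook = NULL, seed = 1L) {
  method <- match.arg(method)
  stopifnot(all(c("path", "label", "split", "image") %in% names(dataset)))
  out <- tibble::tibble(path = dataset$path, label = dataset$label,
                        split = dataset$split)
  if (method %in% c("hog", "lbp")) {
    rows <- lapply(dataset$image, single_image_feature, method = method, cfg = config)
    out$features <- do.call(rbind, rows)
    return(out)
  }
  sets <- lapply(dataset$image, single_image_descriptors, method = method, cfg = config)
  if (is.null(codebook)) {
    codebook <- build_codebook(sets[dataset$split == "train"],
                               k = config$bow_k,
                               iterations = config$bow_iterations,
                               seed = seed,
                               max_descriptors = config$bow_max_descriptors)
  }
  out$features <- do.call(rbind, lapply(sets, bow_encode, codebook = codebook))
  attr(out, "codebook") <- codebook
  out
}
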