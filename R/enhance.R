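#' Histogram equalization
#'
#' Remaps intensities through the empirical cumulative distribution of the
#' input: output = round(255 * CDF(v)) with CDF(v) = #\{pixels <= v\} / N and
#' half-up rounding. The mapping is monotone non-decreasing, so intensity
#' order is preserved; a perfectly uniform histogram is (within rounding) a
#' fixed point.
#'
#' @param img a [gray_image()].
#' @return The equalized [gray_image()].
#' @examples
#' histogram_equalize(gray_image(matrix(c(0, 0, 255, 255), 2, 2)))
#' @export
histogram_equalize <- function(img) {
  stopifnot(is_gray_image(img))
  counts <- tabulate(as.integer(img) + 1L, nbins = 256L)
  cdf <- cumsum(counts) / length(img)
  lut <- as.integer(round_half_up(255 * cdf))
  out <- matrix(lut[as.integer(img) + 1L], nrow(img), ncol(img))
  gray_image(out)
}

laplacian_mask <- function(polarity = c("positive", "negative")) {
  polarity <- match.arg(polarity)
  m <- matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0), 3, 3)
  if (polarity == "negative") -m else m
}

#' Laplacian response and sharpening
#'
#' `laplacian_response()` convolves the image with the 3x3 Laplacian mask
#' (positive polarity: negative centre, non-negative ring, i.e.
#' `[[0,1,0],[1,-4,1],[0,1,0]]`; negative polarity is its negation) using
#' edge replication at the border, returning the unclipped signed response.
#' `laplacian_enhance()` sharpens by subtracting the positive-polarity
#' response from (equivalently, adding the negative-polarity response to)
#' the image and clipping to `[0, 255]`; both polarities therefore yield the
#' same sharpened image, differing only in the sign of the reported
#' response.
#'
#' @param img a [gray_image()], at least 3x3.
#' @param polarity `"positive"` (outward-edge operator) or `"negative"`.
#' @return `laplacian_response()`: a numeric matrix (signed, unclipped);
#'   `laplacian_enhance()`: a [gray_image()].
#' @export
laplacian_response <- function(img, polarity = c("positive", "negative")) {
  stopifnot(is_gray_image(img))
  if (nrow(img) < 3L || ncol(img) < 3L) {
    stop_dim("image must be at least 3x3 for the Laplacian mask")
  }
  conv3_replicate(as_pixel_matrix(img), laplacian_mask(match.arg(polarity)))
}

#' @rdname laplacian_response
#' @export
laplacian_enhance <- function(img, polarity = c("positive", "negative")) {
  polarity <- match.arg(polarity)
  resp <- laplacian_response(img, polarity)
  sgn <- if (polarity == "positive") -1 else 1
  gray_image(clip255(round_half_up(as_pixel_matrix(img) + sgn * resp)))
}

#' Logarithm transform
#'
#' Full-range log compression: intensities are mapped through
#' `255 * (log(H + 1) - min log(H + 1)) / (max log(H + 1) - min log(H + 1))`
#' and rounded half-up. This expands near-zero gray values and compresses
#' the bright end; the minimum intensity maps to 0 and the maximum to 255.
#' The logarithm base cancels in the ratio.
#'
#' @param img a [gray_image()] with at least two distinct intensities.
#' @return The transformed [gray_image()].
#' @export
log_transform <- function(img) {
  stopifnot(is_gray_image(img))
  l <- log(as_pixel_matrix(img) + 1)
  lo <- min(l); hi <- max(l)
  if (hi - lo <= 0) {
    stop_degenerate("log transform undefined on a constant image (zero intensity range)")
  }
  gray_image(clip255(round_half_up(255 * (l - lo) / (hi - lo))))
}

#' Gamma correction
#'
#' Power-law remapping `255 * (H / max H)^(1/gamma)`, rounded half-up.
#' `gamma = 1` is the identity when the maximum intensity is 255;
#' `gamma > 1` brightens mid-tones similarly to the logarithm transform.
#'
#' @param img a [gray_image()] with a nonzero maximum intensity.
#' @param gamma exponent parameter, > 0.
#' @return The corrected [gray_image()].
#' @export
gamma_correct <- function(img, gamma) {
  stopifnot(is_gray_image(img))
  if (!is.numeric(gamma) || length(gamma) != 1L || gamma <= 0) {
    stop_param("gamma must be a single positive number", field = "gamma")
  }
  mx <- max(img)
  if (mx <= 0) stop_degenerate("gamma correction undefined on an all-zero image")
  gray_image(clip255(round_half_up(255 * (as_pixel_matrix(img) / mx)^(1 / gamma))))
}

#' Enhancement configuration
#'
#' @param method one of `"none"`, `"hist_eq"`, `"laplacian"`, `"log"`,
#'   `"gamma"`.
#' @param gamma exponent for `method = "gamma"`.
#' @param laplacian_polarity `"positive"` or `"negative"`.
#' @param policy which records the transform targets: `"none"` (identity),
#'   `"malignant_train_only"` (only malignant training images — the policy
#'   that improves downstream classification by darkening/normalizing only
#'   the hypoechoic class) or `"all_train"` (every training image). Test
#'   images are never modified.
#' @return An `enhancement_config` list.
#' @export
enhancement_config <- function(method = c("none", "hist_eq", "laplacian", "log", "gamma"),
                               gamma = 1.5,
                               laplacian_polarity = c("positive", "negative"),
                               policy = c("none", "malignant_train_only", "all_train")) {
  method <- match.arg(method)
  policy <- match.arg(policy)
  laplacian_polarity <- match.arg(laplacian_polarity)
  if (!is.numeric(gamma) || gamma <= 0) stop_param("gamma must be > 0", field = "gamma")
  structure(
    list(method = method, gamma = gamma,
         laplacian_polarity = laplacian_polarity, policy = policy),
    class = "enhancement_config"
  )
}

#' Apply one enhancement method to a single image
#'
#' @param img a [gray_image()].
#' @param config an [enhancement_config()].
#' @return The transformed [gray_image()] (`method = "none"` returns the
#'   input). A degenerate (constant) image falls back to the identity for
#'   the log and gamma transforms, whose normalizations divide by the
#'   intensity range.
#' @export
enhance_image <- function(img, config) {
  stopifnot(inherits(config, "enhancement_config"))
  switch(config$method,
    none = img,
    hist_eq = histogram_equalize(img),
    laplacian = laplacian_enhance(img, config$laplacian_polarity),
    log = tryCatch(log_transform(img), thyrocad_degenerate_error = function(e) img),
    gamma = tryCatch(gamma_correct(img, config$gamma), thyrocad_degenerate_error = function(e) img)
  )
}

#' Apply an enhancement policy to a dataset
#'
#' Implements selective enhancement: depending on `config$policy` the
#' transform touches only malignant training images, all training images,
#' or nothing. Test-split images are never modified under any policy, and
#' non-targeted images pass through byte-identical; labels and splits are
#' unchanged.
#'
#' @param dataset a dataset tibble with columns `label`, `split`, `image`.
#' @param config an [enhancement_config()].
#' @return The dataset with targeted images transformed.
#' @export
apply_policy <- function(dataset, config) {
  stopifnot(inherits(config, "enhancement_config"))
  if (!all(c("label", "split", "image") %in% names(dataset))) {
    stop_data("dataset must have columns label, split, image")
  }
  target <- switch(config$policy,
    none = rep(FALSE, nrow(dataset)),
    malignant_train_only = dataset$label == "malignant" & dataset$split == "train",
    all_train = dataset$split == "train",
    stop_config(paste0("unknown enhancement policy: ", config$policy))
  )
  if (config$method == "none") target[] <- FALSE
  out <- dataset
  out$image <- purrr::map2(dataset$image, target, function(im, hit) {
    if (hit) enhance_image(im, config) else im
  })
  out
}
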