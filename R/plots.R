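#' Plot a grayscale image
#'
#' @param object a [gray_image()].
#' @param ... unused.
#' @return A ggplot raster plot in radiological gray with equal aspect.
#' @export
autoplot.gray_image <- function(object, ...) {
  df <- tibble::tibble(
    y = rep(seq_len(nrow(object)), times = ncol(object)),
    x = rep(seq_len(ncol(object)), each = nrow(object)),
    value = as.vector(unclass(object))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white", limits = c(0, 255)) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_void() +
    ggplot2::labs(fill = "intensity")
}

#' Plot a dataset montage of class examples
#'
#' Shows the first few benign and malignant images side by side — a quick
#' visual check that the morphology presets (round hyperechoic vs
#' taller-than-wide hypoechoic with specks) look as intended.
#'
#' @param dataset a dataset tibble.
#' @param n_per_class images per class.
#' @return A ggplot object.
#' @export
plot_dataset_examples <- function(dataset, n_per_class = 3L) {
  pick <- dplyr::slice_head(dplyr::group_by(dataset, .data$label), n = n_per_class)
  dfs <- purrr::pmap(list(pick$image, pick$path, pick$label), function(im, p, lab) {
    tibble::tibble(
      y = rep(seq_len(nrow(im)), times = ncol(im)),
      x = rep(seq_len(ncol(im)), each = nrow(im)),
      value = as.vector(unclass(im)),
      panel = paste0(lab, ": ", p)
    )
  })
  df <- dplyr::bind_rows(dfs)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white", limits = c(0, 255)) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::facet_wrap(~panel) +
    ggplot2::theme_void() +
    ggplot2::labs(fill = "intensity")
}
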