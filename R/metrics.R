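#' Confusion counts with malignant as the positive class
#'
#' @param y_true,y_pred character vectors of equal length with values in
#'   `{benign, malignant}`.
#' @return A `confusion_counts` list with integer fields `TP`, `TN`, `FP`,
#'   `FN` (TP: malignant predicted malignant; TN: benign predicted benign).
#'   Counts always sum to the number of samples.
#' @examples
#' confusion_counts(c("malignant", "benign"), c("malignant", "benign"))
#' @export
confusion_counts <- function(y_true, y_pred) {
  y_true <- as.character(y_true); y_pred <- as.character(y_pred)
  if (length(y_true) != length(y_pred)) stop_data("y_true and y_pred differ in length")
  bad <- setdiff(unique(c(y_true, y_pred)), c("benign", "malignant"))
  if (length(bad)) stop_data(paste0("unknown label: ", paste(bad, collapse = ", ")))
  structure(
    list(
      TP = sum(y_true == "malignant" & y_pred == "malignant"),
      TN = sum(y_true == "benign" & y_pred == "benign"),
      FP = sum(y_true == "benign" & y_pred == "malignant"),
      FN = sum(y_true == "malignant" & y_pred == "benign")
    ),
    class = "confusion_counts"
  )
}

sum_counts <- function(counts_list) {
  structure(
    list(
      TP = sum(vapply(counts_list, `[[`, numeric(1), "TP")),
      TN = sum(vapply(counts_list, `[[`, numeric(1), "TN")),
      FP = sum(vapply(counts_list, `[[`, numeric(1), "FP")),
      FN = sum(vapply(counts_list, `[[`, numeric(1), "FN"))
    ),
    class = "confusion_counts"
  )
}

#' Accuracy, specificity and sensitivity from confusion counts
#'
#' accuracy = (TP + TN) / (TP + TN + FP + FN), specificity = TN / (TN + FP),
#' sensitivity = TP / (TP + FN), with malignant as the positive class. A
#' metric whose denominator is zero is reported as `NA` and named in the
#' `undefined` field — never silently coerced to 0.
#'
#' @param counts a [confusion_counts()] object (all-zero counts are a data
#'   error).
#' @return A one-row tibble with the counts, the three metrics and an
#'   `undefined` string (comma-separated metric names, or `NA`).
#' @examples
#' compute_metrics(confusion_counts(
#'   rep(c("malignant", "benign"), c(4, 4)),
#'   rep(c("malignant", "benign", "malignant", "benign"), c(3, 1, 2, 2))
#' ))
#' @export
compute_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  n <- counts$TP + counts$TN + counts$FP + counts$FN
  if (n == 0) stop_data("confusion counts are all zero")
  undef <- character(0)
  sens <- if (counts$TP + counts$FN > 0) counts$TP / (counts$TP + counts$FN) else {
    undef <- c(undef, "sensitivity"); NA_real_
  }
  spec <- if (counts$TN + counts$FP > 0) counts$TN / (counts$TN + counts$FP) else {
    undef <- c(undef, "specificity"); NA_real_
  }
  tibble::tibble(
    TP = counts$TP, TN = counts$TN, FP = counts$FP, FN = counts$FN,
    accuracy = (counts$TP + counts$TN) / n,
    specificity = spec,
    sensitivity = sens,
    undefined = if (length(undef)) paste(undef, collapse = ",") else NA_character_
  )
}

new_metrics_report <- function(per_fold_counts, config = NULL) {
  per_fold <- dplyr::bind_rows(lapply(seq_along(per_fold_counts), function(i) {
    dplyr::mutate(compute_metrics(per_fold_counts[[i]]), fold = i, .before = 1L)
  }))
  pooled <- compute_metrics(sum_counts(per_fold_counts))
  structure(list(per_fold = per_fold, pooled = pooled, config = config),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "<metrics_report: %d fold(s); pooled accuracy %.3f, specificity %.3f, sensitivity %.3f>\n",
    nrow(x$per_fold), x$pooled$accuracy, x$pooled$specificity, x$pooled$sensitivity
  ))
  invisible(x)
}

#' Tidy methods for metrics reports
#'
#' `tidy()` returns the per-fold confusion counts and metrics; `glance()`
#' the single pooled row (metrics recomputed from summed per-fold counts).
#'
#' @param x a `metrics_report`.
#' @param ... unused.
#' @return A tibble.
#' @importFrom generics tidy glance
#' @export
tidy.metrics_report <- function(x, ...) x$per_fold

#' @rdname tidy.metrics_report
#' @export
glance.metrics_report <- function(x, ...) x$pooled

#' @export
generics::tidy

#' @export
generics::glance

#' Plot per-fold metrics
#'
#' Bar chart of accuracy, specificity and sensitivity per fold with the
#' pooled value overlaid as a horizontal line.
#'
#' @param object a `metrics_report`.
#' @param ... unused.
#' @return A ggplot object.
#' @importFrom ggplot2 autoplot
#' @export
autoplot.metrics_report <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object$per_fold[, c("fold", "accuracy", "specificity", "sensitivity")],
    -"fold", names_to = "metric", values_to = "value"
  )
  pooled <- tidyr::pivot_longer(
    object$pooled[, c("accuracy", "specificity", "sensitivity")],
    dplyr::everything(), names_to = "metric", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = factor(.data$fold), y = .data$value)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(data = pooled,
                        ggplot2::aes(yintercept = .data$value),
                        linetype = 2) +
    ggplot2::facet_wrap(~metric) +
    ggplot2::labs(x = "fold", y = NULL) +
    ggplot2::ylim(0, 1)
}

#' @export
ggplot2::autoplot
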