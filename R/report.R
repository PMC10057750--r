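#' @export
print.seg_evaluation <- function(x, digits = 4, ...) {
  writeLines(format_summary(x, digits = digits))
  invisible(x)
}

# Summary lines in the tool's output order: discovered ground-truth classes
# first, then pixel-level metrics, then per-object metrics.
format_summary <- function(x, digits = 4) {
  stopifnot(inherits(x, "seg_evaluation"))
  fmt <- function(m) sprintf("Precision: %.*f  Recall: %.*f  F-measure: %.*f",
                             digits, m$precision, digits, m$recall, digits, m$f_measure)
  c(sprintf("Per-object segmentation evaluation of '%s' (%d x %d)",
            x$image_id, x$dim[1], x$dim[2]),
    sprintf("Ground-truth intensity classes: %s",
            paste(as.integer(x$classes), collapse = ", ")),
    paste0("Pixel-level   ", fmt(x$pixel$metrics)),
    paste0("Object-level  ", fmt(x$object$metrics)),
    sprintf("Objects: %d ground truth, %d test (%d test object(s) unmatched)",
            x$n_gt_objects, x$n_test_objects, x$n_unmatched_test))
}

#' Tidy the per-object results of an evaluation
#'
#' @param x A `seg_evaluation`.
#' @param ... Unused.
#' @return A tibble with one row per ground-truth object: ids, matched test
#'   label, TP/FP/FN pixel counts and Precision/Recall/F-measure.
#' @exportS3Method generics::tidy
tidy.seg_evaluation <- function(x, ...) {
  x$per_object
}

#' One-row summary of an evaluation
#'
#' @param x A `seg_evaluation`.
#' @param ... Unused.
#' @return A one-row tibble with pixel-level and object-level metrics and
#'   object counts.
#' @exportS3Method generics::glance
glance.seg_evaluation <- function(x, ...) {
  tibble::tibble(
    image_id = x$image_id,
    pixel_precision = x$pixel$metrics$precision,
    pixel_recall = x$pixel$metrics$recall,
    pixel_f_measure = x$pixel$metrics$f_measure,
    object_precision = x$object$metrics$precision,
    object_recall = x$object$metrics$recall,
    object_f_measure = x$object$metrics$f_measure,
    n_gt_objects = x$n_gt_objects,
    n_test_objects = x$n_test_objects,
    n_unmatched_test = x$n_unmatched_test)
}

#' Plot per-object metrics of an evaluation
#'
#' One point per ground-truth object and metric, with the image-level object
#' metric overlaid as a dashed line; low outliers flag poorly segmented
#' objects.
#'
#' @param object A `seg_evaluation`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.seg_evaluation <- function(object, ...) {
  po <- object$per_object
  long <- tibble::tibble(
    gt_id = rep(po$gt_id, 3L),
    metric = rep(c("precision", "recall", "f_measure"), each = nrow(po)),
    value = c(po$precision, po$recall, po$f_measure))
  long$metric <- factor(long$metric, levels = c("precision", "recall", "f_measure"),
                        labels = c("Precision", "Recall", "F-measure"))
  img <- tibble::tibble(
    metric = factor(c("Precision", "Recall", "F-measure"),
                    levels = c("Precision", "Recall", "F-measure")),
    value = c(object$object$metrics$precision, object$object$metrics$recall,
              object$object$metrics$f_measure))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$gt_id, y = .data$value)) +
    ggplot2::geom_hline(data = img, ggplot2::aes(yintercept = .data$value),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~metric) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "ground-truth object id", y = "value",
                  title = sprintf("Per-object metrics: %s", object$image_id))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom ggplot2 .data
NULL
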