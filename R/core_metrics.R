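#' Binarize a label image
#'
#' Produces the foreground mask used by the traditional pixel-level
#' evaluation: every pixel with a value above zero becomes 1, background
#' stays 0. Idempotent on masks.
#'
#' @param image A label or ground-truth image (non-negative integer matrix).
#' @return An integer matrix of 0/1 with the same dimensions.
#' @examples
#' binarize(matrix(c(0, 100, 200, 0), 2, 2))
#' @export
binarize <- function(image) {
  img <- validate_image(image)
  (img > 0L) * 1L
}

#' Tally TP/FP/FN pixels between two binary masks
#'
#' A pixel is a true positive when it is 1 in both masks, a false positive
#' when it is 1 only in the test mask, and a false negative when it is 1 only
#' in the ground-truth mask. True negatives (0 in both) enter no metric and
#' are not tracked.
#'
#' @param gt_mask,test_mask Binary masks of identical dimensions.
#' @return A `pixel_counts` object: a list with numeric fields `tp`, `fp`,
#'   `fn`.
#' @export
pixel_counts <- function(gt_mask, test_mask) {
  g <- validate_mask(gt_mask)
  t <- validate_mask(test_mask)
  check_same_dim(g, t)
  tp <- sum(g == 1L & t == 1L)
  fp <- sum(g == 0L & t == 1L)
  fn <- sum(g == 1L & t == 0L)
  new_pixel_counts(tp, fp, fn)
}

new_pixel_counts <- function(tp, fp, fn) {
  structure(list(tp = as.numeric(tp), fp = as.numeric(fp), fn = as.numeric(fn)),
            class = "pixel_counts")
}

#' @export
print.pixel_counts <- function(x, ...) {
  cat(sprintf("Pixel counts: TP = %g, FP = %g, FN = %g\n", x$tp, x$fp, x$fn))
  invisible(x)
}

#' Precision, Recall and F-measure from TP/FP/FN counts
#'
#' Precision = TP / (TP + FP), Recall = TP / (TP + FN) and F-measure is their
#' harmonic mean 2PR / (P + R). Every 0/0 denominator yields 0: comparing an
#' all-background image against itself therefore scores Precision 0, since
#' background pixels belong to no segmented object.
#'
#' @param counts A `pixel_counts` object, or any list/vector with named
#'   elements `tp`, `fp`, `fn`.
#' @return A `metric_set` object: list with fields `precision`, `recall`,
#'   `f_measure`, each in \[0, 1\].
#' @examples
#' metrics_from_counts(list(tp = 50, fp = 20, fn = 0))
#' @export
metrics_from_counts <- function(counts) {
  counts <- as.list(counts)
  need <- c("tp", "fp", "fn")
  if (!all(need %in% names(counts))) {
    stop("`counts` must supply named elements tp, fp and fn", call. = FALSE)
  }
  tp <- as.numeric(counts$tp); fp <- as.numeric(counts$fp); fn <- as.numeric(counts$fn)
  if (any(c(tp, fp, fn) < 0)) stop("counts must be non-negative", call. = FALSE)
  p <- ratio_or_zero(tp, tp + fp)
  r <- ratio_or_zero(tp, tp + fn)
  f <- ratio_or_zero(2 * p * r, p + r)
  new_metric_set(p, r, f)
}

ratio_or_zero <- function(num, den) if (den > 0) num / den else 0

new_metric_set <- function(precision, recall, f_measure) {
  structure(list(precision = precision, recall = recall, f_measure = f_measure),
            class = "metric_set")
}

#' @export
print.metric_set <- function(x, ...) {
  cat(sprintf("Precision: %.4f  Recall: %.4f  F-measure: %.4f\n",
              x$precision, x$recall, x$f_measure))
  invisible(x)
}

#' Traditional pixel-level evaluation of a segmentation
#'
#' Binarizes both images and scores the test foreground against the
#' ground-truth foreground, ignoring object identity. Two segmentations with
#' the same overall footprint but different internal object boundaries score
#' a perfect 1 here; see [evaluate_segmentation()] for the per-object
#' evaluation that resolves them.
#'
#' @param gt Ground-truth image (background 0).
#' @param test Test label image (background 0).
#' @return A `metric_set`.
#' @export
evaluate_pixel_level <- function(gt, test) {
  metrics_from_counts(pixel_counts(binarize(gt), binarize(test)))
}
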