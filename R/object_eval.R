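#' Discover the ground-truth intensity classes
#'
#' The ground-truth encoding reuses a small set of intensity values across
#' non-touching objects (the four-color convention), so the evaluation does
#' not need to know the values in advance: they are recovered as the distinct
#' non-zero pixel values of the image, in ascending order. Pixel frequencies
#' are attached as the `n_pixels` attribute; a class occupying fewer than
#' `min_pixels` pixels triggers a warning, as tiny classes usually indicate
#' annotation noise.
#'
#' @param gt Ground-truth image with at least one non-zero pixel.
#' @param min_pixels Minimum pixel count per class before warning
#'   (default 1, i.e. off).
#' @return Integer vector of distinct non-zero values, ascending, with
#'   attribute `n_pixels` holding the per-class pixel counts.
#' @export
intensity_classes <- function(gt, min_pixels = 1L) {
  img <- validate_image(gt)
  vals <- img[img > 0]
  if (length(vals) == 0L) {
    stop("no ground-truth objects: the image has no non-zero pixels", call. = FALSE)
  }
  tab <- table(vals)
  classes <- as.integer(names(tab))
  n_pixels <- as.integer(tab)
  small <- n_pixels < min_pixels
  if (any(small)) {
    warning(sprintf("intensity class(es) %s occupy fewer than %d pixels; possible annotation noise",
                    paste(classes[small], collapse = ", "), min_pixels),
            call. = FALSE)
  }
  structure(classes, n_pixels = n_pixels)
}

#' Enumerate objects in a label or ground-truth image
#'
#' Objects are the connected components of each intensity class. Under the
#' four-color convention touching objects carry different values, so
#' per-class component labeling separates them even when adjacent. Canonical
#' ids 1..K are assigned by ascending intensity class, then by scan order
#' (column-major) of each component's first pixel.
#'
#' @param image Ground-truth or test label image.
#' @param connectivity Pixel neighborhood: 4 (edge-adjacent) or 8 (edge- or
#'   corner-adjacent, the default, matching common cell-mask practice).
#' @return An `object_map`: list with `labels` (integer matrix, ids 1..K),
#'   `sizes` (pixel count per id), `source_class` (originating intensity per
#'   id), `n` (K) and `connectivity`.
#' @export
label_objects <- function(image, connectivity = 8) {
  img <- validate_image(image)
  connectivity <- check_connectivity(connectivity)
  classes <- sort(unique(img[img > 0]))
  labels <- matrix(0L, nrow(img), ncol(img))
  sizes <- integer(0)
  src <- integer(0)
  offset <- 0L
  for (v in classes) {
    comp <- connected_components(img == v, connectivity)
    m <- attr(comp, "n")
    sel <- comp > 0L
    labels[sel] <- comp[sel] + offset
    sizes <- c(sizes, tabulate(comp[sel], m))
    src <- c(src, rep.int(as.integer(v), m))
    offset <- offset + m
  }
  new_object_map(labels, sizes, src, connectivity)
}

check_connectivity <- function(connectivity) {
  if (!(length(connectivity) == 1L && connectivity %in% c(4, 8))) {
    stop("`connectivity` must be 4 or 8", call. = FALSE)
  }
  as.integer(connectivity)
}

new_object_map <- function(labels, sizes, source_class, connectivity = NA_integer_) {
  structure(list(labels = labels,
                 sizes = as.integer(sizes),
                 source_class = as.integer(source_class),
                 n = length(sizes),
                 connectivity = connectivity),
            class = "object_map")
}

#' @export
print.object_map <- function(x, ...) {
  cat(sprintf("Object map: %d object(s) on a %d x %d grid", x$n,
              nrow(x$labels), ncol(x$labels)))
  if (!is.na(x$connectivity)) cat(sprintf(" (%d-connectivity)", x$connectivity))
  cat("\n")
  if (x$n > 0L) {
    cat(sprintf("  sizes: %s px; classes: %s\n",
                paste(utils::head(x$sizes, 10L), collapse = ", "),
                paste(utils::head(x$source_class, 10L), collapse = ", ")))
  }
  invisible(x)
}

# Connected components of a logical mask. Returns an integer matrix with
# components numbered 1..n in scan order (column-major) of their first pixel;
# attribute "n" holds the component count. igraph does the graph traversal.
connected_components <- function(mask, connectivity = 8L) {
  out <- matrix(0L, nrow(mask), ncol(mask))
  idx <- which(mask)
  if (length(idx) == 0L) {
    attr(out, "n") <- 0L
    return(out)
  }
  nr <- nrow(mask); nc <- ncol(mask)
  pos <- matrix(0L, nr, nc)
  pos[idx] <- seq_along(idx)
  row <- ((idx - 1L) %% nr) + 1L
  col <- ((idx - 1L) %/% nr) + 1L
  offs <- list(c(1L, 0L), c(0L, 1L))
  if (connectivity == 8L) offs <- c(offs, list(c(1L, 1L), c(-1L, 1L)))
  from <- integer(0); to <- integer(0)
  for (o in offs) {
    ok <- row + o[1L] >= 1L & row + o[1L] <= nr & col + o[2L] <= nc
    nb <- idx[ok] + o[1L] + o[2L] * nr
    p <- pos[nb]
    hit <- p > 0L
    from <- c(from, pos[idx[ok]][hit])
    to <- c(to, p[hit])
  }
  if (length(from) == 0L) {
    memb <- seq_along(idx)
  } else {
    g <- igraph::make_graph(rbind(from, to), n = length(idx), directed = FALSE)
    memb <- igraph::components(g)$membership
  }
  canon <- match(memb, unique(memb))  # idx is ascending => scan order
  out[idx] <- canon
  attr(out, "n") <- max(canon)
  out
}

#' Match a ground-truth object to a test object by modal overlap
#'
#' The ground-truth object's mask is intersected with the test labeling and
#' the most frequent non-zero test label inside the mask is taken as the
#' matched object. Background does not vote; if the mask covers only
#' background the object is unmatched. Ties resolve to the smallest test
#' label for determinism.
#'
#' @param gt_object_mask Binary mask of one ground-truth object (at least one
#'   foreground pixel).
#' @param test An `object_map` for the test image, or its label matrix.
#' @return The matched test label (integer), or `NA` when unmatched.
#' @export
match_object <- function(gt_object_mask, test) {
  m <- validate_mask(gt_object_mask)
  labels <- if (inherits(test, "object_map")) test$labels else validate_image(test)
  check_same_dim(m, labels, "object mask", "test")
  if (!any(m == 1L)) stop("empty ground-truth object mask", call. = FALSE)
  ov <- labels[m == 1L]
  ov <- ov[ov > 0L]
  if (length(ov) == 0L) return(NA_integer_)
  which.max(tabulate(ov))  # first max = smallest label on ties
}

#' Per-object TP/FP/FN counts
#'
#' For a ground-truth object and its matched test object: TP is the pixel
#' overlap of the pair, FP is the matched test object's size minus TP (test
#' pixels spilling outside this ground-truth object), FN is the ground-truth
#' object's size minus TP (missed pixels). An unmatched object has TP = FP =
#' 0 and FN equal to its size. When two ground-truth objects match the same
#' test object, each is charged the full per-object FP; the image-level
#' aggregation ([aggregate_counts()]) counts every test pixel at most once.
#'
#' @param gt_map `object_map` of the ground truth.
#' @param gt_id Ground-truth object id (1..K).
#' @param matched Matched test label, or `NA`.
#' @param test_map `object_map` of the test image.
#' @return A `pixel_counts` object.
#' @export
per_object_counts <- function(gt_map, gt_id, matched, test_map) {
  stopifnot(inherits(gt_map, "object_map"), inherits(test_map, "object_map"))
  if (!(length(gt_id) == 1L && gt_id >= 1L && gt_id <= gt_map$n)) {
    stop("`gt_id` out of range", call. = FALSE)
  }
  gt_size <- gt_map$sizes[gt_id]
  if (is.na(matched)) return(new_pixel_counts(0, 0, gt_size))
  tp <- sum(test_map$labels[gt_map$labels == gt_id] == matched)
  new_pixel_counts(tp, test_map$sizes[matched] - tp, gt_size - tp)
}

#' Image-level object counts from per-object results
#'
#' TP is the sum of per-object TPs; FP is the total test foreground minus
#' total TP (charging pixels of unmatched test objects and never
#' double-charging a shared test object); FN is the total ground-truth
#' foreground minus total TP.
#'
#' @param per_object A data frame with one row per ground-truth object and a
#'   `tp` column (as produced by [evaluate_segmentation()]).
#' @param gt_map,test_map `object_map`s of the two images.
#' @return A `pixel_counts` object.
#' @export
aggregate_counts <- function(per_object, gt_map, test_map) {
  stopifnot(is.data.frame(per_object), "tp" %in% names(per_object))
  if (nrow(per_object) != gt_map$n) {
    stop("`per_object` must cover every ground-truth object exactly once", call. = FALSE)
  }
  tp <- sum(per_object$tp)
  new_pixel_counts(tp, sum(test_map$sizes) - tp, sum(gt_map$sizes) - tp)
}

#' Per-object segmentation evaluation
#'
#' The full evaluation: discovers the ground-truth intensity classes,
#' enumerates objects in both images, matches every ground-truth object to
#' its colocalized test object by modal overlap, and reports pixel-level
#' metrics, per-object metrics and image-level object metrics.
#'
#' The test image is canonicalized before matching: each distinct non-zero
#' value is treated as one object instance and relabeled 1..n in ascending
#' value order. Set `split_test_components = TRUE` to instead split each
#' distinct value into its connected components (useful when a test labeling
#' reuses values across separate objects).
#'
#' @param gt Ground-truth image (background 0, at least one non-zero pixel;
#'   touching objects must differ in intensity).
#' @param test Test label image of identical dimensions.
#' @param connectivity 4 or 8 (default 8); used to split intensity classes
#'   into objects.
#' @param split_test_components Run connected-component splitting on the test
#'   image too (default `FALSE`: one distinct value = one instance).
#' @param min_class_pixels Warn about ground-truth classes smaller than this
#'   (default 1 = off).
#' @param image_id Identifier carried into the per-object report.
#' @return A `seg_evaluation` object: pixel-level and object-level
#'   `pixel_counts`/`metric_set` pairs, a tibble of per-object results (one
#'   row per ground-truth object, in id order), the discovered intensity
#'   classes, and object counts. See [tidy.seg_evaluation()],
#'   [glance.seg_evaluation()], [autoplot.seg_evaluation()].
#' @examples
#' gt <- matrix(0L, 10, 10); gt[2:5, 2:5] <- 100L; gt[2:5, 6:9] <- 200L
#' ev <- evaluate_segmentation(gt, gt)
#' ev$object$metrics
#' @export
evaluate_segmentation <- function(gt, test, connectivity = 8,
                                  split_test_components = FALSE,
                                  min_class_pixels = 1L,
                                  image_id = "image") {
  gt <- validate_image(gt)
  test <- validate_image(test)
  check_same_dim(gt, test)
  connectivity <- check_connectivity(connectivity)

  classes <- intensity_classes(gt, min_class_pixels)
  px_counts <- pixel_counts(binarize(gt), binarize(test))
  px_metrics <- metrics_from_counts(px_counts)

  gt_map <- label_objects(gt, connectivity)
  test_map <- if (split_test_components) {
    label_objects(test, connectivity)
  } else {
    canonicalize_labels(test)
  }

  k <- gt_map$n
  per <- vector("list", k)
  for (id in seq_len(k)) {
    ov <- test_map$labels[gt_map$labels == id]
    ov <- ov[ov > 0L]
    if (length(ov) == 0L) {
      matched <- NA_integer_
      cnt <- new_pixel_counts(0, 0, gt_map$sizes[id])
    } else {
      hist <- tabulate(ov, test_map$n)
      matched <- which.max(hist)
      tp <- hist[matched]
      cnt <- new_pixel_counts(tp, test_map$sizes[matched] - tp,
                              gt_map$sizes[id] - tp)
    }
    met <- metrics_from_counts(cnt)
    per[[id]] <- tibble::tibble(
      image_id = image_id, gt_id = id,
      class = gt_map$source_class[id], gt_size = gt_map$sizes[id],
      matched_test_id = matched,
      tp = cnt$tp, fp = cnt$fp, fn = cnt$fn,
      precision = met$precision, recall = met$recall, f_measure = met$f_measure)
  }
  per_object <- do.call(rbind, per)

  obj_counts <- aggregate_counts(per_object, gt_map, test_map)
  obj_metrics <- metrics_from_counts(obj_counts)
  matched_ids <- unique(per_object$matched_test_id[!is.na(per_object$matched_test_id)])

  structure(list(
    image_id = image_id,
    dim = dim(gt),
    classes = classes,
    pixel = list(counts = px_counts, metrics = px_metrics),
    object = list(counts = obj_counts, metrics = obj_metrics),
    per_object = per_object,
    n_gt_objects = k,
    n_test_objects = test_map$n,
    n_unmatched_test = test_map$n - length(matched_ids),
    connectivity = connectivity
  ), class = "seg_evaluation")
}

# Relabel distinct non-zero test values to sequential ids 1..n (ascending
# value order), treating each distinct value as one object instance.
canonicalize_labels <- function(test) {
  vals <- sort(unique(test[test > 0]))
  labels <- matrix(match(test, c(0L, vals)) - 1L, nrow(test), ncol(test))
  sizes <- tabulate(labels[labels > 0L], length(vals))
  new_object_map(labels, sizes, vals)
}
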