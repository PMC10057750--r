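#' Read a grayscale label image from TIFF or PNG
#'
#' Reads 8/16/32-bit integer grayscale TIFF or 8/16-bit grayscale PNG into a
#' validated non-negative integer matrix. PNG sample values are rescaled from
#' the [0, 1] decoded range back to integers using the file's bit depth.
#' Multi-channel input is rejected unless `rgb = TRUE`, in which case the
#' first three channels are routed through [rgb_to_labels()].
#'
#' @param path Path to a `.tif`/`.tiff` or `.png` file.
#' @param rgb Convert a 3-channel image to labels instead of rejecting it.
#' @return An integer label matrix.
#' @export
read_label_image <- function(path, rgb = FALSE) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    img <- tiff::readTIFF(path, as.is = TRUE)
    scale <- 1
  } else if (ext == "png") {
    img <- png::readPNG(path, info = TRUE)
    depth <- attr(img, "info")$bit.depth
    if (is.null(depth)) depth <- 8L
    scale <- 2^depth - 1
  } else {
    stop(sprintf("unsupported image format '%s' (use TIFF or PNG): %s", ext, path),
         call. = FALSE)
  }
  if (length(dim(img)) == 3L) {
    if (dim(img)[3L] == 1L) {
      img <- img[, , 1L]
    } else if (rgb) {
      return(rgb_to_labels(img[, , 1:3, drop = FALSE] * scale))
    } else {
      stop(sprintf("%s has %d channels; label images must be single-channel (pass rgb = TRUE to convert an RGB instance image)",
                   path, dim(img)[3L]), call. = FALSE)
    }
  }
  img <- round_integral(img * scale, path)
  img <- matrix(as.numeric(img), nrow(img), ncol(img))  # drop decoder attributes
  validate_image(img, sprintf("image read from %s", path))
}

# Snap decoder rounding error, but refuse genuinely fractional pixel values.
round_integral <- function(x, what) {
  r <- round(x)
  if (any(abs(x - r) > 1e-6)) {
    stop(sprintf("%s contains non-integer pixel values; expected an integer label image", what),
         call. = FALSE)
  }
  r
}

#' Convert an RGB instance-segmentation image to a label image
#'
#' Each distinct color triple becomes one sequential positive label, with
#' colors assigned in lexicographic (R, then G, then B) order; black (0,0,0)
#' maps to background 0. The color-to-label mapping is attached as the
#' `color_map` attribute.
#'
#' @param image A height x width x 3 array; 8-bit channel values either as
#'   integers 0..255 or decoded to \[0, 1\].
#' @return An integer label matrix with attribute `color_map` (tibble with
#'   columns `label`, `r`, `g`, `b`).
#' @export
rgb_to_labels <- function(image) {
  if (!(is.array(image) && length(dim(image)) == 3L && dim(image)[3L] >= 3L)) {
    stop("`image` must be a height x width x 3 array", call. = FALSE)
  }
  image <- image[, , 1:3, drop = FALSE]
  if (max(image) <= 1 && any(image != floor(image))) image <- image * 255
  image <- round(image)
  if (any(image < 0 | image > 255)) {
    stop("RGB channel values must lie in 0..255", call. = FALSE)
  }
  key <- image[, , 1L] * 65536 + image[, , 2L] * 256 + image[, , 3L]
  colors <- sort(unique(key[key > 0]))
  if (length(colors) > 65535L) {
    stop("more than 65535 distinct colors: this looks like a photograph, not a segmentation",
         call. = FALSE)
  }
  labels <- matrix(match(key, c(0, colors)) - 1L, nrow(key), ncol(key))
  map <- tibble::tibble(label = seq_along(colors),
                        r = as.integer(colors %/% 65536),
                        g = as.integer((colors %/% 256) %% 256),
                        b = as.integer(colors %% 256))
  structure(validate_image(labels, "converted RGB image"), color_map = map)
}

#' Write a label image to TIFF or PNG
#'
#' Label images are written losslessly: 16-bit grayscale TIFF by default
#' (8-bit when `.png` is requested, which restricts labels to 0..255).
#' Labels above 65535 are not writable by these formats' integer encodings
#' and raise an error.
#'
#' @param image Label or ground-truth image.
#' @param path Output path ending in `.tif`/`.tiff` or `.png`.
#' @return `path`, invisibly.
#' @export
write_label_image <- function(image, path) {
  img <- validate_image(image)
  ext <- tolower(tools::file_ext(path))
  mx <- max(img)
  if (ext %in% c("tif", "tiff")) {
    if (mx > 65535) stop("labels exceed 65535; 16-bit TIFF cannot encode them losslessly",
                         call. = FALSE)
    tiff::writeTIFF(img / 65535, path, bits.per.sample = 16L, compression = "none")
  } else if (ext == "png") {
    if (mx > 255) stop("labels exceed 255; write a 16-bit TIFF instead", call. = FALSE)
    png::writePNG(img / 255, path)
  } else {
    stop(sprintf("unsupported output format '%s' (use .tif or .png)", ext), call. = FALSE)
  }
  invisible(path)
}

#' Write the per-object CSV report and evaluation summary
#'
#' The CSV carries one row per ground-truth object, in id order, with header
#' `image_id,gt_id,matched_test_id,tp,fp,fn,precision,recall,f_measure`
#' (UTF-8, LF line endings; an unmatched object leaves `matched_test_id`
#' empty). Raw TP/FP/FN counts ride along with the metrics so downstream
#' thresholding needs no recomputation. The summary lists the discovered
#' intensity classes, then pixel-level metrics, then object-level metrics.
#'
#' @param report A `seg_evaluation`.
#' @param csv_path Path for the per-object CSV.
#' @param summary_path Optional path for the text summary; `NULL` prints it
#'   to the console.
#' @return The per-object report tibble, invisibly.
#' @export
write_report <- function(report, csv_path, summary_path = NULL) {
  stopifnot(inherits(report, "seg_evaluation"))
  rows <- report$per_object[, c("image_id", "gt_id", "matched_test_id",
                                "tp", "fp", "fn",
                                "precision", "recall", "f_measure")]
  con <- file(csv_path, open = "wb")
  on.exit(close(con))
  utils::write.csv(as.data.frame(rows), con, row.names = FALSE, na = "",
                   fileEncoding = "UTF-8", eol = "\n")
  lines <- format_summary(report)
  if (is.null(summary_path)) writeLines(lines) else writeLines(lines, summary_path)
  invisible(rows)
}
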