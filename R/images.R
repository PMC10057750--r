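#' @keywords internal
"_PACKAGE"

#' Validate a label or ground-truth image
#'
#' Label images are 2-D grids of non-negative integers: 0 is background and
#' positive values are object labels (test image) or intensity classes
#' (ground-truth image). Labels are identities, not magnitudes, so
#' floating-point input is accepted only when every value is exactly integral.
#'
#' @param x A numeric matrix (or data frame coercible to one).
#' @param arg Name used in error messages.
#' @return An integer matrix with the same dimensions as `x`.
#' @export
validate_image <- function(x, arg = deparse(substitute(x))) {
  force(arg)
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x) || !is.numeric(x)) {
    stop(sprintf("`%s` must be a numeric matrix (a 2-D single-channel image)", arg),
         call. = FALSE)
  }
  if (anyNA(x) || any(!is.finite(x))) {
    stop(sprintf("`%s` contains missing or non-finite pixel values", arg),
         call. = FALSE)
  }
  if (any(x < 0)) {
    stop(sprintf("`%s` contains negative pixel values; labels must be non-negative integers",
                 arg), call. = FALSE)
  }
  if (any(x != floor(x))) {
    stop(sprintf("`%s` contains non-integer pixel values; labels are identities, not magnitudes",
                 arg), call. = FALSE)
  }
  if (max(x, 0) <= .Machine$integer.max) storage.mode(x) <- "integer"
  x
}

# Binary masks: validated label images restricted to {0, 1}.
validate_mask <- function(x, arg = deparse(substitute(x))) {
  force(arg)
  m <- validate_image(x, arg)
  if (any(m > 1L)) {
    stop(sprintf("`%s` is not a binary mask: values other than 0/1 found (did you mean to binarize() first?)",
                 arg), call. = FALSE)
  }
  m
}

check_same_dim <- function(a, b, what_a = "ground truth", what_b = "test") {
  if (!identical(dim(a), dim(b))) {
    stop(sprintf("image dimensions differ: %s is %d x %d but %s is %d x %d",
                 what_a, nrow(a), ncol(a), what_b, nrow(b), ncol(b)),
         call. = FALSE)
  }
  invisible(TRUE)
}

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}
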