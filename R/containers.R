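# Core value types. Class ids are fixed repo-wide:
#   0 = background, 1 = PanCK tumor, 2 = CD3/CD20 TIL, 3 = DAPI nuclei.

#' Fixed class legend of the biomarker segmentation task
#'
#' @return Named integer vector mapping class names to ids.
#' @export
tme_classes <- function() {
  c(background = 0L, panck = 1L, til = 2L, dapi = 3L)
}

#' Construct an RGB image patch
#'
#' The unit of all computation: an `(H, W, 3)` array of fractions in
#' `[0, 1]`, carrying its 0-based origin in the source raster and a source
#' identifier for provenance.
#'
#' @param pixels `(H, W, 3)` numeric array, values in `[0, 1]`.
#' @param origin Integer `(row, col)` offset of the patch in its source
#'   image, 0-based.
#' @param source_id Character scalar naming the source raster.
#' @return A `tmeseg_patch` object.
#' @export
image_patch <- function(pixels, origin = c(0L, 0L), source_id = "patch") {
  d <- dim(pixels)
  if (is.null(d) || length(d) != 3L || d[3L] != 3L)
    stop("pixels must be an (H, W, 3) array")
  if (d[1L] < 1L || d[2L] < 1L) stop("patch dimensions must be positive")
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 1)
    stop("pixel values must lie in [0, 1]")
  structure(list(pixels = pixels, origin = as.integer(origin),
                 source_id = as.character(source_id)),
            class = "tmeseg_patch")
}

#' Construct an integer label mask
#'
#' @param labels `(H, W)` integer matrix with class ids in `0..n_classes-1`.
#' @param n_classes Number of classes `C`.
#' @return A `tmeseg_mask` object.
#' @export
label_mask <- function(labels, n_classes = 4L) {
  if (is.null(dim(labels)) || length(dim(labels)) != 2L)
    stop("labels must be an (H, W) matrix")
  storage.mode(labels) <- "integer"
  if (anyNA(labels) || min(labels) < 0L || max(labels) >= n_classes)
    stop("mask values must lie in 0..n_classes-1")
  structure(list(labels = labels, n_classes = as.integer(n_classes)),
            class = "tmeseg_mask")
}

mask_labels <- function(x) {
  if (inherits(x, "tmeseg_mask")) return(x$labels)
  if (is.matrix(x)) return(x)
  stop("expected a label mask or integer matrix")
}

mask_classes <- function(x) {
  if (inherits(x, "tmeseg_mask")) return(x$n_classes)
  max(x) + 1L
}

patch_pixels <- function(x) {
  if (inherits(x, "tmeseg_patch")) return(x$pixels)
  if (is.array(x) && length(dim(x)) == 3L) return(x)
  stop("expected an image patch or (H, W, 3) array")
}

#' Validate a probability map
#'
#' Checks that an `(H, W, C)` array is a per-pixel class distribution:
#' values in `[0, 1]` and channels summing to 1 within `tol`.
#'
#' @param S `(H, W, C)` numeric array.
#' @param tol Tolerance on the per-pixel channel sum.
#' @return `S`, invisibly, after validation.
#' @export
validate_probability_map <- function(S, tol = 1e-5) {
  d <- dim(S)
  if (is.null(d) || length(d) != 3L) stop("expected an (H, W, C) array")
  if (min(S) < -tol || max(S) > 1 + tol) stop("probabilities must lie in [0, 1]")
  sums <- rowSums(matrix(S, ncol = d[3L]))
  if (max(abs(sums - 1)) > tol) stop("per-pixel channel sums must equal 1")
  invisible(S)
}

#' @export
print.tmeseg_patch <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("image patch %dx%d from '%s' at (%d, %d)\n",
              d[1L], d[2L], x$source_id, x$origin[1L], x$origin[2L]))
  invisible(x)
}

#' @export
print.tmeseg_mask <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("label mask %dx%d, %d classes; class pixel counts: %s\n",
              d[1L], d[2L], x$n_classes,
              paste(tabulate(x$labels + 1L, x$n_classes), collapse = "/")))
  invisible(x)
}
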