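# Data preparation: tiling, Reinhard color normalization, background
# filtering, tumor-fraction patch selection, one-hot encoding, mask-safe
# augmentation. Filter thresholds are strict inequalities.

#' Tile a raster into fixed-size patches
#'
#' Enumerates `tile x tile` windows row-major with the given stride,
#' recording each patch's 0-based `(row, col)` origin. Edge remainders
#' smaller than the tile are dropped, not padded.
#'
#' @param image `(H, W, 3)` array in `[0, 1]` (or a [image_patch()]).
#' @param tile Tile side in pixels; must not exceed either image extent.
#' @param stride Step between tile origins (default: non-overlapping).
#' @param source_id Provenance string stamped on every patch.
#' @return List of [image_patch()] objects, row-major.
#' @export
tile_image <- function(image, tile, stride = tile, source_id = "image") {
  px <- patch_pixels(image)
  d <- dim(px)
  if (tile > d[1L] || tile > d[2L])
    stop("tile size exceeds image extent")
  if (stride <= 0) stop("stride must be positive")
  r0 <- seq(0L, d[1L] - tile, by = stride)
  c0 <- seq(0L, d[2L] - tile, by = stride)
  out <- vector("list", length(r0) * length(c0))
  i <- 0L
  for (r in r0) for (cc in c0) {                    # row-major enumeration
    i <- i + 1L
    out[[i]] <- image_patch(px[(r + 1L):(r + tile), (cc + 1L):(cc + tile), ,
                               drop = FALSE],
                            origin = c(r, cc), source_id = source_id)
  }
  out
}

# Ruderman RGB -> lab (decorrelated log-LMS) transform matrices
.rgb2lms <- matrix(c(0.3811, 0.5783, 0.0402,
                     0.1967, 0.7244, 0.0782,
                     0.0241, 0.1288, 0.8444), 3, 3, byrow = TRUE)
.lms2rgb <- solve(.rgb2lms)
.lms2lab <- matrix(c(1 / sqrt(3), 0, 0,
                     0, 1 / sqrt(6), 0,
                     0, 0, 1 / sqrt(2)), 3, 3, byrow = TRUE) %*%
  matrix(c(1, 1, 1, 1, 1, -2, 1, -1, 0), 3, 3, byrow = TRUE)
.lab2lms <- solve(.lms2lab)

rgb_to_lab <- function(px) {
  m <- matrix(px, ncol = 3L)                         # N x 3
  lms <- m %*% t(.rgb2lms)
  lms <- log10(pmax(lms, 1e-6))
  lms %*% t(.lms2lab)
}

lab_to_rgb <- function(lab, d) {
  lms <- 10^(lab %*% t(.lab2lms))
  array(lms %*% t(.lms2rgb), d)
}

#' Reference statistics for color normalization
#'
#' Per-channel target mean and standard deviation in the decorrelated
#' log-LMS (lab) color space used by Reinhard-style normalization.
#'
#' @param mean,sd Length-3 numeric vectors; all `sd` entries must be > 0.
#' @return A `tmeseg_colorref` object.
#' @export
normalization_reference <- function(mean, sd) {
  stopifnot(length(mean) == 3L, length(sd) == 3L)
  if (any(sd <= 0)) stop("reference standard deviations must be positive")
  structure(list(mean = as.numeric(mean), sd = as.numeric(sd)),
            class = "tmeseg_colorref")
}

#' Measure a normalization reference from an image
#'
#' @param image Patch or `(H, W, 3)` array to measure.
#' @return A [normalization_reference()] with the image's lab statistics.
#' @export
normalization_reference_from <- function(image) {
  lab <- rgb_to_lab(patch_pixels(image))
  normalization_reference(colMeans(lab), apply(lab, 2L, stats::sd))
}

#' Reinhard color normalization of a patch
#'
#' Matches the patch's per-channel mean and standard deviation in the
#' decorrelated lab space to the reference, then maps back to RGB. With
#' `clip = TRUE` (default) the result is clamped to `[0, 1]`; pass
#' `clip = FALSE` to inspect the exact matched statistics. A patch with a
#' zero-variance lab channel is degenerate (e.g. constant color) and is
#' returned unchanged with a warning.
#'
#' @param patch An [image_patch()] (or `(H, W, 3)` array).
#' @param ref A [normalization_reference()].
#' @param clip Clamp the output to `[0, 1]`.
#' @return The normalized patch (same type as the input patch).
#' @export
normalize_color <- function(patch, ref, clip = TRUE) {
  px <- patch_pixels(patch)
  lab <- rgb_to_lab(px)
  mu <- colMeans(lab)
  sd <- apply(lab, 2L, stats::sd)
  if (any(sd < 1e-12)) {
    warning("degenerate patch (zero-variance color channel); returned unchanged")
    return(patch)
  }
  lab <- sweep(lab, 2L, mu)
  lab <- sweep(lab, 2L, ref$sd / sd, `*`)
  lab <- sweep(lab, 2L, ref$mean, `+`)
  out <- lab_to_rgb(lab, dim(px))
  if (clip) out <- pmin(pmax(out, 0), 1)
  if (inherits(patch, "tmeseg_patch"))
    image_patch(out, origin = patch$origin, source_id = patch$source_id)
  else out
}

#' Background fraction of a patch or mask
#'
#' For a label mask, the fraction of class-0 pixels. For an (unlabeled) RGB
#' patch, background is defined by luminance: a pixel is background iff its
#' Rec.709 luminance exceeds `luminance_threshold` (the standard white-glass
#' convention for slide tiles).
#'
#' @param x A label mask, integer matrix, patch, or `(H, W, 3)` array.
#' @param luminance_threshold Luminance cutoff for RGB inputs.
#' @return Fraction in `[0, 1]`.
#' @export
background_fraction <- function(x, luminance_threshold = 0.8) {
  if (inherits(x, "tmeseg_mask") || is.matrix(x))
    return(mean(mask_labels(x) == 0L))
  px <- patch_pixels(x)
  lum <- 0.2126 * px[, , 1L] + 0.7152 * px[, , 2L] + 0.0722 * px[, , 3L]
  mean(lum > luminance_threshold)
}

#' Select patches usable for semi-supervised training
#'
#' Keeps exactly the patches whose background fraction is strictly below
#' `max_background` (default 50%); a patch at exactly the threshold is
#' dropped.
#'
#' @param patches List of patches (or masks) accepted by
#'   [background_fraction()].
#' @param max_background Strict upper bound on the background fraction.
#' @param ... Passed to [background_fraction()].
#' @return The selected subset of `patches`.
#' @export
filter_for_semisup <- function(patches, max_background = 0.5, ...) {
  keep <- vapply(patches, function(p) background_fraction(p, ...) < max_background,
                 logical(1))
  patches[keep]
}

#' Select tumor patches by predicted PanCK fraction
#'
#' A patch qualifies iff the fraction of its pixels whose argmax class is
#' PanCK strictly exceeds `min_fraction` (default 50%); exactly 50% is not
#' selected.
#'
#' @param prob_maps List of `(H, W, C)` probability maps.
#' @param min_fraction Strict lower bound on the PanCK argmax fraction.
#' @param class_id Class id counted as tumor (default: PanCK = 1).
#' @return Integer indices of the selected maps.
#' @export
select_tumor_patches <- function(prob_maps, min_fraction = 0.5,
                                 class_id = tme_classes()[["panck"]]) {
  frac <- vapply(prob_maps, function(S) {
    mean(mask_labels(compress_to_labels(S)) == class_id)
  }, numeric(1))
  which(frac > min_fraction)
}

#' One-hot encode a label mask
#'
#' @param mask A [label_mask()] or integer matrix.
#' @param n_classes Number of classes; any label `>= n_classes` is an error.
#' @return `(H, W, C)` binary array with exactly one 1 per pixel, class
#'   `tmeseg_onehot`.
#' @export
one_hot_encode <- function(mask, n_classes = mask_classes(mask)) {
  m <- mask_labels(mask)
  if (max(m) >= n_classes) stop("mask contains labels >= n_classes")
  d <- dim(m)
  oh <- array(0, c(d[1L], d[2L], n_classes))
  for (ci in seq_len(n_classes)) oh[, , ci] <- (m == ci - 1L) * 1
  structure(oh, class = c("tmeseg_onehot", class(oh)))
}

# --- augmentation ----------------------------------------------------------

#' Neutral augmentation transform
#'
#' @return Identity transform for [apply_augmentation()].
#' @export
identity_transform <- function() {
  list(flip_h = FALSE, flip_v = FALSE, rot90 = 0L,
       hue = 0, sat = 1, val = 1)
}

hsv_to_rgb <- function(h, s, v) {
  h <- (h %% 1) * 6
  i <- floor(h)
  f <- h - i
  p <- v * (1 - s); q <- v * (1 - s * f); t <- v * (1 - s * (1 - f))
  r <- ifelse(i == 0 | i == 5, v, ifelse(i == 1, q, ifelse(i == 4, t, p)))
  g <- ifelse(i == 1 | i == 2, v, ifelse(i == 0, t, ifelse(i == 3, q, p)))
  b <- ifelse(i == 3 | i == 4, v, ifelse(i == 2, t, ifelse(i == 5, q, p)))
  cbind(r, g, b)
}

jitter_hsv <- function(px, hue, sat, val) {
  d <- dim(px)
  m <- t(matrix(px, ncol = 3L))                       # 3 x N in [0,1]
  hsv <- grDevices::rgb2hsv(m, maxColorValue = 1)
  rgb <- hsv_to_rgb(hsv[1L, ] + hue,
                    pmin(pmax(hsv[2L, ] * sat, 0), 1),
                    pmin(pmax(hsv[3L, ] * val, 0), 1))
  array(pmin(pmax(rgb, 0), 1), d)
}

rot90_cw <- function(m, k = 1L) {
  k <- ((k %% 4L) + 4L) %% 4L
  for (i in seq_len(k)) m <- t(m[rev(seq_len(nrow(m))), , drop = FALSE])
  m
}

apply_spatial <- function(m, tr) {
  if (tr$flip_h) m <- m[, rev(seq_len(ncol(m))), drop = FALSE]
  if (tr$flip_v) m <- m[rev(seq_len(nrow(m))), , drop = FALSE]
  if (tr$rot90 != 0L) m <- rot90_cw(m, tr$rot90)
  m
}

#' Apply one augmentation transform to a patch/mask pair
#'
#' The spatial part (horizontal/vertical flips, 90-degree rotations) is
#' applied identically to patch and mask; the photometric part (HSV jitter)
#' touches only the patch, so mask class identity is never altered.
#'
#' @param patch An [image_patch()] or `(H, W, 3)` array.
#' @param mask Optional matching [label_mask()].
#' @param transform A transform list as produced by [identity_transform()].
#' @return List with elements `patch` and `mask`.
#' @export
apply_augmentation <- function(patch, mask = NULL, transform = identity_transform()) {
  px <- patch_pixels(patch)
  out <- array(0, c(dim(apply_spatial(px[, , 1L], transform)), 3L))
  for (ci in 1:3) out[, , ci] <- apply_spatial(px[, , ci], transform)
  if (transform$hue != 0 || transform$sat != 1 || transform$val != 1)
    out <- jitter_hsv(out, transform$hue, transform$sat, transform$val)
  new_patch <- if (inherits(patch, "tmeseg_patch"))
    image_patch(out, origin = patch$origin, source_id = patch$source_id)
  else out
  new_mask <- NULL
  if (!is.null(mask)) {
    ml <- apply_spatial(mask_labels(mask), transform)
    new_mask <- label_mask(ml, n_classes = mask_classes(mask))
  }
  list(patch = new_patch, mask = new_mask)
}

#' Seeded mask-safe augmentation of a labeled pair
#'
#' Draws `n` random transforms (flips, 90-degree rotations, small HSV
#' jitter) and applies each to the pair. Geometric operations act on patch
#' and mask identically; photometric jitter acts on the patch only.
#'
#' @inheritParams apply_augmentation
#' @param seed Integer seed controlling the drawn transforms.
#' @param n Number of augmented copies to produce.
#' @param hue_jitter,sat_jitter,val_jitter Photometric jitter amplitudes.
#' @return List of `n` lists, each with `patch`, `mask`, and the `transform`.
#' @export
augment <- function(patch, mask = NULL, seed = 1L, n = 4L,
                    hue_jitter = 0.02, sat_jitter = 0.1, val_jitter = 0.1) {
  with_seed(seed, {
    lapply(seq_len(n), function(i) {
      tr <- list(flip_h = stats::runif(1) < 0.5,
                 flip_v = stats::runif(1) < 0.5,
                 rot90 = sample(0:3, 1L),
                 hue = stats::runif(1, -hue_jitter, hue_jitter),
                 sat = 1 + stats::runif(1, -sat_jitter, sat_jitter),
                 val = 1 + stats::runif(1, -val_jitter, val_jitter))
      out <- apply_augmentation(patch, mask, tr)
      out$transform <- tr
      out
    })
  })
}
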