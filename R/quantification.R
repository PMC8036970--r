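# Downstream read-outs from predicted class maps: pooled class fractions,
# fluorescence binarization, PD-1-expressing-TIL percentages, overlay
# rendering, and the Pearson comparison utility.
#
# Quantification is pixel-based: class pixel fractions proxy for the
# nucleus-anchored cell counting of commercial mIHC software, which would
# require nucleus instance segmentation not in scope here.

#' Pooled per-class pixel fractions
#'
#' Pools pixel counts over one or several label masks and divides by the
#' total, yielding a probability vector over classes; `tumor_fraction` is
#' the PanCK class share and `til_fraction` the CD3/CD20 class share.
#'
#' @param masks A [label_mask()] or list of masks sharing the class legend.
#' @param n_classes Number of classes (default: taken from the first mask).
#' @return A `tmeseg_fractions` list: `fractions` (named numeric vector
#'   summing to 1), `tumor_fraction`, `til_fraction`, `total_pixels`.
#' @export
class_fractions <- function(masks, n_classes = NULL) {
  if (inherits(masks, "tmeseg_mask") || is.matrix(masks)) masks <- list(masks)
  if (is.null(n_classes)) n_classes <- mask_classes(masks[[1L]])
  counts <- numeric(n_classes)
  for (m in masks) counts <- counts + tabulate(mask_labels(m) + 1L, n_classes)
  tot <- sum(counts)
  fr <- counts / tot
  names(fr) <- if (n_classes == 4L) names(tme_classes()) else
    paste0("class", seq_len(n_classes) - 1L)
  structure(list(fractions = fr,
                 tumor_fraction = unname(fr[tme_classes()[["panck"]] + 1L]),
                 til_fraction = unname(fr[tme_classes()[["til"]] + 1L]),
                 total_pixels = tot),
            class = "tmeseg_fractions")
}

#' Binarize a fluorescence channel
#'
#' Thresholds a single-channel raster either at a fixed cutoff or at the
#' Otsu threshold (the value maximizing between-class variance of the
#' 256-bin intensity histogram). A constant image is degenerate for Otsu
#' and yields an all-zero mask with a warning.
#'
#' @param channel `(H, W)` numeric matrix in `[0, 1]`.
#' @param method `"otsu"` or `"fixed"`.
#' @param threshold Cutoff for `method = "fixed"`.
#' @return Binary `(H, W)` matrix with attributes `method` and `threshold`.
#' @export
binarize_fluorescence <- function(channel, method = c("otsu", "fixed"),
                                  threshold = NULL) {
  method <- match.arg(method)
  if (!is.matrix(channel)) stop("expected a single-channel (H, W) matrix")
  if (method == "fixed") {
    if (is.null(threshold)) stop("fixed method requires a threshold")
    thr <- threshold
  } else {
    if (max(channel) - min(channel) < 1e-12) {
      warning("constant image: Otsu threshold undefined, returning all-zero mask")
      out <- matrix(0L, nrow(channel), ncol(channel))
      attr(out, "method") <- "otsu"
      attr(out, "threshold") <- NA_real_
      return(out)
    }
    thr <- otsu_threshold(channel)
  }
  out <- (channel > thr) * 1L
  dim(out) <- dim(channel)
  attr(out, "method") <- method
  attr(out, "threshold") <- thr
  out
}

otsu_threshold <- function(x, n_bins = 256L) {
  h <- tabulate(pmin(pmax(floor(x * n_bins) + 1L, 1L), n_bins), n_bins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * seq_len(n_bins))
  mu_t <- mu[n_bins]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  # center of the maximizing plateau (well-separated modes give a flat top)
  best <- which(sigma_b >= max(sigma_b) - 1e-12)
  floor(mean(range(best))) / n_bins
}

#' Quantify PD-1-expressing TILs
#'
#' Intersects a binary PD-1 positivity mask with the predicted TIL class:
#' reports the PD-1-positive TIL pixel count and its fraction of all TIL
#' pixels and of all cell (non-background) pixels — both denominators are
#' reported since either normalization is used in practice. A zero
#' denominator yields an `NA` fraction (flagged undefined).
#'
#' @param pred Predicted [label_mask()].
#' @param pd1 Binary `(H, W)` matrix (1 = PD-1 positive).
#' @param til_class,background_class Class ids of TILs and background.
#' @return A `tmeseg_pd1` list with counts and fractions.
#' @export
pd1_til_quantification <- function(pred, pd1,
                                   til_class = tme_classes()[["til"]],
                                   background_class = tme_classes()[["background"]]) {
  m <- mask_labels(pred)
  if (!identical(dim(m), dim(pd1))) stop("shape mismatch between pred and pd1")
  til <- m == til_class
  cells <- m != background_class
  pos <- sum(til & (pd1 > 0))
  n_til <- sum(til)
  n_cells <- sum(cells)
  structure(list(pd1_positive_til_pixels = pos,
                 til_pixels = n_til,
                 cell_pixels = n_cells,
                 fraction_of_tils = if (n_til > 0) pos / n_til else NA_real_,
                 fraction_of_cells = if (n_cells > 0) pos / n_cells else NA_real_),
            class = "tmeseg_pd1")
}

#' Default rendering colors of the class legend
#'
#' @return `4 x 3` RGB matrix (rows: background, PanCK, TIL, DAPI).
#' @export
class_palette_colors <- function() {
  rbind(background = c(0.10, 0.10, 0.10),
        panck = c(0.85, 0.20, 0.20),
        til = c(0.20, 0.75, 0.20),
        dapi = c(0.25, 0.35, 0.95))
}

#' Render a class map with a PD-1 overlay
#'
#' Paints each class in its legend color and recolors PD-1-positive TIL
#' pixels with the overlay color, so the overlay pixel count equals
#' `pd1_positive_til_pixels` of [pd1_til_quantification()].
#'
#' @param pred Predicted [label_mask()].
#' @param pd1 Binary PD-1 mask of the same shape (or `NULL` for none).
#' @param palette `n_classes x 3` RGB matrix.
#' @param overlay_color RGB triple for PD-1-positive TIL pixels.
#' @param til_class Class id of TILs.
#' @return `(H, W, 3)` RGB array.
#' @export
merge_overlay <- function(pred, pd1 = NULL, palette = class_palette_colors(),
                          overlay_color = c(1, 0.55, 0),
                          til_class = tme_classes()[["til"]]) {
  m <- mask_labels(pred)
  if (!is.null(pd1) && !identical(dim(m), dim(pd1)))
    stop("shape mismatch between pred and pd1")
  out <- array(0, c(nrow(m), ncol(m), 3L))
  for (ch in 1:3) out[, , ch] <- matrix(palette[m + 1L, ch], nrow(m), ncol(m))
  if (!is.null(pd1)) {
    hit <- (m == til_class) & (pd1 > 0)
    for (ch in 1:3) {
      plane <- out[, , ch]
      plane[hit] <- overlay_color[ch]
      out[, , ch] <- plane
    }
  }
  out
}

#' Pearson correlation with a t-distribution p value
#'
#' Standard product-moment correlation; the p value comes from the t
#' statistic with `n - 2` degrees of freedom. Requires at least 3 paired
#' observations and nonzero variance in both series.
#'
#' @param x,y Numeric vectors of equal length `n >= 3`.
#' @return List with `r`, `p`, and `n`.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("x and y differ in length")
  if (length(x) < 3L) stop("need at least 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for zero-variance input")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}
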