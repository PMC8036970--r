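# Disk interfaces: PNG rasters for patches and masks, CSV for label tables
# and training histories, JSON for manifests and metric reports.

#' Write / read an RGB patch as PNG
#'
#' @param patch An [image_patch()] or `(H, W, 3)` array in `[0, 1]`.
#' @param path Output PNG path.
#' @return `path`, invisibly (writer); an [image_patch()] (reader).
#' @export
write_patch_png <- function(patch, path) {
  png::writePNG(patch_pixels(patch), path)
  invisible(path)
}

#' @rdname write_patch_png
#' @param source_id Provenance string for the patch read back.
#' @export
read_patch_png <- function(path, source_id = basename(path)) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 2L) px <- array(rep(px, 3L), c(dim(px), 3L))
  if (dim(px)[3L] > 3L) px <- px[, , 1:3, drop = FALSE]
  image_patch(px, source_id = source_id)
}

#' Write / read a label mask as single-channel 8-bit PNG
#'
#' Class ids are stored directly as 8-bit gray levels (id / 255).
#'
#' @param mask A [label_mask()].
#' @param path PNG path.
#' @param n_classes Classes expected when reading back.
#' @return `path`, invisibly (writer); a [label_mask()] (reader).
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(mask_labels(mask) / 255, path)
  invisible(path)
}

#' @rdname write_mask_png
#' @export
read_mask_png <- function(path, n_classes = 4L) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3L) m <- m[, , 1L]
  label_mask(matrix(as.integer(round(m * 255)), nrow(m), ncol(m)),
             n_classes = n_classes)
}

#' Write a synthetic dataset to a directory
#'
#' Patches as `patch-XXXX.png`, masks as `mask-XXXX.png`, mutation labels
#' (if present) as `labels.csv` (columns `patch_id`, `APC`, `TP53`,
#' `KRAS`), and a `manifest.json` recording the full generating config.
#'
#' @param dataset Result of [generate_dataset()] or
#'   [generate_mutation_dataset()].
#' @param dir Output directory (created if needed).
#' @param config The generating config(s), stored in the manifest.
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir, config = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(dataset$labeled)) {
    for (i in seq_along(dataset$labeled)) {
      write_patch_png(dataset$labeled[[i]]$image,
                      file.path(dir, sprintf("patch-%04d.png", i)))
      write_mask_png(dataset$labeled[[i]]$mask,
                     file.path(dir, sprintf("mask-%04d.png", i)))
    }
    for (i in seq_along(dataset$unlabeled))
      write_patch_png(dataset$unlabeled[[i]],
                      file.path(dir, sprintf("unlabeled-%04d.png", i)))
  }
  if (!is.null(dataset$patches)) {
    for (i in seq_along(dataset$patches)) {
      write_patch_png(dataset$patches[[i]],
                      file.path(dir, sprintf("patch-%04d.png", i)))
      if (!is.null(dataset$masks))
        write_mask_png(dataset$masks[[i]],
                       file.path(dir, sprintf("mask-%04d.png", i)))
    }
  }
  if (!is.null(dataset$labels))
    utils::write.csv(dataset$labels, file.path(dir, "labels.csv"),
                     row.names = FALSE)
  manifest <- list(created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                   n_labeled = length(dataset$labeled),
                   n_unlabeled = length(dataset$unlabeled),
                   n_patches = length(dataset$patches),
                   config = strip_classes(config))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

strip_classes <- function(x) {
  if (is.list(x)) {
    x <- unclass(x)
    lapply(x, strip_classes)
  } else if (is.matrix(x)) {
    apply(x, 1L, as.numeric, simplify = FALSE)
  } else x
}

#' Write a metrics report (JSON) and per-class counts (CSV)
#'
#' @param report A `tmeseg_metrics` report.
#' @param counts Optional [confusion_counts()] for the per-class CSV.
#' @param path JSON output path; the CSV lands next to it.
#' @return `path`, invisibly.
#' @export
write_metrics_report <- function(report, path, counts = NULL) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA)
  if (!is.null(counts)) {
    df <- data.frame(class = seq_along(counts$tp) - 1L, tp = counts$tp,
                     fp = counts$fp, tn = counts$tn, fn = counts$fn)
    utils::write.csv(df, sub("\\.json$", "-per-class.csv", path),
                     row.names = FALSE)
  }
  invisible(path)
}
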