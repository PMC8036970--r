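# Seeded synthetic tissue scenes: elliptical cell regions of the three
# non-background classes painted over a bright background, with per-class
# colors separated enough (relative to the noise) that the segmentation task
# is learnable by construction. Stands in for stained-tissue patch pairs so
# that every downstream stage is testable without any download.

#' Default H&E-like class palette
#'
#' Per-class mean RGB colors (bright background, eosin-pink tumor,
#' basophilic purple TILs, dark blue nuclei) and per-class noise standard
#' deviations. Every pair of class means is separated by well over
#' `3 * noise_sigma` in at least one channel at the default noise level.
#'
#' @param noise_sigma Noise sd used to fill the per-class sd matrix.
#' @return List with `means` (4 x 3) and `sds` (4 x 3).
#' @export
default_palette <- function(noise_sigma = 0.05) {
  means <- rbind(background = c(0.95, 0.93, 0.95),
                 panck      = c(0.85, 0.45, 0.60),   # eosin-pink tumor
                 til        = c(0.45, 0.35, 0.70),   # basophilic lymphocyte
                 dapi       = c(0.15, 0.20, 0.45))   # dark nuclear stain
  list(means = means, sds = matrix(noise_sigma, nrow(means), 3L,
                                   dimnames = list(rownames(means), NULL)))
}

#' Configuration of a synthetic tissue scene
#'
#' Defines the geometry and color statistics of generated scenes. The
#' palette must keep every pair of class means separated by at least
#' `3 * noise_sigma` in some RGB channel, which guarantees the classes are
#' separable and hence that the segmentation task is learnable.
#'
#' @param height,width Scene size in pixels.
#' @param n_classes Number of classes including background (default 4).
#' @param class_palette List with `means` (`n_classes x 3` RGB fractions) and
#'   `sds` (`n_classes x 3` per-class noise sd); default emulates an
#'   H&E-like coloring of the four biomarker classes.
#' @param blob_count_range Integer `(min, max)` count of elliptical regions
#'   per non-background class.
#' @param blob_radius_range Pixel `(min, max)` range of ellipse semi-axes.
#' @param noise_sigma Gaussian pixel noise sd (fraction of dynamic range).
#' @param seed Integer seed making the scene a pure function of this config.
#' @return A `tmeseg_scene_config` list.
#' @export
scene_config <- function(height = 64L, width = 64L, n_classes = 4L,
                         class_palette = default_palette(noise_sigma),
                         blob_count_range = c(2L, 5L),
                         blob_radius_range = c(5, 12),
                         noise_sigma = 0.05, seed = 1L) {
  if (height < 1L || width < 1L) stop("invalid scene dimensions")
  if (n_classes < 2L) stop("need at least background plus one class")
  if (nrow(class_palette$means) != n_classes)
    stop("palette must have exactly n_classes entries")
  if (blob_count_range[1L] < 0L || blob_count_range[2L] < blob_count_range[1L])
    stop("invalid blob_count_range")
  if (blob_radius_range[1L] <= 0 || blob_radius_range[2L] < blob_radius_range[1L])
    stop("invalid blob_radius_range")
  means <- class_palette$means
  for (a in seq_len(n_classes - 1L)) for (b in (a + 1L):n_classes) {
    if (max(abs(means[a, ] - means[b, ])) < 3 * noise_sigma)
      stop(sprintf("palette classes %d and %d are closer than 3 * noise_sigma",
                   a - 1L, b - 1L))
  }
  structure(list(height = as.integer(height), width = as.integer(width),
                 n_classes = as.integer(n_classes),
                 class_palette = class_palette,
                 blob_count_range = as.integer(blob_count_range),
                 blob_radius_range = as.numeric(blob_radius_range),
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "tmeseg_scene_config")
}

# Draw the blob list for one scene: class, center, semi-axes, paint order.
draw_blobs <- function(config) {
  blobs <- list()
  for (cl in seq_len(config$n_classes - 1L)) {       # class ids 1..C-1
    rng <- config$blob_count_range
    k <- rng[1L] + sample.int(rng[2L] - rng[1L] + 1L, 1L) - 1L
    if (k == 0L) next
    for (i in seq_len(k)) {
      blobs[[length(blobs) + 1L]] <- list(
        class = cl,
        cy = stats::runif(1, 1, config$height),
        cx = stats::runif(1, 1, config$width),
        ry = stats::runif(1, config$blob_radius_range[1L], config$blob_radius_range[2L]),
        rx = stats::runif(1, config$blob_radius_range[1L], config$blob_radius_range[2L]))
    }
  }
  if (length(blobs) > 1L) blobs <- blobs[sample(length(blobs))]  # random z-order
  blobs
}

paint_blob <- function(m, blob) {
  h <- nrow(m); w <- ncol(m)
  r0 <- max(1L, floor(blob$cy - blob$ry)); r1 <- min(h, ceiling(blob$cy + blob$ry))
  c0 <- max(1L, floor(blob$cx - blob$rx)); c1 <- min(w, ceiling(blob$cx + blob$rx))
  if (r0 > r1 || c0 > c1) return(m)
  rr <- r0:r1; cc <- c0:c1
  dy <- (rr - blob$cy) / blob$ry
  dx <- (cc - blob$cx) / blob$rx
  inside <- outer(dy^2, dx^2, `+`) <= 1
  sub <- m[rr, cc, drop = FALSE]
  sub[inside] <- blob$class
  m[rr, cc] <- sub
  m
}

#' Generate one synthetic scene
#'
#' Paints elliptical regions of each non-background class in a random
#' z-order (later blobs overwrite earlier ones), then renders the image as
#' per-class mean colors plus Gaussian noise clipped to `[0, 1]`. The whole
#' scene is a pure function of the config (including its seed).
#'
#' @param config A [scene_config()].
#' @return List with `image` ([image_patch()]) and `mask` ([label_mask()]).
#' @export
generate_scene <- function(config) {
  with_seed(config$seed, {
    m <- matrix(0L, config$height, config$width)
    for (blob in draw_blobs(config)) m <- paint_blob(m, blob)
    means <- config$class_palette$means
    sds <- config$class_palette$sds
    px <- array(0, c(config$height, config$width, 3L))
    for (ch in 1:3) {
      base <- matrix(means[m + 1L, ch], config$height, config$width)
      sd_m <- matrix(sds[m + 1L, ch], config$height, config$width)
      px[, , ch] <- pmin(pmax(base + stats::rnorm(length(m)) * sd_m, 0), 1)
    }
    list(image = image_patch(px, source_id = sprintf("scene-%d", config$seed)),
         mask = label_mask(m, n_classes = config$n_classes))
  })
}

#' Generate a labeled/unlabeled synthetic dataset
#'
#' Draws `n_labeled` (image, mask) pairs and `n_unlabeled` images from the
#' same scene distribution. Per-item seeds are derived from the config seed
#' by a counter scheme, so the i-th item is reproducible independently of
#' the rest.
#'
#' @param config A [scene_config()]; its `seed` acts as the master seed.
#' @param n_labeled,n_unlabeled Item counts (>= 0).
#' @return List with `labeled` (list of `list(image, mask)`) and
#'   `unlabeled` (list of [image_patch()]).
#' @export
generate_dataset <- function(config, n_labeled, n_unlabeled) {
  stopifnot(n_labeled >= 0L, n_unlabeled >= 0L)
  item <- function(counter) {
    cfg <- config
    cfg$seed <- derive_seed(config$seed, counter)
    generate_scene(cfg)
  }
  labeled <- lapply(seq_len(n_labeled), item)
  unlabeled <- lapply(seq_len(n_unlabeled) + n_labeled,
                      function(i) item(i)$image)
  list(labeled = labeled, unlabeled = unlabeled)
}

#' Generate a binary fluorescence mask over a label mask
#'
#' Emulates an immunofluorescence channel (e.g. an anti-PD-1 stain) that is
#' expressed regionwise: every 4-connected region of `target_class` turns
#' positive with probability `positivity_rate`, regions of other
#' non-background classes with probability `off_target_rate`, and background
#' never.
#'
#' @param mask A [label_mask()].
#' @param target_class Class id the stain targets (default: TIL = 2).
#' @param positivity_rate,off_target_rate Probabilities in `[0, 1]`.
#' @param seed Integer seed.
#' @return Binary `(H, W)` matrix (1 = positive).
#' @export
generate_fluorescence_mask <- function(mask, target_class = tme_classes()[["til"]],
                                       positivity_rate = 0.6,
                                       off_target_rate = 0.05, seed = 1L) {
  stopifnot(positivity_rate >= 0, positivity_rate <= 1,
            off_target_rate >= 0, off_target_rate <= 1)
  m <- mask_labels(mask)
  C <- mask_classes(mask)
  if (target_class < 1L || target_class >= C)
    stop("unknown (or background) target_class")
  out <- matrix(0L, nrow(m), ncol(m))
  with_seed(seed, {
    for (cl in seq_len(C - 1L)) {
      comp <- label_components_cpp(m == cl)
      ncomp <- max(comp)
      if (ncomp == 0L) next
      rate <- if (cl == target_class) positivity_rate else off_target_rate
      on <- stats::runif(ncomp) < rate
      if (any(on)) out[comp > 0 & on[pmax(comp, 1L)]] <- 1L
    }
  })
  out
}

# --- mutation label planting ----------------------------------------------

#' Patch statistics available to mutation label rules
#'
#' @return Character vector of statistic names usable in [mutation_rule()].
#' @export
patch_statistics <- function() {
  c("background_fraction", "panck_fraction", "til_fraction", "dapi_fraction",
    "mean_red", "mean_green", "mean_blue", "mean_intensity")
}

compute_patch_statistic <- function(stat, patch, mask) {
  px <- patch_pixels(patch)
  m <- mask_labels(mask)
  switch(stat,
    background_fraction = mean(m == 0L),
    panck_fraction = mean(m == 1L),
    til_fraction = mean(m == 2L),
    dapi_fraction = mean(m == 3L),
    mean_red = mean(px[, , 1L]),
    mean_green = mean(px[, , 2L]),
    mean_blue = mean(px[, , 3L]),
    mean_intensity = mean(px),
    stop(sprintf("unknown patch statistic '%s'", stat)))
}

#' A thresholded patch-statistic rule for one mutation label
#'
#' @param stat One of [patch_statistics()].
#' @param op Comparison, `">"` or `"<"` (strict).
#' @param threshold Numeric cutoff.
#' @return A `tmeseg_rule` list.
#' @export
mutation_rule <- function(stat, op = ">", threshold = 0.2) {
  if (!stat %in% patch_statistics())
    stop(sprintf("rule references unavailable statistic '%s'", stat))
  if (!op %in% c(">", "<")) stop("op must be '>' or '<'")
  structure(list(stat = stat, op = op, threshold = threshold),
            class = "tmeseg_rule")
}

apply_rule <- function(rule, patch, mask) {
  v <- compute_patch_statistic(rule$stat, patch, mask)
  as.integer(if (rule$op == ">") v > rule$threshold else v < rule$threshold)
}

#' Configuration for planting mutation labels
#'
#' Each of the three gene labels (APC, TP53, KRAS) is a deterministic
#' thresholded patch statistic, optionally corrupted by independent flip
#' noise. With `flip_noise = 0` the labels are an exact function of each
#' patch, so a classifier can in principle reach perfect ranking.
#'
#' @param n_patches Number of patches to generate.
#' @param label_rules Named list of three [mutation_rule()]s
#'   (APC, TP53, KRAS). Defaults tie APC to tumor area, TP53 to TIL area,
#'   and KRAS to nuclear area, with thresholds near the median of each
#'   statistic under the default scene geometry so both label polarities
#'   occur at realistic rates.
#' @param flip_noise Per-label flip probability in `[0, 0.5)`.
#' @param seed Integer master seed.
#' @return A `tmeseg_plant_config` list.
#' @export
mutation_plant_config <- function(n_patches = 100L,
                                  label_rules = list(
                                    APC = mutation_rule("panck_fraction", ">", 0.13),
                                    TP53 = mutation_rule("til_fraction", ">", 0.14),
                                    KRAS = mutation_rule("dapi_fraction", ">", 0.13)),
                                  flip_noise = 0.05, seed = 1L) {
  stopifnot(n_patches >= 1L, length(label_rules) == 3L)
  if (flip_noise < 0 || flip_noise >= 0.5)
    stop("flip_noise must lie in [0, 0.5)")
  for (r in label_rules) if (!inherits(r, "tmeseg_rule"))
    stop("label_rules must be built with mutation_rule()")
  structure(list(n_patches = as.integer(n_patches), label_rules = label_rules,
                 flip_noise = flip_noise, seed = as.integer(seed)),
            class = "tmeseg_plant_config")
}

#' Generate a mutation-labeled patch dataset
#'
#' Draws scenes from `scene_cfg` (per-item counter-derived seeds), computes
#' each label by its planted rule, and flips each label independently with
#' probability `flip_noise`.
#'
#' @param scene_cfg A [scene_config()].
#' @param plant_cfg A [mutation_plant_config()].
#' @return List with `patches`, `masks`, and a `labels` data frame
#'   (`patch_id`, one binary column per gene).
#' @export
generate_mutation_dataset <- function(scene_cfg, plant_cfg) {
  n <- plant_cfg$n_patches
  genes <- names(plant_cfg$label_rules)
  patches <- vector("list", n)
  masks <- vector("list", n)
  lab <- matrix(0L, n, 3L, dimnames = list(NULL, genes))
  for (i in seq_len(n)) {
    cfg <- scene_cfg
    cfg$seed <- derive_seed(plant_cfg$seed, i)
    sc <- generate_scene(cfg)
    patches[[i]] <- sc$image
    masks[[i]] <- sc$mask
    for (g in seq_along(genes))
      lab[i, g] <- apply_rule(plant_cfg$label_rules[[g]], sc$image, sc$mask)
  }
  if (plant_cfg$flip_noise > 0) {
    flips <- with_seed(derive_seed(plant_cfg$seed, n + 1L),
                       matrix(stats::runif(n * 3L) < plant_cfg$flip_noise, n, 3L))
    lab[flips] <- 1L - lab[flips]
  }
  labels <- data.frame(patch_id = sprintf("patch-%04d", seq_len(n)), lab)
  list(patches = patches, masks = masks, labels = labels)
}
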