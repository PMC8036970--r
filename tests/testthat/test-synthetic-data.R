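# Scene generator: determinism, geometry against an independent
# Monte-Carlo oracle, fluorescence region statistics, planted labels.

test_that("scene config validates geometry and palette separation", {
  expect_error(scene_config(height = 0), "dimensions")
  pal <- default_palette()
  expect_error(scene_config(class_palette = list(means = pal$means[1:3, ],
                                                 sds = pal$sds[1:3, ])),
               "n_classes")
  close_pal <- pal
  close_pal$means[2, ] <- close_pal$means[1, ] + 0.01
  expect_error(scene_config(class_palette = close_pal), "noise_sigma")
  expect_error(scene_config(blob_radius_range = c(5, 2)), "radius")
})

test_that("no blobs means an all-background mask; same seed is bit-identical", {
  cfg <- scene_config(blob_count_range = c(0L, 0L), seed = 7L)
  sc <- generate_scene(cfg)
  expect_true(all(sc$mask$labels == 0L))
  cfg2 <- tiny_scene_config(seed = 123)
  a <- generate_scene(cfg2)
  b <- generate_scene(cfg2)
  expect_identical(a$image$pixels, b$image$pixels)
  expect_identical(a$mask$labels, b$mask$labels)
  # generators restore the caller's RNG stream
  set.seed(99); before <- runif(5)
  set.seed(99); invisible(generate_scene(cfg2)); after <- runif(5)
  expect_identical(before, after)
})

test_that("TIL pixel frequency matches a geometric Monte-Carlo oracle", {
  # Oracle: re-simulate the blob model without rasterizing — sample counts,
  # centers, radii and a random z-order, then classify a fixed subsample of
  # pixel centers by the last covering ellipse.
  cfg <- tiny_scene_config(seed = 1000)
  oracle_til_fraction <- function(cfg, n_scenes = 1000, n_pix = 64, seed = 4321) {
    set.seed(seed)
    px_h <- runif(n_pix, 1, cfg$height)
    px_w <- runif(n_pix, 1, cfg$width)
    til_hits <- 0; total <- 0
    for (s in seq_len(n_scenes)) {
      cls <- c(); cy <- c(); cx <- c(); ry <- c(); rx <- c()
      for (cl in 1:(cfg$n_classes - 1)) {
        k <- sample(cfg$blob_count_range[1]:cfg$blob_count_range[2], 1)
        if (k > 0) for (i in 1:k) {
          cls <- c(cls, cl)
          cy <- c(cy, runif(1, 1, cfg$height)); cx <- c(cx, runif(1, 1, cfg$width))
          ry <- c(ry, runif(1, cfg$blob_radius_range[1], cfg$blob_radius_range[2]))
          rx <- c(rx, runif(1, cfg$blob_radius_range[1], cfg$blob_radius_range[2]))
        }
      }
      ord <- sample(length(cls))
      for (p in seq_len(n_pix)) {
        final <- 0L
        for (b in ord)
          if (((px_h[p] - cy[b]) / ry[b])^2 + ((px_w[p] - cx[b]) / rx[b])^2 <= 1)
            final <- cls[b]
        if (final == 2L) til_hits <- til_hits + 1
        total <- total + 1
      }
    }
    til_hits / total
  }
  expected <- oracle_til_fraction(cfg)
  emp <- mean(vapply(seq_len(1000), function(i) {
    c2 <- cfg; c2$seed <- i
    mean(generate_scene(c2)$mask$labels == 2L)
  }, 0))
  expect_equal(emp, expected, tolerance = 0.2)
})

test_that("dataset generation honors counts and per-item determinism", {
  cfg <- tiny_scene_config(seed = 5)
  d0 <- generate_dataset(cfg, 0, 5)
  expect_length(d0$labeled, 0)
  expect_length(d0$unlabeled, 5)
  d1 <- generate_dataset(cfg, 8, 0)
  expect_length(d1$labeled, 8)
  expect_length(d1$unlabeled, 0)
  d2 <- generate_dataset(cfg, 8, 0)
  for (i in c(1, 4, 8))
    expect_identical(d1$labeled[[i]]$image$pixels, d2$labeled[[i]]$image$pixels)
  # different items differ
  expect_false(identical(d1$labeled[[1]]$mask$labels, d1$labeled[[2]]$mask$labels))
})

test_that("palette classification recovers masks at default noise", {
  # separability guarantee: nearest palette color recovers >= 95% of labels
  cfg <- tiny_scene_config(seed = 31)
  means <- cfg$class_palette$means
  hits <- 0; total <- 0
  for (s in 1:5) {
    c2 <- cfg; c2$seed <- s
    sc <- generate_scene(c2)
    px <- sc$image$pixels
    d2 <- sapply(seq_len(nrow(means)), function(ci) {
      (px[, , 1] - means[ci, 1])^2 + (px[, , 2] - means[ci, 2])^2 +
        (px[, , 3] - means[ci, 3])^2
    })
    pred <- max.col(-d2, ties.method = "first") - 1L
    hits <- hits + sum(pred == as.vector(sc$mask$labels))
    total <- total + length(pred)
  }
  expect_gte(hits / total, 0.95)
})

test_that("fluorescence masks: degenerate rates, subset property, region CI", {
  cfg <- tiny_scene_config(seed = 61)
  sc <- generate_scene(cfg)
  z <- generate_fluorescence_mask(sc$mask, positivity_rate = 0,
                                  off_target_rate = 0, seed = 1)
  expect_true(all(z == 0))
  full <- generate_fluorescence_mask(sc$mask, positivity_rate = 1,
                                     off_target_rate = 0, seed = 1)
  expect_identical(full == 1L, unname(sc$mask$labels == 2L))
  expect_error(generate_fluorescence_mask(sc$mask, target_class = 0L), "target")
  # subset invariant: positives never on background
  r <- generate_fluorescence_mask(sc$mask, positivity_rate = 0.7,
                                  off_target_rate = 0.3, seed = 9)
  expect_true(all(sc$mask$labels[r == 1L] != 0L))
  # region-level rate: isolated square regions, rate 0.5, 200 regions
  blocks <- matrix(0L, 8, 8)
  blocks[3:4, 3:4] <- 2L; blocks[7:8, 7:8] <- 2L      # two separated regions
  bm <- label_mask(blocks, 4L)
  pos <- 0
  for (s in 1:100) {                                   # 200 regions total
    fm <- generate_fluorescence_mask(bm, positivity_rate = 0.5,
                                     off_target_rate = 0, seed = s)
    pos <- pos + (fm[3, 3] == 1L) + (fm[7, 7] == 1L)
  }
  ci_half <- 2.576 * sqrt(0.25 / 200)                  # binomial 99% CI
  expect_lt(abs(pos / 200 - 0.5), ci_half + 1e-9)
})

test_that("planted mutation labels are exact at zero flip noise", {
  cfg <- tiny_scene_config(seed = 71)
  pc <- mutation_plant_config(n_patches = 30, flip_noise = 0, seed = 3)
  ds <- generate_mutation_dataset(cfg, pc)
  expect_equal(nrow(ds$labels), 30)
  ns <- asNamespace("tmeseg")
  for (i in seq_len(30)) for (g in seq_along(pc$label_rules)) {
    expect_equal(ds$labels[i, names(pc$label_rules)[g]],
                 ns$apply_rule(pc$label_rules[[g]], ds$patches[[i]],
                               ds$masks[[i]]))
  }
  # all-background scene: every default rule (fractions of painted classes) is 0
  cfg0 <- scene_config(blob_count_range = c(0L, 0L), seed = 8)
  ds0 <- generate_mutation_dataset(cfg0, mutation_plant_config(n_patches = 2,
                                                               flip_noise = 0))
  expect_true(all(ds0$labels[, c("APC", "TP53", "KRAS")] == 0L))
  expect_error(mutation_rule("not_a_stat"), "unavailable")
})

test_that("flip noise corrupts labels at the configured binomial rate", {
  cfg <- tiny_scene_config(seed = 81)
  pc0 <- mutation_plant_config(n_patches = 500, flip_noise = 0, seed = 13)
  pc1 <- mutation_plant_config(n_patches = 500, flip_noise = 0.1, seed = 13)
  clean <- generate_mutation_dataset(cfg, pc0)$labels
  noisy <- generate_mutation_dataset(cfg, pc1)$labels
  genes <- c("APC", "TP53", "KRAS")
  dis <- mean(as.matrix(clean[genes]) != as.matrix(noisy[genes]))
  n <- 500 * 3
  ci_half <- 2.576 * sqrt(0.1 * 0.9 / n)
  expect_lt(abs(dis - 0.1), ci_half + 1e-9)
})
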