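# Training loop mechanics at very small step counts. The scaled-down
# learning benchmarks live in the acceptance suite.

small_labeled <- function(n, seed = 70) {
  generate_dataset(tiny_scene_config(seed = seed), n, 0)$labeled
}

test_that("schedules validate and scale proportionally", {
  s <- semisup_schedule(scale = 0.001)
  expect_equal(s$generator_warmup_steps, 10L)
  expect_equal(s$joint_steps, 300L)
  expect_equal(s$semi_activation_step, 100L)
  expect_error(semisup_schedule(semi_activation_step = 1e6), "exceeds")
  expect_error(tgmdn_schedule(epochs = 0), "epochs")
  # published defaults survive in the unscaled schedule
  expect_equal(semisup_schedule()$generator_warmup_steps, 10000L)
  expect_equal(semisup_schedule()$lr_generator, 1e-3)
  expect_equal(semisup_schedule()$lr_discriminator, 1e-6)
  expect_equal(semisup_schedule()$weights$lambda_semi, 0.1)
  expect_equal(tgmdn_schedule()$epochs, 100L)
  expect_equal(tgmdn_schedule()$batch_size, 16L)
})

test_that("zero training steps leave parameters unchanged", {
  ns <- asNamespace("tmeseg")
  gen <- build_generator(tiny_gen_config(), seed = 31)
  before <- ns$nn_get_params(gen$modules)
  r <- train_supervised(gen, small_labeled(4), semisup_schedule(seed = 1),
                        steps = 0)
  expect_identical(ns$nn_get_params(r$generator$modules), before)
  expect_equal(nrow(r$history), 0)
  expect_error(train_supervised(gen, list(), semisup_schedule()), "empty")
})

test_that("training is bit-reproducible for a fixed seed", {
  ns <- asNamespace("tmeseg")
  lab <- small_labeled(6)
  run <- function() {
    gen <- build_generator(tiny_gen_config(), seed = 32)
    train_supervised(gen, lab, semisup_schedule(seed = 5), steps = 4)
  }
  r1 <- run(); r2 <- run()
  expect_identical(ns$nn_get_params(r1$generator$modules),
                   ns$nn_get_params(r2$generator$modules))
  expect_identical(r1$history, r2$history)
})

test_that("zero-weight semi-supervised training reduces to supervised training", {
  ns <- asNamespace("tmeseg")
  lab <- small_labeled(6)
  unl <- generate_dataset(tiny_scene_config(seed = 71), 0, 6)$unlabeled
  w0 <- loss_weights(0, 0, 0, 0.5)
  sch <- semisup_schedule(generator_warmup_steps = 3, joint_steps = 4,
                          semi_activation_step = 2, weights = w0,
                          batch_size = 4, seed = 8)
  gen_a <- build_generator(tiny_gen_config(), seed = 33)
  disc <- build_discriminator(4, 0.125, seed = 34)
  ra <- train_semi_supervised(gen_a, disc, lab, unl, sch)
  gen_b <- build_generator(tiny_gen_config(), seed = 33)
  rb <- train_supervised(gen_b, lab, sch, steps = 7)
  expect_equal(ns$nn_get_params(ra$generator$modules),
               ns$nn_get_params(rb$generator$modules), tolerance = 1e-14)
  expect_equal(ra$history$lce, rb$history$lce, tolerance = 1e-12)
})

test_that("history exposes the phase schedule and gates the semi loss", {
  lab <- small_labeled(5)
  unl <- generate_dataset(tiny_scene_config(seed = 72), 0, 8)$unlabeled
  gen <- build_generator(tiny_gen_config(), seed = 35)
  disc <- build_discriminator(4, 0.125, seed = 36)
  sch <- semisup_schedule(generator_warmup_steps = 2, joint_steps = 6,
                          semi_activation_step = 5, batch_size = 2, seed = 9)
  r <- train_semi_supervised(gen, disc, lab, unl, sch)
  h <- r$history
  expect_equal(h$phase, c(rep("warmup", 2), rep("joint", 6)))
  expect_true(all(h$lsemi[h$step < 5] == 0))
  expect_true(all(h$kind[h$step >= 5] == "labeled+unlabeled"))
  expect_true(all(is.na(h$ld[h$phase == "warmup"])))
  expect_true(all(is.finite(h$ld[h$phase == "joint"])))
  expect_true(all(is.finite(h$lce)))
})

test_that("mutation training loss decreases and is reproducible", {
  ns <- asNamespace("tmeseg")
  ds <- generate_mutation_dataset(tiny_scene_config(seed = 73),
                                  mutation_plant_config(n_patches = 24,
                                                        flip_noise = 0,
                                                        seed = 2))
  run <- function() {
    tg <- build_tgmdn(tgmdn_config(0.125), seed = 37)
    train_tgmdn(tg, ds, tgmdn_schedule(epochs = 5, batch_size = 8, seed = 11))
  }
  r1 <- run()
  expect_equal(nrow(r1$history), 5)
  expect_lt(r1$history$loss[5], r1$history$loss[1])
  r2 <- run()
  expect_identical(ns$nn_get_params(r1$classifier$modules),
                   ns$nn_get_params(r2$classifier$modules))
  # single-polarity labels warn
  ds1 <- ds
  ds1$labels$APC <- 1L
  tg <- build_tgmdn(tgmdn_config(0.125), seed = 38)
  expect_warning(train_tgmdn(tg, ds1, tgmdn_schedule(epochs = 1, seed = 1)),
                 "polarity")
})

test_that("segmentation evaluation agrees with an oracle generator", {
  pairs <- small_labeled(3)
  # oracle: predicts the exact one-hot of the ground truth
  oracle <- new.env()
  oracle$config <- list(n_classes = 4L)
  oracle$predict <- function(patches, batch_size = 8L) {
    lapply(seq_along(patches), function(i)
      unclass(one_hot_encode(pairs[[i]]$mask)))
  }
  rep <- evaluate_segmentation(oracle, pairs)
  expect_equal(rep$accuracy, 1)
  expect_equal(rep$dice, 1)
  # constant-background predictor: accuracy equals background fraction
  bg <- new.env()
  bg$config <- list(n_classes = 4L)
  bg$predict <- function(patches, batch_size = 8L) {
    lapply(patches, function(p) {
      S <- array(0, c(64, 64, 4)); S[, , 1] <- 1; S
    })
  }
  rep2 <- evaluate_segmentation(bg, pairs)
  bgfrac <- mean(vapply(pairs, function(p) mean(p$mask$labels == 0L), 0))
  expect_equal(rep2$accuracy, bgfrac, tolerance = 1e-12)
  # per-patch mode returns the same perfect scores for the oracle
  expect_equal(evaluate_segmentation(oracle, pairs, mode = "per_patch")$dice, 1)
})

test_that("mutation evaluation delegates to the rank AUC and flags undefined", {
  ds <- generate_mutation_dataset(tiny_scene_config(seed = 74),
                                  mutation_plant_config(n_patches = 16,
                                                        flip_noise = 0,
                                                        seed = 4))
  # oracle classifier: scores equal the labels
  oracle <- new.env()
  oracle$predict <- function(patches, batch_size = 16L) {
    as.matrix(ds$labels[, c("APC", "TP53", "KRAS")]) * 0.8 + 0.1
  }
  ev <- evaluate_mutations(oracle, ds$patches, ds$labels)
  for (g in names(ev)) {
    if (ev[[g]]$defined) expect_equal(ev[[g]]$auc, 1)
  }
  # degenerate labels are flagged, not errored
  labs <- ds$labels
  labs$APC <- 1L
  ev2 <- evaluate_mutations(oracle, ds$patches, labs)
  expect_false(ev2$APC$defined)
  expect_true(is.na(ev2$APC$auc))
})
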