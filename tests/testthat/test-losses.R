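# Loss definitions against closed forms and independent scalar-loop oracles.

test_that("cross-entropy hits closed-form spot values", {
  # perfect one-hot prediction -> 0
  Y <- one_hot_encode(label_mask(matrix(c(0L, 1L, 2L, 3L), 2, 2)))
  expect_equal(cross_entropy_loss(unclass(Y), unclass(Y)), 0)
  # uniform prediction over 4 classes on one pixel -> ln 4
  S <- array(0.25, c(1, 1, 4))
  Y1 <- array(c(0, 1, 0, 0), c(1, 1, 4))
  expect_equal(cross_entropy_loss(S, Y1), log(4), tolerance = 1e-12)
})

test_that("cross-entropy matches the scalar-loop oracle on random tensors", {
  set.seed(31)
  for (i in 1:25) {
    S <- random_prob_map(4, 4, 3)
    Y <- unclass(one_hot_encode(random_mask(4, 4, 3), 3L))
    expect_equal(cross_entropy_loss(S, Y), oracle_cross_entropy(S, Y),
                 tolerance = 1e-6)
  }
  expect_error(cross_entropy_loss(random_prob_map(4, 4, 3),
                                  array(0, c(4, 5, 3))), "shape")
})

test_that("adversarial loss: fooled discriminator gives 0, else matches oracle", {
  expect_equal(adversarial_loss(matrix(1, 3, 3)), 0)
  expect_equal(adversarial_loss(matrix(0.5, 1, 1)), -log(0.5), tolerance = 1e-12)
  set.seed(32)
  for (i in 1:25) {
    D <- matrix(runif(20, 0.01, 1), 4, 5)
    expect_equal(adversarial_loss(D), oracle_adversarial(D), tolerance = 1e-6)
  }
})

test_that("semi-supervised loss gates on the confidence threshold", {
  S <- array(c(0.7, 0.1, 0.1, 0.1), c(1, 1, 4))
  # nothing trustworthy
  expect_equal(semi_supervised_loss(S, matrix(0.5, 1, 1), t_semi = 0.5), 0)
  expect_equal(semi_supervised_loss(S, matrix(0.2, 1, 1), t_semi = 0.5), 0)
  # fully trustworthy single pixel -> -log(max prob)
  expect_equal(semi_supervised_loss(S, matrix(1, 1, 1), t_semi = 0.5),
               -log(0.7), tolerance = 1e-12)
})

test_that("semi-supervised loss matches the indicator loop oracle", {
  set.seed(33)
  for (i in 1:25) {
    S <- random_prob_map(4, 4, 4)
    D <- matrix(runif(16), 4, 4)
    t <- runif(1)
    expect_equal(semi_supervised_loss(S, D, t), oracle_semi(S, D, t),
                 tolerance = 1e-6)
  }
})

test_that("semi-supervised loss is monotone non-increasing in the threshold", {
  set.seed(34)
  S <- random_prob_map(6, 6, 4)
  D <- matrix(runif(36), 6, 6)
  vals <- vapply(seq(0, 1, by = 0.1),
                 function(t) semi_supervised_loss(S, D, t), 0)
  expect_true(all(diff(vals) <= 1e-12))
})

test_that("with full confidence the semi loss equals CE against argmax labels", {
  set.seed(35)
  S <- random_prob_map(5, 5, 4)
  pseudo <- unclass(one_hot_encode(compress_to_labels(S), 4L))
  expect_equal(semi_supervised_loss(S, matrix(1, 5, 5), t_semi = 0.5),
               cross_entropy_loss(S, pseudo), tolerance = 1e-10)
})

test_that("discriminator loss: perfect discrimination gives 0, else oracle", {
  expect_equal(discriminator_loss(matrix(0, 2, 2), matrix(1, 2, 2)), 0,
               tolerance = 1e-6)
  expect_equal(discriminator_loss(matrix(0.5, 1, 1), matrix(0.5, 1, 1)),
               -2 * log(0.5), tolerance = 1e-12)
  set.seed(36)
  for (i in 1:25) {
    a <- matrix(runif(12, 0.01, 0.99), 3, 4)
    b <- matrix(runif(12, 0.01, 0.99), 3, 4)
    expect_equal(discriminator_loss(a, b), oracle_discriminator(a, b),
                 tolerance = 1e-6)
  }
})

test_that("multilabel BCE: exact match gives 0, 0.5 gives log 2, else oracle", {
  expect_equal(multilabel_bce(c(1, 0, 1), c(1, 0, 1)), 0, tolerance = 1e-6)
  expect_equal(multilabel_bce(rep(0.5, 3), c(1, 0, 1)), log(2),
               tolerance = 1e-12)
  set.seed(37)
  for (i in 1:25) {
    p <- runif(3); y <- rbinom(3, 1, 0.5)
    expect_equal(multilabel_bce(p, y), oracle_multilabel_bce(p, y),
                 tolerance = 1e-6)
  }
})

test_that("generator total loss combines terms by batch kind", {
  w0 <- loss_weights(0, 0, 0, 0.5)
  expect_equal(generator_total_loss(2.5, 9, 9, w0, labeled = TRUE), 2.5)
  expect_equal(generator_total_loss(2.5, 9, 9, w0, labeled = FALSE), 0)
  w <- loss_weights()   # published defaults: 0.01 / 0.001 / 0.1
  expect_equal(generator_total_loss(1, 2, 3, w, labeled = TRUE),
               1 + 0.01 * 2)
  expect_equal(generator_total_loss(1, 2, 3, w, labeled = FALSE),
               0.001 * 2 + 0.1 * 3)
  expect_equal(generator_total_loss(1, 2, 3, w, labeled = TRUE,
                                    semi_on_labeled = TRUE),
               1 + 0.01 * 2 + 0.1 * 3)
  # linearity in each component (finite-difference style)
  base <- generator_total_loss(1, 2, 3, w, labeled = FALSE)
  up <- generator_total_loss(1, 2 + 1, 3, w, labeled = FALSE)
  expect_equal(up - base, w$lambda_adv_unlabeled, tolerance = 1e-12)
  up2 <- generator_total_loss(1, 2, 3 + 1, w, labeled = FALSE)
  expect_equal(up2 - base, w$lambda_semi, tolerance = 1e-12)
})

test_that("losses stay finite and non-negative on clamped degenerate inputs", {
  S <- array(0, c(2, 2, 4)); S[, , 1] <- 1
  Y <- array(0, c(2, 2, 4)); Y[, , 2] <- 1      # fully wrong prediction
  expect_true(is.finite(cross_entropy_loss(S, Y)))
  expect_gte(cross_entropy_loss(S, Y), 0)
  expect_true(is.finite(adversarial_loss(matrix(0, 3, 3))))
  expect_true(is.finite(discriminator_loss(matrix(1, 2, 2), matrix(0, 2, 2))))
})

test_that("analytic loss gradients match central finite differences", {
  set.seed(38)
  ns <- asNamespace("tmeseg")
  fd <- function(f, x, g, k, eps = 1e-6) {
    xp <- x; xm <- x
    xp[k] <- xp[k] + eps; xm[k] <- xm[k] - eps
    num <- (f(xp) - f(xm)) / (2 * eps)
    abs(num - g[k]) / max(abs(num), 1e-8)
  }
  S <- random_prob_map(3, 3, 4) * 0.9 + 0.025      # keep away from the clamp
  Y <- unclass(one_hot_encode(random_mask(3, 3, 4), 4L))
  g <- ns$cross_entropy_grad(S, Y)
  for (k in sample(length(S), 5))
    expect_lt(fd(function(s) cross_entropy_loss(s, Y), S, g, k), 1e-4)
  D <- matrix(runif(9, 0.1, 0.9), 3, 3)
  g <- ns$adversarial_grad(D)
  for (k in sample(length(D), 4))
    expect_lt(fd(adversarial_loss, D, g, k), 1e-4)
  gd <- ns$discriminator_grad(D, D)
  for (k in sample(length(D), 4)) {
    expect_lt(fd(function(a) discriminator_loss(a, D), D, gd$d_on_s, k), 1e-4)
    expect_lt(fd(function(b) discriminator_loss(D, b), D, gd$d_on_y, k), 1e-4)
  }
  p <- runif(3, 0.1, 0.9); y <- c(1, 0, 1)
  g <- ns$multilabel_bce_grad(p, y)
  for (k in 1:3)
    expect_lt(fd(function(q) multilabel_bce(q, y), p, g, k), 1e-4)
  # semi grad (pseudo-labels and mask held fixed, as in training)
  Dc <- matrix(runif(9), 3, 3)
  g <- ns$semi_supervised_grad(S, Dc, 0.5)
  masked <- ns$semi_masked_pseudo(S, Dc, 0.5)
  for (k in sample(length(S), 4)) {
    f <- function(s) -sum(masked * log(pmax(s, 1e-8)))
    expect_lt(fd(f, S, g, k), 1e-4)
  }
})
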