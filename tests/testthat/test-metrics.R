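# Metric stack against hand enumerations and independent oracles.

test_that("argmax compression handles one-hot, ties, and random maps", {
  m <- random_mask(5, 5, 4, seed = 41)
  S <- unclass(one_hot_encode(m))
  expect_equal(compress_to_labels(S)$labels, m$labels)
  # uniform map -> all class 0 by the lowest-index tie rule
  expect_true(all(compress_to_labels(array(0.25, c(3, 3, 4)))$labels == 0L))
  set.seed(42)
  for (i in 1:20) {
    S <- random_prob_map(4, 4, 4)
    expect_equal(compress_to_labels(S)$labels, oracle_argmax_labels(S))
  }
})

test_that("confusion counts match hand enumeration and conserve pixels", {
  pred <- label_mask(matrix(c(0L, 2L, 1L, 3L), 2, 2))   # col-major: (0,2;1,3)
  truth <- label_mask(matrix(c(0L, 3L, 1L, 2L), 2, 2))
  cc <- confusion_counts(pred, truth)
  expect_equal(cc$tp, c(1, 1, 0, 0))
  expect_equal(cc$fp[3], 1)   # class 2 predicted where truth is 3
  expect_equal(cc$fn[3], 1)   # class 2 in truth predicted as 3
  expect_true(all(cc$tp + cc$fp + cc$tn + cc$fn == 4))
  expect_equal(sum(cc$tp), sum(pred$labels == truth$labels))
  expect_error(confusion_counts(pred, random_mask(3, 3, 4)), "shape")
})

test_that("confusion counts agree with the loop oracle on random masks", {
  set.seed(43)
  for (i in 1:10) {
    p <- random_mask(6, 6, 4)
    t <- random_mask(6, 6, 4)
    cc <- confusion_counts(p, t)
    oc <- oracle_confusion(as.vector(p$labels), as.vector(t$labels), 4)
    expect_equal(cc[c("tp", "fp", "tn", "fn")], oc)
  }
})

test_that("macro IoU/Dice: perfect, disjoint, and the algebraic identity", {
  m <- random_mask(8, 8, 4, seed = 44)
  cc <- confusion_counts(m, m)
  expect_equal(macro_iou(cc), 1)
  expect_equal(macro_dice(cc), 1)
  # completely disjoint single-class prediction vs truth
  cc2 <- confusion_counts(label_mask(matrix(1L, 4, 4)),
                          label_mask(matrix(2L, 4, 4)))
  expect_equal(macro_iou(cc2), 0)
  expect_equal(macro_dice(cc2), 0)
  ns <- asNamespace("tmeseg")
  set.seed(45)
  for (i in 1:100) {
    cc <- confusion_counts(random_mask(6, 6, 4), random_mask(6, 6, 4))
    iou_c <- ns$per_class_iou(cc)
    dice_c <- ns$per_class_dice(cc)
    expect_equal(dice_c, 2 * iou_c / (1 + iou_c), tolerance = 1e-12)
    expect_gte(macro_dice(cc), macro_iou(cc))
  }
})

test_that("macro precision/recall match hand computation and loop oracle", {
  m <- random_mask(8, 8, 4, seed = 46)
  cc <- confusion_counts(m, m)
  expect_equal(macro_precision(cc), 1)
  expect_equal(macro_recall(cc), 1)
  # all-background prediction against balanced 4-class truth: recall 1/4
  truth <- label_mask(matrix(rep(0:3, each = 4), 4, 4))
  pred <- label_mask(matrix(0L, 4, 4))
  cc2 <- confusion_counts(pred, truth)
  expect_equal(macro_recall(cc2), 0.25)
  set.seed(47)
  for (i in 1:20) {
    p <- random_mask(5, 5, 4); t <- random_mask(5, 5, 4)
    cc <- confusion_counts(p, t)
    oc <- oracle_confusion(as.vector(p$labels), as.vector(t$labels), 4)
    prec <- mean(ifelse(oc$tp + oc$fp > 0, oc$tp / (oc$tp + oc$fp), 0))
    rec <- mean(ifelse(oc$tp + oc$fn > 0, oc$tp / (oc$tp + oc$fn), 0))
    # all 4 classes virtually always present at 5x5; guard the rare miss
    if (all(oc$tp + oc$fp + oc$fn > 0)) {
      expect_equal(macro_precision(cc), prec, tolerance = 1e-9)
      expect_equal(macro_recall(cc), rec, tolerance = 1e-9)
    }
  }
})

test_that("empty classes are excluded from the macro average", {
  # only classes 0 and 1 occur; classes 2/3 must not enter the average
  pred <- label_mask(matrix(c(0L, 0L, 1L, 1L), 2, 2), n_classes = 4L)
  truth <- label_mask(matrix(c(0L, 1L, 1L, 1L), 2, 2), n_classes = 4L)
  cc <- confusion_counts(pred, truth)
  # class 0: tp 1 fp 1 fn 0; class 1: tp 2 fp 0 fn 1
  expect_equal(macro_precision(cc), mean(c(1 / 2, 1)))
  expect_equal(macro_recall(cc), mean(c(1, 2 / 3)))
  expect_equal(macro_iou(cc), mean(c(1 / 2, 2 / 3)))
})

test_that("pixel accuracy equals the TP identity and handles single errors", {
  m <- random_mask(10, 10, 4, seed = 48)
  expect_equal(pixel_accuracy(m, m), 1)
  m2 <- m$labels
  m2[1, 1] <- (m2[1, 1] + 1L) %% 4L
  expect_equal(pixel_accuracy(label_mask(m2), m), 0.99)
  p <- random_mask(7, 9, 4); t <- random_mask(7, 9, 4)
  cc <- confusion_counts(p, t)
  expect_equal(pixel_accuracy(p, t), sum(cc$tp) / cc$total)
})

test_that("metrics are invariant to simultaneous class relabeling", {
  set.seed(49)
  p <- random_mask(8, 8, 4); t <- random_mask(8, 8, 4)
  perm <- sample(0:3)
  pp <- label_mask(matrix(perm[p$labels + 1L], 8, 8))
  tt <- label_mask(matrix(perm[t$labels + 1L], 8, 8))
  cc <- confusion_counts(p, t); cc2 <- confusion_counts(pp, tt)
  expect_equal(macro_iou(cc), macro_iou(cc2))
  expect_equal(macro_dice(cc), macro_dice(cc2))
  expect_equal(pixel_accuracy(p, t), pixel_accuracy(pp, tt))
})

test_that("AUC: separating, null, oracle, tie and monotone-transform cases", {
  expect_equal(roc_auc(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1))$auc, 1)
  set.seed(50)
  big <- roc_auc(runif(4000), rbinom(4000, 1, 0.5))
  expect_equal(big$auc, 0.5, tolerance = 0.05)
  for (i in 1:30) {
    n <- sample(6:15, 1)
    s <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)   # forces ties
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) next
    r <- roc_auc(s, y)
    expect_equal(r$auc, oracle_auc(s, y), tolerance = 1e-12)
    # invariance under strictly monotone transform
    expect_equal(roc_auc(exp(3 * s), y)$auc, r$auc, tolerance = 1e-12)
    expect_true(all(diff(r$roc$fpr) >= 0) && all(diff(r$roc$tpr) >= 0))
  }
  expect_error(roc_auc(c(0.3, 0.6), c(1, 1)), "undefined")
})

test_that("AUC agrees with an independent library implementation", {
  skip_if_not_installed("pROC")
  set.seed(51)
  for (i in 1:5) {
    s <- runif(40); y <- rbinom(40, 1, 0.4)
    if (length(unique(y)) < 2) next
    ref <- suppressMessages(as.numeric(pROC::auc(pROC::roc(
      y, s, quiet = TRUE, levels = c(0, 1), direction = "<"))))
    expect_equal(roc_auc(s, y)$auc, ref, tolerance = 1e-10)
  }
})

test_that("metrics report bundles the five values and prints", {
  m <- random_mask(8, 8, 4, seed = 52)
  rep <- metrics_report(confusion_counts(m, m))
  expect_equal(unclass(rep),
               list(accuracy = 1, precision = 1, recall = 1, dice = 1, iou = 1))
  expect_output(print(rep), "accuracy 1")
})
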