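# Training schedules and loops. The semi-supervised loop follows the
# two-phase published schedule: a generator-only warmup on labeled data,
# then alternating discriminator/generator updates, with self-training on
# unlabeled batches activated only after a fixed step count. Every loop is
# driven by a single seeded RNG stream, so runs are bit-reproducible.

#' Semi-supervised training schedule
#'
#' Defaults are the published configuration (generator warmup 10,000 steps,
#' 300,000 joint steps, self-training activated at step 100,000, batch size
#' 8, Adam with beta1 = 0.9, learning rates 1e-3 / 1e-6 for generator /
#' discriminator, weight decay 1e-8, loss weights via [loss_weights()]).
#' `scale` shrinks all three step counts proportionally, preserving the
#' phase structure, for desk-size runs.
#'
#' @param scale Multiplier applied to the three step counts.
#' @param generator_warmup_steps,joint_steps,semi_activation_step Step
#'   counts (before scaling).
#' @param batch_size Patches per batch.
#' @param lr_generator,lr_discriminator Adam learning rates.
#' @param optimizer_momentum Adam beta1.
#' @param weight_decay Additive L2 coefficient.
#' @param weights A [loss_weights()] bundle.
#' @param loss_reduction `"mean"` (per-pixel, scale-invariant; default) or
#'   `"sum"` (the literal defining form of the losses).
#' @param semi_on_labeled Apply the self-training term to labeled batches
#'   (the literal three-term objective); default `FALSE`.
#' @param seed Integer seed driving batch sampling.
#' @return A `tmeseg_semisup_schedule` list.
#' @export
semisup_schedule <- function(scale = 1, generator_warmup_steps = 10000L,
                             joint_steps = 300000L,
                             semi_activation_step = 100000L,
                             batch_size = 8L, lr_generator = 1e-3,
                             lr_discriminator = 1e-6,
                             optimizer_momentum = 0.9, weight_decay = 1e-8,
                             weights = loss_weights(),
                             loss_reduction = c("mean", "sum"),
                             semi_on_labeled = FALSE, seed = 1L) {
  loss_reduction <- match.arg(loss_reduction)
  s <- structure(list(
    generator_warmup_steps = max(0L, as.integer(round(generator_warmup_steps * scale))),
    joint_steps = max(0L, as.integer(round(joint_steps * scale))),
    semi_activation_step = max(0L, as.integer(round(semi_activation_step * scale))),
    batch_size = as.integer(batch_size),
    lr_generator = lr_generator, lr_discriminator = lr_discriminator,
    optimizer_momentum = optimizer_momentum, weight_decay = weight_decay,
    weights = weights, loss_reduction = loss_reduction,
    semi_on_labeled = isTRUE(semi_on_labeled), seed = as.integer(seed)),
    class = "tmeseg_semisup_schedule")
  stopifnot(s$lr_generator > 0, s$lr_discriminator > 0, s$batch_size >= 1L)
  if (s$semi_activation_step > s$generator_warmup_steps + s$joint_steps)
    stop("semi_activation_step exceeds the total step count")
  s
}

#' Mutation classifier training schedule
#'
#' Defaults are the published configuration: RMSprop for 100 epochs, batch
#' size 16, learning rate 0.01, momentum 0.9, weight decay 1e-8.
#'
#' @param epochs,batch_size,lr,momentum,weight_decay Scalars, all positive.
#' @param optimizer `"rmsprop"` (the full-scale default) or `"adam"`.
#' @param seed Integer seed driving shuffling.
#' @return A `tmeseg_tgmdn_schedule` list.
#' @export
tgmdn_schedule <- function(epochs = 100L, batch_size = 16L, lr = 0.01,
                           momentum = 0.9, weight_decay = 1e-8,
                           optimizer = c("rmsprop", "adam"), seed = 1L) {
  optimizer <- match.arg(optimizer)
  stopifnot(epochs >= 1L, batch_size >= 1L, lr > 0, momentum >= 0,
            weight_decay >= 0)
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 lr = lr, momentum = momentum, weight_decay = weight_decay,
                 optimizer = optimizer, seed = as.integer(seed)),
            class = "tmeseg_tgmdn_schedule")
}

labeled_batch <- function(labeled, idx, n_classes) {
  list(x = patches_to_batch(lapply(labeled[idx], `[[`, "image")),
       y = masks_to_onehot_batch(lapply(labeled[idx], `[[`, "mask"), n_classes))
}

#' Fully supervised generator training
#'
#' Minimizes the cross-entropy loss over the labeled set (plus the weighted
#' adversarial term when a discriminator is attached; the discriminator is
#' then used frozen). Batches are drawn with replacement from a seeded
#' stream, so the run is reproducible.
#'
#' @param generator A [build_generator()] object.
#' @param labeled List of `list(image, mask)` pairs.
#' @param schedule A [semisup_schedule()].
#' @param steps Number of update steps (default: warmup + joint steps).
#' @param discriminator Optional frozen discriminator for the adversarial
#'   term.
#' @return List with `generator` and a per-step `history` data frame.
#' @export
train_supervised <- function(generator, labeled, schedule = semisup_schedule(),
                             steps = NULL, discriminator = NULL) {
  if (length(labeled) == 0L) stop("labeled set is empty")
  if (is.null(steps))
    steps <- schedule$generator_warmup_steps + schedule$joint_steps
  C <- generator$config$n_classes
  red <- schedule$loss_reduction
  lam <- schedule$weights$lambda_adv_labeled
  optG <- opt_adam(generator$modules, lr = schedule$lr_generator,
                   beta1 = schedule$optimizer_momentum,
                   weight_decay = schedule$weight_decay)
  h_lce <- numeric(steps); h_ladv <- numeric(steps)
  with_seed(schedule$seed, {
    for (step in seq_len(steps)) {
      b <- labeled_batch(labeled,
                         sample.int(length(labeled), schedule$batch_size,
                                    replace = TRUE), C)
      S <- generator$forward(b$x, training = TRUE)
      lce <- cross_entropy_loss(S, b$y, reduction = red)
      dS <- cross_entropy_grad(S, b$y, reduction = red)
      ladv <- 0
      if (!is.null(discriminator) && lam > 0) {
        Dmap <- discriminator$forward(S, training = FALSE)
        ladv <- adversarial_loss(Dmap, reduction = red)
        dS <- dS + lam * discriminator$backward(adversarial_grad(Dmap, red))
        nn_zero_grad(discriminator$modules)
      }
      nn_zero_grad(generator$modules)
      generator$backward(dS)
      optG$step()
      h_lce[step] <- lce; h_ladv[step] <- ladv
      if (!is.finite(lce)) stop("non-finite loss at step ", step)
    }
  })
  history <- data.frame(step = seq_len(steps),
                        phase = rep("supervised", steps),
                        kind = rep("labeled", steps),
                        lce = h_lce, ladv = h_ladv,
                        ld = rep(NA_real_, steps), lsemi = rep(0, steps))
  list(generator = generator, history = history)
}

#' Semi-supervised adversarial training
#'
#' Phase 1 trains the generator alone on labeled batches (cross-entropy
#' only). Phase 2 alternates per step: (a) a discriminator update on the
#' spatial real/fake loss, contrasting the detached generator prediction
#' with the ground-truth one-hot mask of a labeled batch; (b) a generator
#' update on the multitask loss over the labeled batch, plus — once the
#' global step reaches `semi_activation_step` — an unlabeled batch whose
#' confidence map (treated as fixed for the trustworthy-region mask) gates
#' the self-training loss. The history exposes every component per step, so
#' the self-training loss can be seen to be exactly zero before activation.
#'
#' @param generator,discriminator Networks from [build_generator()] /
#'   [build_discriminator()].
#' @param labeled List of `list(image, mask)` pairs.
#' @param unlabeled List of patches without masks.
#' @param schedule A [semisup_schedule()].
#' @return List with `generator`, `discriminator`, and per-step `history`.
#' @export
train_semi_supervised <- function(generator, discriminator, labeled, unlabeled,
                                  schedule = semisup_schedule()) {
  if (length(labeled) == 0L || length(unlabeled) == 0L)
    stop("labeled and unlabeled sets must both be non-empty")
  C <- generator$config$n_classes
  red <- schedule$loss_reduction
  w <- schedule$weights
  warmup <- schedule$generator_warmup_steps
  joint <- schedule$joint_steps
  total <- warmup + joint
  optG <- opt_adam(generator$modules, lr = schedule$lr_generator,
                   beta1 = schedule$optimizer_momentum,
                   weight_decay = schedule$weight_decay)
  optD <- opt_adam(discriminator$modules, lr = schedule$lr_discriminator,
                   beta1 = schedule$optimizer_momentum,
                   weight_decay = schedule$weight_decay)
  use_unlabeled <- w$lambda_adv_unlabeled > 0 || w$lambda_semi > 0
  h <- list(phase = character(total), kind = character(total),
            lce = numeric(total), ladv = numeric(total),
            ld = rep(NA_real_, total), lsemi = numeric(total))
  with_seed(schedule$seed, {
    for (step in seq_len(total)) {
      b <- labeled_batch(labeled,
                         sample.int(length(labeled), schedule$batch_size,
                                    replace = TRUE), C)
      if (step <= warmup) {
        # phase 1: generator-only warmup, cross-entropy only
        S <- generator$forward(b$x, training = TRUE)
        nn_zero_grad(generator$modules)
        generator$backward(cross_entropy_grad(S, b$y, reduction = red))
        optG$step()
        h$phase[step] <- "warmup"; h$kind[step] <- "labeled"
        h$lce[step] <- cross_entropy_loss(S, b$y, reduction = red)
        next
      }
      # phase 2a: discriminator update on (detached prediction, ground truth)
      S <- generator$forward(b$x, training = TRUE)
      nn_zero_grad(discriminator$modules)
      d_on_s <- discriminator$forward(S, training = TRUE)
      gr <- discriminator_grad(d_on_s, d_on_s, reduction = red)  # fake part
      discriminator$backward(gr$d_on_s)
      d_on_y <- discriminator$forward(b$y, training = TRUE)
      gr <- discriminator_grad(d_on_y, d_on_y, reduction = red)  # real part
      discriminator$backward(gr$d_on_y)
      ld <- discriminator_loss(d_on_s, d_on_y, reduction = red)
      optD$step()
      # phase 2b: generator update on the labeled batch (caches of S intact)
      nn_zero_grad(generator$modules)
      lce <- cross_entropy_loss(S, b$y, reduction = red)
      dS <- cross_entropy_grad(S, b$y, reduction = red)
      ladv <- 0
      if (w$lambda_adv_labeled > 0) {
        Dmap <- discriminator$forward(S, training = FALSE)
        ladv <- adversarial_loss(Dmap, reduction = red)
        dS <- dS + w$lambda_adv_labeled *
          discriminator$backward(adversarial_grad(Dmap, red))
        nn_zero_grad(discriminator$modules)
      }
      lsemi_lab <- 0
      if (schedule$semi_on_labeled && step >= schedule$semi_activation_step) {
        Dmap_fix <- discriminator$forward(S, training = FALSE)
        lsemi_lab <- semi_supervised_loss(S, Dmap_fix, w$t_semi, reduction = red)
        dS <- dS + w$lambda_semi *
          semi_supervised_grad(S, Dmap_fix, w$t_semi, reduction = red)
      }
      generator$backward(dS)
      semi_active <- step >= schedule$semi_activation_step && use_unlabeled
      lsemi <- lsemi_lab
      if (semi_active) {
        xu <- patches_to_batch(unlabeled[sample.int(length(unlabeled),
                                                    schedule$batch_size,
                                                    replace = TRUE)])
        Su <- generator$forward(xu, training = TRUE)
        Du <- discriminator$forward(Su, training = FALSE)
        dSu <- w$lambda_semi * semi_supervised_grad(Su, Du, w$t_semi, red)
        if (w$lambda_adv_unlabeled > 0) {
          dSu <- dSu + w$lambda_adv_unlabeled *
            discriminator$backward(adversarial_grad(Du, red))
          nn_zero_grad(discriminator$modules)
        }
        lsemi <- lsemi + semi_supervised_loss(Su, Du, w$t_semi, reduction = red)
        generator$backward(dSu)
      }
      optG$step()
      h$phase[step] <- "joint"
      h$kind[step] <- if (semi_active) "labeled+unlabeled" else "labeled"
      h$lce[step] <- lce; h$ladv[step] <- ladv; h$ld[step] <- ld
      h$lsemi[step] <- lsemi
      if (!is.finite(lce) || !is.finite(ld))
        stop("non-finite loss at step ", step)
    }
  })
  history <- data.frame(step = seq_len(total), phase = h$phase, kind = h$kind,
                        lce = h$lce, ladv = h$ladv, ld = h$ld, lsemi = h$lsemi)
  list(generator = generator, discriminator = discriminator, history = history)
}

#' Train the multilabel mutation classifier
#'
#' Minimizes the multilabel binary cross-entropy with RMSprop over shuffled
#' minibatches; fully seeded.
#'
#' @param classifier A [build_tgmdn()] object.
#' @param dataset List with `patches` and `labels` (data frame with one
#'   binary column per gene, or a binary matrix).
#' @param schedule A [tgmdn_schedule()].
#' @return List with `classifier` and a per-epoch `history` data frame.
#' @export
train_tgmdn <- function(classifier, dataset, schedule = tgmdn_schedule()) {
  patches <- dataset$patches
  lab <- dataset$labels
  if (is.data.frame(lab))
    lab <- as.matrix(lab[, !vapply(lab, is.character, TRUE), drop = FALSE])
  n <- length(patches)
  if (n < 2L) stop("need at least 2 training patches")
  pol <- colSums(lab)
  if (any(pol == 0L | pol == n))
    warning("some label has a single polarity; its AUC will be undefined")
  optm <- if (identical(schedule$optimizer, "adam"))
    opt_adam(classifier$modules, lr = schedule$lr, beta1 = schedule$momentum,
             weight_decay = schedule$weight_decay)
  else
    opt_rmsprop(classifier$modules, lr = schedule$lr,
                momentum = schedule$momentum,
                weight_decay = schedule$weight_decay)
  epoch_loss <- numeric(schedule$epochs)
  with_seed(schedule$seed, {
    for (ep in seq_len(schedule$epochs)) {
      ord <- sample.int(n)
      losses <- c()
      for (start in seq(1L, n, by = schedule$batch_size)) {
        ii <- ord[start:min(start + schedule$batch_size - 1L, n)]
        x <- patches_to_batch(patches[ii])
        y <- t(lab[ii, , drop = FALSE])               # (L, N)
        p <- classifier$forward(x, training = TRUE)
        nn_zero_grad(classifier$modules)
        classifier$backward(multilabel_bce_grad(p, y))
        optm$step()
        losses <- c(losses, multilabel_bce(p, y))
      }
      epoch_loss[ep] <- mean(losses)
      if (!is.finite(epoch_loss[ep])) stop("non-finite loss at epoch ", ep)
    }
  })
  list(classifier = classifier,
       history = data.frame(epoch = seq_len(schedule$epochs),
                            loss = epoch_loss))
}

#' Evaluate a generator on labeled test pairs
#'
#' Predicts probability maps in evaluation mode, compresses them to label
#' masks, and scores the five segmentation metrics. `mode = "global"`
#' (default) pools one confusion table over all test pixels;
#' `mode = "per_patch"` averages each metric over patches.
#'
#' @param generator A trained [build_generator()] object.
#' @param pairs List of `list(image, mask)` test pairs.
#' @param mode Pooling mode.
#' @return A `tmeseg_metrics` report.
#' @export
evaluate_segmentation <- function(generator, pairs,
                                  mode = c("global", "per_patch")) {
  mode <- match.arg(mode)
  if (length(pairs) == 0L) stop("empty test set")
  C <- generator$config$n_classes
  maps <- generator$predict(lapply(pairs, `[[`, "image"))
  preds <- lapply(maps, compress_to_labels)
  truths <- lapply(pairs, `[[`, "mask")
  if (mode == "global") {
    pool <- NULL
    correct <- 0; tot <- 0
    for (i in seq_along(preds)) {
      cc <- confusion_counts(preds[[i]], truths[[i]], n_classes = C)
      if (is.null(pool)) pool <- cc
      else for (f in c("tp", "fp", "tn", "fn")) pool[[f]] <- pool[[f]] + cc[[f]]
      pool$total <- if (i == 1L) cc$total else pool$total + cc$total
    }
    metrics_report(pool)
  } else {
    reps <- lapply(seq_along(preds), function(i) {
      metrics_report(confusion_counts(preds[[i]], truths[[i]], n_classes = C))
    })
    structure(list(accuracy = mean(vapply(reps, `[[`, 0, "accuracy")),
                   precision = mean(vapply(reps, `[[`, 0, "precision")),
                   recall = mean(vapply(reps, `[[`, 0, "recall")),
                   dice = mean(vapply(reps, `[[`, 0, "dice")),
                   iou = mean(vapply(reps, `[[`, 0, "iou"))),
              class = "tmeseg_metrics")
  }
}

#' Evaluate the mutation classifier per gene
#'
#' Scores the test patches and computes, for each gene in column order
#' (APC, TP53, KRAS), the ROC curve and rank-statistic AUC. A gene whose
#' test labels have a single polarity is returned with `defined = FALSE`
#' and `auc = NA`.
#'
#' @param classifier A trained [build_tgmdn()] object.
#' @param patches List of test patches.
#' @param labels Binary label data frame or matrix, one column per gene.
#' @return Named list per gene: `auc`, `roc`, `defined`.
#' @export
evaluate_mutations <- function(classifier, patches, labels) {
  if (is.data.frame(labels))
    labels <- as.matrix(labels[, !vapply(labels, is.character, TRUE),
                               drop = FALSE])
  probs <- classifier$predict(patches)               # n x L
  out <- list()
  for (g in seq_len(ncol(labels))) {
    nm <- colnames(labels)[g]
    if (is.null(nm)) nm <- paste0("label", g)
    y <- labels[, g]
    if (length(unique(y)) < 2L) {
      out[[nm]] <- list(auc = NA_real_, roc = NULL, defined = FALSE)
    } else {
      r <- roc_auc(probs[, g], y)
      out[[nm]] <- list(auc = r$auc, roc = r$roc, defined = TRUE)
    }
  }
  out
}
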