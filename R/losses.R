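# Objectives of the semi-supervised adversarial segmentation scheme and the
# multilabel mutation classifier. All pixel losses are written as sums over
# pixels, exactly as the defining equations; reduction = "mean" divides by
# the number of pixels (and samples) for scale-invariant training at other
# resolutions. Logs are guarded by an epsilon clamp at 1e-8.

LOSS_EPS <- 1e-8

loss_reduce <- function(total, x, reduction) {
  if (reduction == "sum") return(total)
  d <- dim(x)
  npix <- if (length(d) >= 4L) d[1L] * d[2L] * d[4L] else d[1L] * d[2L]
  total / npix
}

#' Loss weights of the multitask segmentation objective
#'
#' Bundles the weighting parameters of the generator objective: the
#' cross-entropy term is always on for labeled data, the adversarial term is
#' weighted by `lambda_adv_labeled` / `lambda_adv_unlabeled` depending on the
#' batch kind, and the self-training term by `lambda_semi`, with `t_semi` the
#' confidence threshold defining the trustworthy region.
#'
#' Defaults are the published training configuration: adversarial weight 0.01
#' on labeled and 0.001 on unlabeled batches, self-training weight 0.1,
#' confidence threshold 0.5.
#'
#' @param lambda_adv_labeled Adversarial weight for labeled batches.
#' @param lambda_adv_unlabeled Adversarial weight for unlabeled batches.
#' @param lambda_semi Weight of the semi-supervised (self-training) loss.
#' @param t_semi Confidence threshold in `[0, 1]` selecting trustworthy pixels.
#' @return A `loss_weights` list.
#' @export
loss_weights <- function(lambda_adv_labeled = 0.01, lambda_adv_unlabeled = 0.001,
                         lambda_semi = 0.1, t_semi = 0.5) {
  stopifnot(lambda_adv_labeled >= 0, lambda_adv_unlabeled >= 0,
            lambda_semi >= 0, t_semi >= 0, t_semi <= 1)
  structure(list(lambda_adv_labeled = lambda_adv_labeled,
                 lambda_adv_unlabeled = lambda_adv_unlabeled,
                 lambda_semi = lambda_semi, t_semi = t_semi),
            class = "tmeseg_loss_weights")
}

#' Multiclass cross-entropy over a probability map
#'
#' Computes `-sum_{h,w} sum_c Y[h,w,c] * log S[h,w,c]` for a predicted
#' per-pixel class distribution `S` against a one-hot mask `Y`. Accepts a
#' single `(H, W, C)` map or a `(H, W, C, N)` batch.
#'
#' @param S Probability map array, values in `[0, 1]`, channels summing to 1.
#' @param Y One-hot mask array of the same shape.
#' @param reduction `"sum"` (the defining form) or `"mean"` (per-pixel mean).
#' @return Non-negative scalar; 0 iff `S` equals `Y` exactly.
#' @export
cross_entropy_loss <- function(S, Y, reduction = c("sum", "mean")) {
  reduction <- match.arg(reduction)
  if (!identical(dim(S), dim(Y))) stop("shape mismatch between S and Y")
  total <- -sum(Y * log(pmax(S, LOSS_EPS)))
  loss_reduce(total, S, reduction)
}

cross_entropy_grad <- function(S, Y, reduction = "sum") {
  g <- -Y / pmax(S, LOSS_EPS)
  if (reduction == "mean") g <- g / loss_npix(S)
  g
}

loss_npix <- function(x) {
  d <- dim(x)
  if (length(d) >= 4L) d[1L] * d[2L] * d[4L] else d[1L] * d[2L]
}

#' Adversarial loss of the generator
#'
#' Computes `-sum_{h,w} log D[h,w]` over a discriminator confidence map. It is
#' minimized when the discriminator scores the generator's prediction as
#' ground-truth-like everywhere, i.e. when the generator fools the
#' discriminator.
#'
#' @param Dmap Confidence map (`(H, W)` matrix, `(H, W, 1)` or `(H, W, 1, N)`
#'   array) with values in `[0, 1]`.
#' @inheritParams cross_entropy_loss
#' @return Non-negative scalar.
#' @export
adversarial_loss <- function(Dmap, reduction = c("sum", "mean")) {
  reduction <- match.arg(reduction)
  total <- -sum(log(pmax(Dmap, LOSS_EPS)))
  if (reduction == "mean") {
    d <- dim(Dmap)
    n <- if (is.null(d)) length(Dmap) else prod(d)
    total <- total / n
  }
  total
}

adversarial_grad <- function(Dmap, reduction = "sum") {
  g <- -1 / pmax(Dmap, LOSS_EPS)
  if (reduction == "mean") {
    d <- dim(Dmap)
    g <- g / (if (is.null(d)) length(Dmap) else prod(d))
  }
  g
}

#' Semi-supervised self-training loss
#'
#' Builds pseudo one-hot labels from the per-pixel argmax of `S` (ties broken
#' toward the lowest class index) and accumulates cross-entropy only on the
#' trustworthy region, i.e. pixels whose discriminator confidence strictly
#' exceeds `t_semi`:
#' `-sum_{h,w} sum_c I(D[h,w] > t_semi) * Yhat[h,w,c] * log S[h,w,c]`.
#' Pixels at or below the threshold contribute exactly zero.
#'
#' @param S Probability map, `(H, W, C)` or `(H, W, C, N)`.
#' @param Dmap Confidence map with matching spatial (and batch) extent.
#' @param t_semi Confidence threshold in `[0, 1]`.
#' @inheritParams cross_entropy_loss
#' @return Non-negative scalar; 0 when no pixel is trustworthy.
#' @export
semi_supervised_loss <- function(S, Dmap, t_semi = 0.5,
                                 reduction = c("sum", "mean")) {
  reduction <- match.arg(reduction)
  masked <- semi_masked_pseudo(S, Dmap, t_semi)
  total <- -sum(masked * log(pmax(S, LOSS_EPS)))
  loss_reduce(total, S, reduction)
}

semi_supervised_grad <- function(S, Dmap, t_semi = 0.5, reduction = "sum") {
  masked <- semi_masked_pseudo(S, Dmap, t_semi)
  g <- -masked / pmax(S, LOSS_EPS)
  if (reduction == "mean") g <- g / loss_npix(S)
  g
}

# indicator(D > t) * onehot(argmax S), as an array shaped like S
semi_masked_pseudo <- function(S, Dmap, t_semi) {
  d0 <- dim(S)
  d <- d0
  if (length(d) == 3L) {
    S <- array(S, c(d, 1L))
    d <- dim(S)
  }
  hw <- d[1L] * d[2L]
  sm <- array(S, c(hw, d[3L], d[4L]))
  best <- matrix(1L, hw, d[4L])
  bestv <- sm[, 1L, ]
  for (ci in seq_len(d[3L])[-1L]) {
    upd <- sm[, ci, ] > bestv                        # strict: ties keep lowest
    best[upd] <- ci
    bestv <- pmax(bestv, sm[, ci, ])
  }
  conf <- matrix(as.numeric(Dmap), hw, d[4L])
  trust <- conf > t_semi
  out <- array(0, dim(sm))
  for (ci in seq_len(d[3L])) out[, ci, ] <- (best == ci) * trust
  array(out, d0)
}

#' Total generator loss for one batch
#'
#' Combines the three components of the multitask objective. On labeled
#' batches the loss is `Lce + lambda_adv_labeled * Ladv` (pseudo-labels are
#' redundant where ground truth exists, so the self-training term is off by
#' default; set `semi_on_labeled = TRUE` for the literal three-term form). On
#' unlabeled batches there is no ground-truth mask, so the cross-entropy term
#' is absent and the loss is
#' `lambda_adv_unlabeled * Ladv + lambda_semi * Lsemi`.
#'
#' @param lce,ladv,lsemi Precomputed loss components (finite scalars).
#' @param weights A [loss_weights()] bundle.
#' @param labeled Logical: was this batch labeled?
#' @param semi_on_labeled Apply the self-training term on labeled batches too.
#' @return Scalar total loss.
#' @export
generator_total_loss <- function(lce, ladv, lsemi, weights, labeled,
                                 semi_on_labeled = FALSE) {
  stopifnot(is.finite(lce), is.finite(ladv), is.finite(lsemi))
  if (labeled) {
    out <- lce + weights$lambda_adv_labeled * ladv
    if (semi_on_labeled) out <- out + weights$lambda_semi * lsemi
    out
  } else {
    weights$lambda_adv_unlabeled * ladv + weights$lambda_semi * lsemi
  }
}

#' Spatial cross-entropy loss of the discriminator
#'
#' Real/fake objective over per-pixel confidence maps:
#' `-sum_{h,w} [ log(1 - D_on_S[h,w]) + log D_on_Y[h,w] ]`, where `D_on_S`
#' is the confidence on a generated probability map (fake, flag 0) and
#' `D_on_Y` on a ground-truth one-hot mask (real, flag 1).
#'
#' @param d_on_s Confidence map on the generator output.
#' @param d_on_y Confidence map on the ground-truth one-hot mask.
#' @inheritParams cross_entropy_loss
#' @return Non-negative scalar; approaches 0 under perfect discrimination.
#' @export
discriminator_loss <- function(d_on_s, d_on_y, reduction = c("sum", "mean")) {
  reduction <- match.arg(reduction)
  total <- -sum(log(pmax(1 - d_on_s, LOSS_EPS))) - sum(log(pmax(d_on_y, LOSS_EPS)))
  if (reduction == "mean") {
    d <- dim(d_on_s)
    n <- if (is.null(d)) length(d_on_s) else prod(d)
    total <- total / n
  }
  total
}

discriminator_grad <- function(d_on_s, d_on_y, reduction = "sum") {
  gs <- 1 / pmax(1 - d_on_s, LOSS_EPS)
  gy <- -1 / pmax(d_on_y, LOSS_EPS)
  if (reduction == "mean") {
    d <- dim(d_on_s)
    n <- if (is.null(d)) length(d_on_s) else prod(d)
    gs <- gs / n; gy <- gy / n
  }
  list(d_on_s = gs, d_on_y = gy)
}

#' Multilabel binary cross-entropy
#'
#' Mean over labels (and samples) of `-[y log p + (1 - y) log(1 - p)]`, the
#' objective of the mutation classifier whose sigmoid head scores each gene
#' (APC, TP53, KRAS) as an independent binary label.
#'
#' @param probs Numeric vector of label probabilities, or `(L, N)` matrix.
#' @param labels Binary vector/matrix of the same shape.
#' @return Non-negative scalar; 0 iff `probs == labels` exactly.
#' @export
multilabel_bce <- function(probs, labels) {
  if (length(probs) != length(labels)) stop("shape mismatch")
  p <- pmin(pmax(probs, LOSS_EPS), 1 - LOSS_EPS)
  -mean(labels * log(p) + (1 - labels) * log(1 - p))
}

multilabel_bce_grad <- function(probs, labels) {
  p <- pmin(pmax(probs, LOSS_EPS), 1 - LOSS_EPS)
  (-labels / p + (1 - labels) / (1 - p)) / length(probs)
}
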