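# The three trainable function families:
#   * segmentation generator: encoder-decoder with a conv stem, residual
#     blocks after the first max-pool, inception-style multi-resolution
#     stages, and a U-Net-style decoder with encoder-skip concatenation;
#   * fully convolutional discriminator: five 4x4 stride-2 convolutions
#     (64/128/256/512/1 channels at full width), bilinear upsampling back to
#     the input size, sigmoid squash to a per-pixel confidence;
#   * multilabel mutation classifier: small CNN encoder, global average
#     pooling, fully connected head with three independent sigmoids.
# All builders are pure: the same config and seed give identical parameters.

scale_width <- function(base, wm, floor_at = 4L, multiple = 1L) {
  w <- max(floor_at, round(base * wm))
  as.integer(multiple * ceiling(w / multiple))
}

#' Generator configuration
#'
#' @param n_classes Number of output classes `C`.
#' @param width_multiplier Channel-width scale; 1 is the full-size network,
#'   `<= 0.125` the tiny CPU preset.
#' @param input_size Expected square input side (must be divisible by 4).
#' @param use_residual_stem Insert the two residual blocks after the first
#'   max-pooling layer.
#' @param n_inception_stages Number of inception feature stages (>= 1) at
#'   the half-resolution scale before the high-dimensional promotion block.
#' @return A `tmeseg_generator_config` list.
#' @export
generator_config <- function(n_classes = 4L, width_multiplier = 1,
                             input_size = 512L, use_residual_stem = TRUE,
                             n_inception_stages = 2L) {
  stopifnot(n_classes >= 2L, width_multiplier > 0, n_inception_stages >= 1L)
  if (input_size %% 4L != 0L) stop("input_size must be divisible by 4")
  structure(list(n_classes = as.integer(n_classes),
                 width_multiplier = width_multiplier,
                 input_size = as.integer(input_size),
                 use_residual_stem = isTRUE(use_residual_stem),
                 n_inception_stages = as.integer(n_inception_stages)),
            class = "tmeseg_generator_config")
}

#' Tiny CPU presets for the three networks
#'
#' @param n_classes Number of segmentation classes.
#' @return Named list of configs (`generator`, `discriminator_width`,
#'   `tgmdn`) sized to train on one CPU in minutes.
#' @export
tiny_preset <- function(n_classes = 4L) {
  list(generator = generator_config(n_classes = n_classes,
                                    width_multiplier = 0.125,
                                    input_size = 64L),
       discriminator_width = 0.125,
       tgmdn = tgmdn_config(width_multiplier = 0.125))
}

conv_bn_relu <- function(cin, cout, kh, kw = kh, stride = 1L) {
  nn_sequential(list(nn_conv2d(cin, cout, kh, kw, stride = stride),
                     nn_batchnorm(cout), nn_relu()))
}

residual_block <- function(w) {
  nn_sequential(list(
    nn_residual(nn_sequential(list(
      nn_conv2d(w, w, 3L), nn_batchnorm(w), nn_relu(),
      nn_conv2d(w, w, 3L), nn_batchnorm(w)))),
    nn_relu()))
}

# Standard inception block: parallel 1x1, 1x1->3x3, factorized 1x3/3x1,
# and a 3x3 average-pooling branch, each ending in cout/4 channels.
inception_block <- function(cin, cout) {
  q <- cout %/% 4L
  nn_parallel_concat(list(
    conv_bn_relu(cin, q, 1L),
    nn_sequential(list(conv_bn_relu(cin, q, 1L), conv_bn_relu(q, q, 3L))),
    nn_sequential(list(conv_bn_relu(cin, q, 1L),
                       conv_bn_relu(q, q, 1L, 3L),
                       conv_bn_relu(q, q, 3L, 1L))),
    nn_sequential(list(nn_avgpool3(), conv_bn_relu(cin, q, 1L)))))
}

# Expanded-filter-bank block promoting high-dimensional representations:
# wide 1x1 branch plus a 1x1 stem fanned out into parallel 1x3 and 3x1.
inception_block_e <- function(cin, cout) {
  q <- cout %/% 4L
  nn_parallel_concat(list(
    conv_bn_relu(cin, 2L * q, 1L),
    nn_sequential(list(conv_bn_relu(cin, q, 1L),
                       nn_parallel_concat(list(conv_bn_relu(q, q %/% 2L, 1L, 3L),
                                               conv_bn_relu(q, q %/% 2L, 3L, 1L))))),
    nn_sequential(list(nn_avgpool3(), conv_bn_relu(cin, q, 1L)))))
}

#' Build the segmentation generator
#'
#' Encoder: conv stem, first max-pool, two residual blocks, inception-style
#' multi-resolution stages, second max-pool, and a high-dimensional
#' promotion block. Decoder: bilinear upsampling with encoder-skip
#' concatenation at each scale, a `C`-channel score map, and a per-pixel
#' softmax, so the output spatial size equals the input size.
#'
#' @param config A [generator_config()].
#' @param seed Integer seed for parameter initialization.
#' @return A generator object with `$forward(x, training)`, `$backward(dy)`,
#'   `$predict(patches)`, and `$modules`.
#' @export
build_generator <- function(config = generator_config(), seed = 1L) {
  wm <- config$width_multiplier
  w1 <- scale_width(64L, wm)
  w2 <- scale_width(128L, wm, multiple = 4L)
  w3 <- scale_width(256L, wm, multiple = 8L)
  C <- config$n_classes
  g <- new.env(parent = emptyenv())
  g$config <- config
  g$seed <- as.integer(seed)
  with_seed(seed, {
    g$stem <- conv_bn_relu(3L, w1, 3L)
    g$pool1 <- nn_maxpool(2L)
    g$res <- if (config$use_residual_stem)
      nn_sequential(list(residual_block(w1), residual_block(w1)))
    else nn_sequential(list())
    g$stages <- c(list(inception_block(w1, w2)),
                  if (config$n_inception_stages > 1L)
                    lapply(seq_len(config$n_inception_stages - 1L),
                           function(i) inception_block(w2, w2)))
    g$pool2 <- nn_maxpool(2L)
    g$blockE <- inception_block_e(w2, w3)
    g$up1 <- nn_upsample(2L)
    g$dec1 <- conv_bn_relu(w3 + w2, w2, 3L)
    g$up2 <- nn_upsample(2L)
    g$dec2 <- conv_bn_relu(w2 + w1, w1, 3L)
    g$head <- nn_conv2d(w1, C, 1L)
    g$softmax <- nn_softmax_spatial()
  })
  g$ch1 <- c(w3, w2)
  g$ch2 <- c(w2, w1)
  g$modules <- c(list(g$stem, g$res), g$stages,
                 list(g$blockE, g$dec1, g$dec2, g$head))
  g$forward <- function(x, training = FALSE) {
    d <- nn_dims(x)
    if (d[1L] %% 4L != 0L || d[2L] %% 4L != 0L)
      stop("generator input height/width must be divisible by 4")
    s0 <- g$stem$fwd(x, training)
    p1 <- g$pool1$fwd(s0, training)
    r <- g$res$fwd(p1, training)
    e <- r
    for (st in g$stages) e <- st$fwd(e, training)
    p2 <- g$pool2$fwd(e, training)
    b <- g$blockE$fwd(p2, training)
    u1 <- g$up1$fwd(b, training)
    d1 <- g$dec1$fwd(cat_channels(list(u1, e)), training)
    u2 <- g$up2$fwd(d1, training)
    d2 <- g$dec2$fwd(cat_channels(list(u2, s0)), training)
    g$softmax$fwd(g$head$fwd(d2, training), training)
  }
  g$backward <- function(dy) {
    dd2 <- g$head$bwd(g$softmax$bwd(dy))
    dcat2 <- g$dec2$bwd(dd2)
    p2s <- split_channels(dcat2, g$ch2)
    dd1 <- g$up2$bwd(p2s[[1L]])
    dcat1 <- g$dec1$bwd(dd1)
    p1s <- split_channels(dcat1, g$ch1)
    db <- g$up1$bwd(p1s[[1L]])
    dp2 <- g$blockE$bwd(db)
    de <- p1s[[2L]] + g$pool2$bwd(dp2)
    for (st in rev(g$stages)) de <- st$bwd(de)
    dp1 <- g$res$bwd(de)
    ds0 <- p2s[[2L]] + g$pool1$bwd(dp1)
    g$stem$bwd(ds0)
  }
  g$predict <- function(patches, batch_size = 8L) {
    predict_prob_maps(g, patches, batch_size)
  }
  class(g) <- "tmeseg_generator"
  g
}

#' Build the fully convolutional discriminator
#'
#' Five 4x4 stride-2 convolutions with channels
#' `64/128/256/512/1 * width_multiplier`; the first four are followed by
#' batch normalization and leaky rectification. The final 1-channel score
#' is upsampled bilinearly to the input size and squashed to `[0, 1]`,
#' giving a per-pixel confidence that the input class map was sampled from
#' a ground-truth mask rather than generated.
#'
#' @param n_classes Channel count `C` of the input probability map.
#' @param width_multiplier Channel-width scale.
#' @param seed Integer seed for parameter initialization.
#' @return A discriminator object with `$forward(x, training)` and
#'   `$backward(dy)`.
#' @export
build_discriminator <- function(n_classes = 4L, width_multiplier = 1,
                                seed = 1L) {
  ch <- vapply(c(64L, 128L, 256L, 512L),
               function(b) scale_width(b, width_multiplier), 0L)
  d <- new.env(parent = emptyenv())
  d$n_classes <- as.integer(n_classes)
  d$seed <- as.integer(seed)
  with_seed(seed, {
    body <- list()
    cin <- n_classes
    for (co in ch) {
      body <- c(body, list(nn_conv2d(cin, co, 4L, stride = 2L, pad = 1L),
                           nn_batchnorm(co), nn_leaky_relu(0.2)))
      cin <- co
    }
    # final score conv: no normalization/activation before the squash
    body <- c(body, list(nn_conv2d(cin, 1L, 4L, stride = 2L, pad = 1L)))
    d$body <- nn_sequential(body)
    d$resize <- nn_resize_to()
    d$squash <- nn_sigmoid()
  })
  d$modules <- list(d$body)
  d$forward <- function(x, training = FALSE) {
    dm <- nn_dims(x)
    if (dm[3L] != d$n_classes)
      stop(sprintf("discriminator expects %d input channels, got %d",
                   d$n_classes, dm[3L]))
    if (dm[1L] %% 32L != 0L || dm[2L] %% 32L != 0L)
      stop("discriminator input height/width must be divisible by 32")
    s <- d$body$fwd(x, training)
    d$resize$target <- dm[1:2]
    d$squash$fwd(d$resize$fwd(s, training), training)
  }
  d$backward <- function(dy) d$body$bwd(d$resize$bwd(d$squash$bwd(dy)))
  class(d) <- "tmeseg_discriminator"
  d
}

#' Mutation classifier configuration
#'
#' @param width_multiplier Channel-width scale of the encoder.
#' @param n_labels Number of independent binary labels (genes).
#' @param feature_dim Width of the penultimate fully connected layer
#'   (`NULL`: scaled from 64 by the width multiplier).
#' @return A `tmeseg_tgmdn_config` list.
#' @export
tgmdn_config <- function(width_multiplier = 1, n_labels = 3L,
                         feature_dim = NULL) {
  structure(list(width_multiplier = width_multiplier,
                 n_labels = as.integer(n_labels),
                 feature_dim = if (is.null(feature_dim)) NULL
                               else as.integer(feature_dim)),
            class = "tmeseg_tgmdn_config")
}

#' Build the multilabel mutation classifier
#'
#' A compact image encoder (stride-2 conv/BN/ReLU units in the spirit of
#' lightweight shuffle-unit backbones; pluggable via the width multiplier),
#' global average pooling, one hidden fully connected layer (the feature
#' layer exported for embedding), and a per-label sigmoid head, so each
#' patch is scored with independent probabilities for APC, TP53 and KRAS —
#' the outputs are not constrained to sum to 1.
#'
#' @param config A [tgmdn_config()].
#' @param seed Integer seed for parameter initialization.
#' @return A classifier object with `$forward(x, training)`,
#'   `$backward(dy)`, `$predict(patches)`, and `$features(patches)`.
#' @export
build_tgmdn <- function(config = tgmdn_config(), seed = 1L) {
  wm <- config$width_multiplier
  ws <- vapply(c(32L, 64L, 128L), function(b) scale_width(b, wm), 0L)
  fdim <- if (is.null(config$feature_dim)) scale_width(64L, wm, floor_at = 32L)
          else config$feature_dim
  m <- new.env(parent = emptyenv())
  m$config <- config
  m$seed <- as.integer(seed)
  with_seed(seed, {
    m$encoder <- nn_sequential(list(
      # stride-1 stem: per-pixel color/texture features before downsampling
      nn_conv2d(3L, ws[1L], 3L, stride = 1L, pad = 1L),
      nn_batchnorm(ws[1L]), nn_relu(),
      nn_conv2d(ws[1L], ws[1L], 3L, stride = 2L, pad = 1L),
      nn_batchnorm(ws[1L]), nn_relu(),
      nn_conv2d(ws[1L], ws[2L], 3L, stride = 2L, pad = 1L),
      nn_batchnorm(ws[2L]), nn_relu(),
      nn_conv2d(ws[2L], ws[3L], 3L, stride = 2L, pad = 1L),
      nn_batchnorm(ws[3L]), nn_relu()))
    m$gap <- nn_global_avgpool()
    m$gap_in <- nn_global_avgpool()
    # +3: global mean of each input channel, a direct color-statistics
    # shortcut past the encoder (stain fractions are near-linear in it)
    m$fc1 <- nn_dense(ws[3L] + 3L, fdim)
    m$act1 <- nn_relu()
    m$fc2 <- nn_dense(fdim, config$n_labels)
    # linear bypass: channel means feed the logits directly, so the head
    # can realize an exact linear decoder of stain fractions
    m$fc_skip <- nn_dense(3L, config$n_labels)
    m$squash <- nn_sigmoid()
  })
  m$feature_dim <- fdim
  m$enc_dim <- ws[3L]
  m$modules <- list(m$encoder, m$fc1, m$fc2, m$fc_skip)
  m$forward <- function(x, training = FALSE) {
    means <- m$gap_in$fwd(x, training)               # (3, N)
    z <- rbind(m$gap$fwd(m$encoder$fwd(x, training), training), means)
    m$penultimate <- m$act1$fwd(m$fc1$fwd(z, training), training)
    logits <- m$fc2$fwd(m$penultimate, training) + m$fc_skip$fwd(means, training)
    m$squash$fwd(logits, training)                   # (L, N)
  }
  m$backward <- function(dy) {
    dlog <- m$squash$bwd(dy)
    dmeans_skip <- m$fc_skip$bwd(dlog)
    dz <- m$fc1$bwd(m$act1$bwd(m$fc2$bwd(dlog)))
    enc_rows <- seq_len(m$enc_dim)
    m$encoder$bwd(m$gap$bwd(dz[enc_rows, , drop = FALSE])) +
      m$gap_in$bwd(dz[-enc_rows, , drop = FALSE] + dmeans_skip)
  }
  m$predict <- function(patches, batch_size = 16L) {
    batched_apply(patches, batch_size, function(x) t(m$forward(x, FALSE)))
  }
  m$features <- function(patches, batch_size = 16L) {
    batched_apply(patches, batch_size, function(x) {
      m$forward(x, FALSE)
      t(m$penultimate)
    })
  }
  class(m) <- "tmeseg_tgmdn"
  m
}

#' Export penultimate-layer features for external embedding
#'
#' One fixed-length feature vector per patch (the values of the last hidden
#' fully connected layer), row order following the input order — suitable
#' input for any off-the-shelf 2-d embedding.
#'
#' @param classifier A [build_tgmdn()] object.
#' @param patches List of patches (or `(H, W, 3)` arrays).
#' @return Numeric matrix, `length(patches)` rows.
#' @export
export_penultimate_features <- function(classifier, patches) {
  classifier$features(patches)
}

# --- batching helpers ------------------------------------------------------

patches_to_batch <- function(patches) {
  pxs <- lapply(patches, patch_pixels)
  d <- dim(pxs[[1L]])
  out <- array(0, c(d[1L], d[2L], 3L, length(pxs)))
  for (i in seq_along(pxs)) out[, , , i] <- pxs[[i]]
  out
}

masks_to_onehot_batch <- function(masks, n_classes) {
  d <- dim(mask_labels(masks[[1L]]))
  out <- array(0, c(d[1L], d[2L], n_classes, length(masks)))
  for (i in seq_along(masks))
    out[, , , i] <- unclass(one_hot_encode(masks[[i]], n_classes))
  out
}

batched_apply <- function(patches, batch_size, fn) {
  idx <- split(seq_along(patches),
               ceiling(seq_along(patches) / batch_size))
  do.call(rbind, lapply(idx, function(ii) fn(patches_to_batch(patches[ii]))))
}

predict_prob_maps <- function(gen, patches, batch_size = 8L) {
  out <- vector("list", length(patches))
  idx <- split(seq_along(patches), ceiling(seq_along(patches) / batch_size))
  for (ii in idx) {
    probs <- gen$forward(patches_to_batch(patches[ii]), training = FALSE)
    for (k in seq_along(ii))
      out[[ii[k]]] <- probs[, , , k, drop = TRUE]
  }
  out
}

#' Save / load a model's parameters with a JSON config sidecar
#'
#' @param model A generator, discriminator or classifier object.
#' @param path Checkpoint path (an `.rds` of the parameter list); a
#'   `<path>.json` sidecar records the config and seed.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  params <- nn_get_params(model$modules)
  saveRDS(params, path)
  side <- list(class = class(model), seed = model$seed)
  if (!is.null(model$config)) side$config <- unclass(model$config)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @param model_skeleton A freshly built model of the same architecture to
#'   receive the stored parameters.
#' @export
load_model <- function(model_skeleton, path) {
  nn_set_params(model_skeleton$modules, readRDS(path))
  model_skeleton
}
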