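# Minimal CNN engine: layers and modules are environments exposing
#   fwd(x, training)  -> output (caching what backward needs)
#   bwd(dy)           -> gradient w.r.t. input (accumulating parameter grads)
#   layers()          -> flat list of parameter-bearing layer environments
# Activations are 4-d arrays dim c(H, W, C, N); dense features are (F, N)
# matrices. Parameter gradients accumulate until nn_zero_grad() so one
# optimizer step can combine several backward passes.

nn_dims <- function(x) {
  d <- dim(x)
  if (is.null(d) || length(d) != 4L) stop("expected a (H, W, C, N) array")
  d
}

#' @noRd
new_layer <- function(type, ...) {
  e <- new.env(parent = emptyenv())
  e$type <- type
  e$par_names <- character(0)
  fields <- list(...)
  for (nm in names(fields)) assign(nm, fields[[nm]], envir = e)
  class(e) <- c(paste0("tmeseg_", type), "tmeseg_layer")
  e
}

# Kaiming-normal fan-in initialization; consumes the current RNG stream.
kaiming_init <- function(dims, fan_in, gain = sqrt(2)) {
  array(stats::rnorm(prod(dims), sd = gain / sqrt(fan_in)), dim = dims)
}

nn_conv2d <- function(cin, cout, kh, kw = kh, stride = 1L, pad = "same",
                      bias = TRUE) {
  if (identical(pad, "same")) {
    pad_h <- (kh - 1L) %/% 2L
    pad_w <- (kw - 1L) %/% 2L
  } else if (length(pad) == 2L) {
    pad_h <- pad[1L]; pad_w <- pad[2L]
  } else {
    pad_h <- pad_w <- pad
  }
  l <- new_layer("conv2d",
    W = kaiming_init(c(kh, kw, cin, cout), fan_in = kh * kw * cin),
    b = numeric(cout),
    stride = as.integer(stride), pad_h = as.integer(pad_h),
    pad_w = as.integer(pad_w), use_bias = bias)
  l$par_names <- if (bias) c("W", "b") else "W"
  l$fwd <- function(x, training = FALSE) {
    l$x <- x
    conv2d_fwd_cpp(x, l$W, l$b, l$stride, l$pad_h, l$pad_w)
  }
  l$bwd <- function(dy) {
    g <- conv2d_bwd_cpp(l$x, l$W, dy, l$stride, l$pad_h, l$pad_w)
    l$g_W <- if (is.null(l$g_W)) g$dw else l$g_W + g$dw
    if (l$use_bias) l$g_b <- if (is.null(l$g_b)) g$db else l$g_b + g$db
    g$dx
  }
  l
}

nn_dense <- function(nin, nout) {
  l <- new_layer("dense",
    W = kaiming_init(c(nout, nin), fan_in = nin),
    b = numeric(nout))
  l$par_names <- c("W", "b")
  l$fwd <- function(x, training = FALSE) {           # x: (F, N)
    l$x <- x
    l$W %*% x + l$b
  }
  l$bwd <- function(dy) {
    gW <- dy %*% t(l$x)
    l$g_W <- if (is.null(l$g_W)) gW else l$g_W + gW
    gb <- rowSums(dy)
    l$g_b <- if (is.null(l$g_b)) gb else l$g_b + gb
    t(l$W) %*% dy
  }
  l
}

nn_batchnorm <- function(c, eps = 1e-5, momentum = 0.1) {
  l <- new_layer("batchnorm",
    gamma = rep(1, c), beta = numeric(c),
    run_mean = numeric(c), run_var = rep(1, c),
    eps = eps, momentum = momentum, nc = c)
  l$par_names <- c("gamma", "beta")
  l$state_names <- c("run_mean", "run_var")
  # broadcasting trick: in the (H*W, C, N) layout a per-channel vector
  # expanded with rep(v, each = H*W) recycles correctly over N
  chan_sums <- function(x, hw, C) {
    rowSums(matrix(colSums(matrix(x, hw)), C))
  }
  l$fwd <- function(x, training = FALSE) {
    d <- nn_dims(x)
    C <- d[3L]; hw <- d[1L] * d[2L]; m <- hw * d[4L]
    if (training) {
      mu <- chan_sums(x, hw, C) / m
      xc <- x - rep(mu, each = hw)
      vv <- chan_sums(xc * xc, hw, C) / m
      l$run_mean <- (1 - l$momentum) * l$run_mean + l$momentum * mu
      l$run_var  <- (1 - l$momentum) * l$run_var  + l$momentum * vv
    } else {
      mu <- l$run_mean; vv <- l$run_var
      xc <- x - rep(mu, each = hw)
    }
    inv <- 1 / sqrt(vv + l$eps)
    xhat <- xc * rep(inv, each = hw)
    l$xhat <- xhat; l$inv <- inv; l$m <- m; l$hw <- hw; l$training <- training
    xhat * rep(l$gamma, each = hw) + rep(l$beta, each = hw)
  }
  l$bwd <- function(dy) {
    d <- nn_dims(dy)
    C <- d[3L]; hw <- l$hw
    dg <- chan_sums(dy * l$xhat, hw, C)
    db <- chan_sums(dy, hw, C)
    l$g_gamma <- if (is.null(l$g_gamma)) dg else l$g_gamma + dg
    l$g_beta  <- if (is.null(l$g_beta))  db else l$g_beta + db
    if (isTRUE(l$training)) {
      dxhat <- dy * rep(l$gamma, each = hw)
      s1 <- chan_sums(dxhat, hw, C)
      s2 <- chan_sums(dxhat * l$xhat, hw, C)
      rep(l$inv / l$m, each = hw) *
        (l$m * dxhat - rep(s1, each = hw) - l$xhat * rep(s2, each = hw))
    } else {
      dy * rep(l$gamma * l$inv, each = hw)
    }
  }
  l
}

nn_relu <- function() {
  l <- new_layer("relu")
  l$fwd <- function(x, training = FALSE) { l$mask <- x > 0; x * l$mask }
  l$bwd <- function(dy) dy * l$mask
  l
}

nn_leaky_relu <- function(alpha = 0.2) {
  l <- new_layer("leaky_relu", alpha = alpha)
  l$fwd <- function(x, training = FALSE) {
    l$mask <- x > 0
    x * l$mask + l$alpha * x * (1 - l$mask)
  }
  l$bwd <- function(dy) dy * l$mask + l$alpha * dy * (1 - l$mask)
  l
}

nn_sigmoid <- function() {
  l <- new_layer("sigmoid")
  l$fwd <- function(x, training = FALSE) { l$y <- 1 / (1 + exp(-x)); l$y }
  l$bwd <- function(dy) dy * l$y * (1 - l$y)
  l
}

nn_maxpool <- function(k = 2L, stride = k) {
  l <- new_layer("maxpool", k = as.integer(k), stride = as.integer(stride))
  l$fwd <- function(x, training = FALSE) {
    l$in_dim <- dim(x)
    r <- maxpool_fwd_cpp(x, l$k, l$stride)
    l$idx <- r$idx
    r$out
  }
  l$bwd <- function(dy) maxpool_bwd_cpp(l$in_dim, l$idx, dy)
  l
}

nn_avgpool3 <- function() {
  l <- new_layer("avgpool3")
  l$fwd <- function(x, training = FALSE) avgpool3_fwd_cpp(x)
  l$bwd <- function(dy) avgpool3_bwd_cpp(dy)
  l
}

nn_upsample <- function(factor = 2L) {
  l <- new_layer("upsample", factor = as.integer(factor))
  l$fwd <- function(x, training = FALSE) {
    d <- nn_dims(x)
    l$in_hw <- d[1:2]
    resize_bilinear_fwd_cpp(x, d[1L] * l$factor, d[2L] * l$factor)
  }
  l$bwd <- function(dy) resize_bilinear_bwd_cpp(dy, l$in_hw[1L], l$in_hw[2L])
  l
}

nn_resize_to <- function() {
  # target size set per forward call via l$target (used by the discriminator
  # to rescale its bottleneck score map back to the input size)
  l <- new_layer("resize_to", target = NULL)
  l$fwd <- function(x, training = FALSE) {
    d <- nn_dims(x)
    l$in_hw <- d[1:2]
    resize_bilinear_fwd_cpp(x, l$target[1L], l$target[2L])
  }
  l$bwd <- function(dy) resize_bilinear_bwd_cpp(dy, l$in_hw[1L], l$in_hw[2L])
  l
}

# Per-pixel softmax over the channel dimension.
nn_softmax_spatial <- function() {
  l <- new_layer("softmax_spatial")
  l$fwd <- function(x, training = FALSE) {
    d <- nn_dims(x)
    hw <- d[1L] * d[2L]
    xm <- array(x, c(hw, d[3L], d[4L]))
    mx <- xm[, 1L, , drop = FALSE]
    for (ci in seq_len(d[3L])[-1L]) mx <- pmax(mx, xm[, ci, , drop = FALSE])
    e <- xm
    for (ci in seq_len(d[3L])) e[, ci, ] <- exp(xm[, ci, ] - mx[, 1L, ])
    tot <- e[, 1L, , drop = FALSE]
    for (ci in seq_len(d[3L])[-1L]) tot <- tot + e[, ci, , drop = FALSE]
    for (ci in seq_len(d[3L])) e[, ci, ] <- e[, ci, ] / tot[, 1L, ]
    l$y <- e; l$d <- d
    array(e, d)
  }
  l$bwd <- function(dy) {
    d <- l$d
    dym <- array(dy, c(d[1L] * d[2L], d[3L], d[4L]))
    dot <- dym[, 1L, , drop = FALSE] * l$y[, 1L, , drop = FALSE]
    for (ci in seq_len(d[3L])[-1L])
      dot <- dot + dym[, ci, , drop = FALSE] * l$y[, ci, , drop = FALSE]
    dx <- dym
    for (ci in seq_len(d[3L])) dx[, ci, ] <- l$y[, ci, ] * (dym[, ci, ] - dot[, 1L, ])
    array(dx, d)
  }
  l
}

nn_global_avgpool <- function() {
  l <- new_layer("global_avgpool")
  l$fwd <- function(x, training = FALSE) {          # (H,W,C,N) -> (C,N)
    d <- nn_dims(x)
    l$in_dim <- d
    xm <- matrix(x, nrow = d[1L] * d[2L])           # cols ordered (c, n)
    matrix(colMeans(xm), nrow = d[3L])
  }
  l$bwd <- function(dy) {
    d <- l$in_dim
    hw <- d[1L] * d[2L]
    dx <- array(rep(as.numeric(dy), each = hw) / hw, d)
    dx
  }
  l
}

# --- combinators -----------------------------------------------------------

nn_sequential <- function(layers) {
  m <- new_layer("sequential", members = layers)
  m$fwd <- function(x, training = FALSE) {
    for (ly in m$members) x <- ly$fwd(x, training)
    x
  }
  m$bwd <- function(dy) {
    for (ly in rev(m$members)) dy <- ly$bwd(dy)
    dy
  }
  m
}

nn_residual <- function(inner) {
  m <- new_layer("residual", members = list(inner))
  m$fwd <- function(x, training = FALSE) x + m$members[[1L]]$fwd(x, training)
  m$bwd <- function(dy) dy + m$members[[1L]]$bwd(dy)
  m
}

# Parallel branches over a shared input, concatenated along the channel axis.
nn_parallel_concat <- function(branches) {
  m <- new_layer("parallel_concat", members = branches)
  m$fwd <- function(x, training = FALSE) {
    outs <- lapply(m$members, function(br) br$fwd(x, training))
    m$ch <- vapply(outs, function(o) dim(o)[3L], 0L)
    cat_channels(outs)
  }
  m$bwd <- function(dy) {
    parts <- split_channels(dy, m$ch)
    dx <- m$members[[1L]]$bwd(parts[[1L]])
    for (i in seq_along(m$members)[-1L]) dx <- dx + m$members[[i]]$bwd(parts[[i]])
    dx
  }
  m
}

cat_channels <- function(xs) {
  d <- dim(xs[[1L]])
  ch <- vapply(xs, function(x) dim(x)[3L], 0L)
  out <- array(0, c(d[1L], d[2L], sum(ch), d[4L]))
  at <- 0L
  for (x in xs) {
    ci <- dim(x)[3L]
    out[, , (at + 1L):(at + ci), ] <- x
    at <- at + ci
  }
  out
}

split_channels <- function(x, ch) {
  parts <- vector("list", length(ch))
  at <- 0L
  for (i in seq_along(ch)) {
    parts[[i]] <- x[, , (at + 1L):(at + ch[i]), , drop = FALSE]
    at <- at + ch[i]
  }
  parts
}

# Flatten a module tree into the list of parameter-bearing layers.
nn_layers <- function(module) {
  if (length(module$par_names) > 0L) return(list(module))
  if (!is.null(module$members))
    return(unlist(lapply(module$members, nn_layers), recursive = FALSE))
  list()
}

nn_zero_grad <- function(modules) {
  for (m in modules)
    for (ly in nn_layers(m))
      for (p in ly$par_names) assign(paste0("g_", p), NULL, envir = ly)
  invisible(NULL)
}

layer_state_names <- function(ly) {
  c(ly$par_names, get0("state_names", envir = ly, ifnotfound = character(0)))
}

nn_get_params <- function(modules) {
  out <- list()
  i <- 0L
  for (m in modules)
    for (ly in nn_layers(m))
      for (p in layer_state_names(ly)) {
        i <- i + 1L
        out[[i]] <- get(p, envir = ly)
      }
  out
}

nn_set_params <- function(modules, params) {
  i <- 0L
  for (m in modules)
    for (ly in nn_layers(m))
      for (p in layer_state_names(ly)) {
        i <- i + 1L
        assign(p, params[[i]], envir = ly)
      }
  invisible(NULL)
}

# --- optimizers ------------------------------------------------------------

#' @noRd
new_optimizer <- function(kind, modules, lr, weight_decay, update_fn) {
  o <- new.env(parent = emptyenv())
  o$kind <- kind
  o$layers <- unlist(lapply(modules, nn_layers), recursive = FALSE)
  o$lr <- lr
  o$weight_decay <- weight_decay
  o$state <- list()
  o$t <- 0L
  o$step <- function() {
    o$t <- o$t + 1L
    for (li in seq_along(o$layers)) {
      ly <- o$layers[[li]]
      for (p in ly$par_names) {
        g <- get0(paste0("g_", p), envir = ly, ifnotfound = NULL)
        if (is.null(g)) next
        th <- get(p, envir = ly)
        if (o$weight_decay > 0) g <- g + o$weight_decay * th
        key <- paste0(li, ".", p)
        upd <- update_fn(o, key, th, g)
        assign(p, upd, envir = ly)
      }
    }
    invisible(NULL)
  }
  o
}

# Adam with additive L2 weight decay; beta1 is the "momentum" of the schedule.
opt_adam <- function(modules, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8, weight_decay = 0) {
  new_optimizer("adam", modules, lr, weight_decay, function(o, key, th, g) {
    st <- o$state[[key]]
    if (is.null(st)) st <- list(m = g * 0, v = g * 0)
    st$m <- beta1 * st$m + (1 - beta1) * g
    st$v <- beta2 * st$v + (1 - beta2) * g^2
    o$state[[key]] <- st
    mhat <- st$m / (1 - beta1^o$t)
    vhat <- st$v / (1 - beta2^o$t)
    th - o$lr * mhat / (sqrt(vhat) + eps)
  })
}

# RMSprop with heavy-ball momentum (classifier training schedule).
opt_rmsprop <- function(modules, lr = 0.01, alpha = 0.99, momentum = 0.9,
                        eps = 1e-8, weight_decay = 0) {
  new_optimizer("rmsprop", modules, lr, weight_decay, function(o, key, th, g) {
    st <- o$state[[key]]
    if (is.null(st)) st <- list(v = g * 0, mom = g * 0)
    st$v <- alpha * st$v + (1 - alpha) * g^2
    st$mom <- momentum * st$mom + g / (sqrt(st$v) + eps)
    o$state[[key]] <- st
    th - o$lr * st$mom
  })
}

# Run code with a private RNG stream, restoring the caller's stream after.
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    stats::runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  code
}

# Counter-based per-item seed derivation (keeps every value < 2^31).
derive_seed <- function(master_seed, counter) {
  as.integer((as.numeric(master_seed) * 48271 + as.numeric(counter) * 16807) %%
               2147483647)
}
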