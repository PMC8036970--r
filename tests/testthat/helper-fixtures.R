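# Shared fixtures: all synthetic, built in code at test time.

tiny_gen_config <- function() {
  generator_config(n_classes = 4L, width_multiplier = 0.125, input_size = 64L)
}

# random valid probability map
random_prob_map <- function(h, w, C, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  x <- array(stats::rexp(h * w * C), c(h, w, C))
  tot <- apply(x, c(1, 2), sum)
  for (ci in seq_len(C)) x[, , ci] <- x[, , ci] / tot
  x
}

random_mask <- function(h, w, C, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  label_mask(matrix(sample(0:(C - 1), h * w, replace = TRUE), h, w),
             n_classes = C)
}

# batchify single-map helpers
as_batch <- function(...) {
  maps <- list(...)
  d <- dim(maps[[1]])
  out <- array(0, c(d, length(maps)))
  for (i in seq_along(maps)) out[, , , i] <- maps[[i]]
  out
}

tiny_scene_config <- function(seed = 1L, height = 64L, width = 64L) {
  scene_config(height = height, width = width, seed = seed)
}
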