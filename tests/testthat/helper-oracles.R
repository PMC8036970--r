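# Independent scalar-loop oracles. These deliberately use explicit loops and
# no shared code with the implementation under test.

oracle_cross_entropy <- function(S, Y, eps = 1e-8) {
  d <- dim(S)
  total <- 0
  for (h in seq_len(d[1])) for (w in seq_len(d[2])) for (ci in seq_len(d[3]))
    total <- total - Y[h, w, ci] * log(max(S[h, w, ci], eps))
  total
}

oracle_adversarial <- function(Dmap, eps = 1e-8) {
  total <- 0
  for (h in seq_len(nrow(Dmap))) for (w in seq_len(ncol(Dmap)))
    total <- total - log(max(Dmap[h, w], eps))
  total
}

oracle_semi <- function(S, Dmap, t_semi, eps = 1e-8) {
  d <- dim(S)
  total <- 0
  for (h in seq_len(d[1])) for (w in seq_len(d[2])) {
    if (Dmap[h, w] > t_semi) {
      cbest <- 1
      for (ci in seq_len(d[3])) if (S[h, w, ci] > S[h, w, cbest]) cbest <- ci
      total <- total - log(max(S[h, w, cbest], eps))
    }
  }
  total
}

oracle_discriminator <- function(d_on_s, d_on_y, eps = 1e-8) {
  total <- 0
  for (h in seq_len(nrow(d_on_s))) for (w in seq_len(ncol(d_on_s)))
    total <- total - log(max(1 - d_on_s[h, w], eps)) - log(max(d_on_y[h, w], eps))
  total
}

oracle_multilabel_bce <- function(p, y, eps = 1e-8) {
  total <- 0
  for (i in seq_along(p)) {
    pi <- min(max(p[i], eps), 1 - eps)
    total <- total - (y[i] * log(pi) + (1 - y[i]) * log(1 - pi))
  }
  total / length(p)
}

oracle_confusion <- function(pred, truth, C) {
  tp <- fp <- tn <- fn <- integer(C)
  for (ci in 0:(C - 1)) {
    for (i in seq_along(pred)) {
      p <- pred[i] == ci; t <- truth[i] == ci
      if (p && t) tp[ci + 1] <- tp[ci + 1] + 1
      else if (p && !t) fp[ci + 1] <- fp[ci + 1] + 1
      else if (!p && t) fn[ci + 1] <- fn[ci + 1] + 1
      else tn[ci + 1] <- tn[ci + 1] + 1
    }
  }
  list(tp = tp, fp = fp, tn = tn, fn = fn)
}

# all-pairs AUC with half credit for ties: O(n^2)
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  total / (length(pos) * length(neg))
}

oracle_argmax_labels <- function(S) {
  d <- dim(S)
  out <- matrix(0L, d[1], d[2])
  for (h in seq_len(d[1])) for (w in seq_len(d[2])) {
    best <- 1
    for (ci in seq_len(d[3])) if (S[h, w, ci] > S[h, w, best]) best <- ci
    out[h, w] <- best - 1L
  }
  out
}
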