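# Independent brute-force oracles.  These deliberately use naive loops and
# set arithmetic, never the package's vectorized implementations.

# AUROC as the explicit Mann-Whitney all-pairs statistic.
oracle_auroc <- function(scores, y) {
  pos <- scores[y == 1]
  neg <- scores[y == 0]
  total <- 0
  for (p in pos) for (n in neg)
    total <- total + (p > n) + 0.5 * (p == n)
  total / (length(pos) * length(neg))
}

# Average precision by walking the PR curve one distinct threshold at a time.
oracle_aupr <- function(scores, y) {
  thresholds <- sort(unique(scores), decreasing = TRUE)
  npos <- sum(y == 1)
  ap <- 0
  prev_recall <- 0
  for (t in thresholds) {
    tp <- 0; fp <- 0
    for (i in seq_along(scores)) {
      if (scores[i] >= t) {
        if (y[i] == 1) tp <- tp + 1 else fp <- fp + 1
      }
    }
    precision <- tp / (tp + fp)
    recall <- tp / npos
    ap <- ap + (recall - prev_recall) * precision
    prev_recall <- recall
  }
  ap
}

# Exhaustive max-F threshold: every cut position between sorted scores plus
# the all-positive and all-negative cuts; smallest threshold wins ties.
oracle_max_f_threshold <- function(scores, y) {
  us <- sort(unique(scores))
  cands <- c(us[1] - 1,
             if (length(us) > 1) (us[-length(us)] + us[-1]) / 2,
             us[length(us)] + 1)
  best_f <- -1
  best_t <- NA_real_
  for (t in cands) {
    tp <- 0; fp <- 0; fn <- 0
    for (i in seq_along(scores)) {
      if (scores[i] >= t) {
        if (y[i] == 1) tp <- tp + 1 else fp <- fp + 1
      } else if (y[i] == 1) fn <- fn + 1
    }
    f <- if (tp == 0) 0 else 2 * tp / (2 * tp + fp + fn)
    if (f > best_f + 1e-15) {
      best_f <- f
      best_t <- t
    }
  }
  best_t
}

# Discrete Bayes posterior from histogram bin masses on a shared grid.
oracle_discrete_posterior <- function(y, breaks, mass_g1, mass_g0, prior_g1) {
  bin <- findInterval(y, breaks, rightmost.closed = TRUE)
  widths <- diff(breaks)
  f1 <- mass_g1[bin] / widths[bin]
  f0 <- mass_g0[bin] / widths[bin]
  f1 * prior_g1 / (f1 * prior_g1 + f0 * (1 - prior_g1))
}

# Tanimoto via explicit set arithmetic.
oracle_tanimoto <- function(a, b) {
  inter <- 0
  for (x in a) if (x %in% b) inter <- inter + 1
  uni <- length(a) + length(b) - inter
  if (uni == 0) 0 else inter / uni
}
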