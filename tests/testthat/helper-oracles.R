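# Independent brute-force oracles used across the suite. These deliberately
# re-derive quantities with plain loops so they share no code path with the
# implementation they check.

naive_kernel_matrix <- function(points, centers, sigma) {
  out <- matrix(NA_real_, nrow(points), nrow(centers))
  for (i in seq_len(nrow(points))) {
    for (l in seq_len(nrow(centers))) {
      out[i, l] <- exp(-sum((points[i, ] - centers[l, ])^2) / (2 * sigma^2))
    }
  }
  out
}

naive_h <- function(K) {
  h <- numeric(ncol(K))
  for (l in seq_len(ncol(K))) {
    s <- 0
    for (i in seq_len(nrow(K))) s <- s + K[i, l]
    h[l] <- s / nrow(K)
  }
  h
}

naive_H <- function(K_tr, K_te, alpha) {
  nb <- ncol(K_tr)
  H <- matrix(0, nb, nb)
  for (l in seq_len(nb)) {
    for (m in seq_len(nb)) {
      a <- 0
      for (i in seq_len(nrow(K_tr))) a <- a + K_tr[i, l] * K_tr[i, m]
      b <- 0
      for (j in seq_len(nrow(K_te))) b <- b + K_te[j, l] * K_te[j, m]
      H[l, m] <- alpha * a / nrow(K_tr) + (1 - alpha) * b / nrow(K_te)
    }
  }
  H
}

# P(score_anomaly > score_normal) + 0.5 P(tie), by exhaustive pairs
pairwise_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# a true anomaly at test index i counts as found if any candidate start lies
# in [i - w + 1, i]
tol_hit <- function(candidates, i, window = 3L) {
  any(candidates >= i - window + 1L & candidates <= i)
}

random_design <- function(n_tr, n_te, nb, d, sigma = 1, seed = 1) {
  withr::with_seed(seed, {
    train <- matrix(stats::rnorm(n_tr * d), ncol = d)
    test <- matrix(stats::rnorm(n_te * d), ncol = d)
    centers <- test[sample.int(n_te, nb), , drop = FALSE]
    list(train = train, test = test, centers = centers,
         design = kernel_design(train, test, centers, sigma))
  })
}
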