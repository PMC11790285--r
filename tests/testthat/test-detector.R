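# small, fast configurations used throughout: singleton grids skip the CV
# search, and nb >= nte makes the center draw deterministic
fast_config <- function(loss = "L2", divergence = "PLSBD", alpha = 0.1,
                        tau = 0.9, window = 3L, step = 1L, nb = 50L) {
  detector_config(loss, divergence, alpha = alpha, window = window,
                  step = step, tau = tau,
                  hyper = hyper_params(alpha = alpha, sigma_grid = 1,
                                       lambda_grid = 0.1, nb = nb))
}

small_pair <- function(seed = 1, ntr = 40, nte = 20) {
  withr::with_seed(seed, list(train = matrix(rnorm(ntr), ncol = 1),
                              test = matrix(rnorm(nte), ncol = 1)))
}

test_that("window bookkeeping follows floor((nte - window)/step) + 1", {
  p <- small_pair(3)
  for (cfg in list(c(3, 1), c(3, 2), c(5, 4), c(1, 1), c(7, 3))) {
    det <- detect_windows(p$train, p$test,
                          fast_config(window = cfg[1], step = cfg[2]), seed = 1)
    expect_equal(nrow(det$windows), floor((20 - cfg[1]) / cfg[2]) + 1)
    expect_equal(det$windows$start[1], 1)
    expect_true(all(det$windows$end == det$windows$start + cfg[1] - 1))
    expect_true(all(det$windows$end <= 20))
  }
  expect_error(detect_windows(p$train, p$test[1:2, , drop = FALSE],
                              fast_config(window = 3)),
               class = "plsbd_error_parameter")
})

test_that("tau = 1 flags nothing and candidates shrink as tau grows", {
  p <- small_pair(5)
  det1 <- detect_windows(p$train, p$test, fast_config(tau = 1), seed = 2)
  expect_length(det1$candidates, 0)

  taus <- c(0.2, 0.5, 0.8, 0.95)
  cands <- lapply(taus, function(tt) {
    detect_windows(p$train, p$test, fast_config(tau = tt), seed = 2)$candidates
  })
  for (k in seq_along(taus)[-1]) {
    expect_true(all(cands[[k]] %in% cands[[k - 1]]))
  }
  # the top-scoring window is always proposed below tau = 1
  det <- detect_windows(p$train, p$test, fast_config(tau = 0.95), seed = 2)
  expect_true(det$windows$start[which.max(det$windows$normalized)] %in%
                det$candidates)
})

test_that("detection is seed-deterministic, and seed-free under full-center designs", {
  p <- small_pair(7, ntr = 60, nte = 30)
  cfg <- detector_config(hyper = hyper_params(alpha = 0.1, nb = 20))
  d1 <- detect_windows(p$train, p$test, cfg, seed = 42)
  d2 <- detect_windows(p$train, p$test, cfg, seed = 42)
  expect_equal(d1$windows, d2$windows)
  expect_identical(d1$candidates, d2$candidates)

  # nb >= nte: centers are all test rows; with singleton grids there is no
  # remaining randomness at all
  cfg_full <- fast_config(nb = 30)
  da <- detect_windows(p$train, p$test, cfg_full, seed = 1)
  db <- detect_windows(p$train, p$test, cfg_full, seed = 999)
  expect_equal(da$windows, db$windows)
})

test_that("alpha = 0 + ALPHA_PE + L2 reproduces an independently coded uLSIF detector", {
  p <- small_pair(9, ntr = 30, nte = 15)
  cfg <- fast_config(loss = "L2", divergence = "ALPHA_PE", alpha = 0, nb = 15)
  det <- detect_windows(p$train, p$test, cfg, seed = 1)

  # independent uLSIF sliding-window scorer: plain loops, test rows as centers
  sigma <- 1; lambda <- 0.1; W <- 3
  ctr <- p$test
  Ktr <- naive_kernel_matrix(p$train, ctr, sigma)
  Kte <- naive_kernel_matrix(p$test, ctr, sigma)
  oracle <- numeric(15 - W + 1)
  for (s in seq_along(oracle)) {
    Kw <- Kte[s:(s + W - 1), , drop = FALSE]
    H <- t(Kw) %*% Kw / W
    th <- solve(H + lambda * diag(15), colMeans(Ktr))
    oracle[s] <- mean(Ktr %*% th) / 2 - 0.5
  }
  expect_equal(det$windows$score, oracle, tolerance = 1e-12)
})

test_that("repeated runs aggregate per-index frequencies and window means", {
  p <- small_pair(11)
  cfg <- detector_config(hyper = hyper_params(alpha = 0.1, nb = 10,
                                              sigma_grid = c(0.7, 1.3),
                                              lambda_grid = 0.1))
  r1 <- detect_repeated(list(train = p$train, test = p$test), cfg,
                        runs = 1, base_seed = 3)
  single <- detect_windows(p$train, p$test, cfg, seed = 3)
  expect_equal(r1$frequency$count,
               as.integer(seq_len(20) %in% single$candidates))
  expect_equal(r1$windows$mean_normalized, single$windows$normalized)

  r5a <- detect_repeated(list(train = p$train, test = p$test), cfg,
                         runs = 5, base_seed = 3)
  r5b <- detect_repeated(list(train = p$train, test = p$test), cfg,
                         runs = 5, base_seed = 3)
  expect_equal(r5a$frequency, r5b$frequency)

  manual <- integer(20)
  for (f in r5a$fits) manual[f$candidates] <- manual[f$candidates] + 1L
  expect_equal(r5a$frequency$count, manual)
})

test_that("the labelled-series front end splits blocks and reports global indices", {
  series <- gen_dataset1(seed = 2)
  det <- detect_anomalies(series, fast_config(), seed = 4)
  expect_equal(det$n_train, 200)
  expect_equal(det$n_test, 100)
  expect_equal(det$candidates_global, det$candidates + 200L)
  expect_length(det$test_labels, 100)
  expect_equal(sum(det$test_labels), 2)

  g <- generics::glance(det)
  expect_equal(g$n_windows, 98)
  expect_equal(g$n_candidates, length(det$candidates))
  expect_s3_class(generics::tidy(det), "tbl_df")

  # training rows must be anomaly-free
  bad <- series
  bad$label[5] <- 1L
  expect_error(detect_anomalies(bad, fast_config()), class = "plsbd_error_format")
})
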