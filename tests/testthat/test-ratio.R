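test_that("the L1 solution is the elementwise reciprocal of the mixture means", {
  expect_equal(solve_l1(c(0.5, 0.25), c(0.5, 0.25), 0.3), c(2, 4))
  expect_equal(solve_l1(0.9, 0.1, 0), 10) # alpha = 0 ignores h_tr
  expect_equal(solve_l1(0.2, 0.4, 0.1), 1 / 0.38, tolerance = 1e-12)

  for (s in 1:10) {
    withr::with_seed(s, {
      h_tr <- runif(20, 1e-4, 1)
      h_te <- runif(20, 1e-4, 1)
      a <- runif(1, 0, 0.99)
    })
    expect_true(all(solve_l1(h_tr, h_te, a) > 0))
  }

  expect_error(solve_l1(c(0.5, -0.2), c(0.5, 0.1), 0.9),
               class = "plsbd_error_degenerate")
  expect_error(solve_l1(c(0.1, 0.2), 0.1, 0), class = "plsbd_error_shape")
})

test_that("the L2 solution solves the ridge system and minimises the quadratic risk", {
  expect_equal(solve_l2(diag(3), c(1, 2, 3), 0), c(1, 2, 3))
  expect_equal(solve_l2(diag(2), c(4, 6), 1), c(2, 3))

  for (s in 1:20) {
    withr::with_seed(100 + s, {
      A <- matrix(rnorm(16), 4)
      H <- crossprod(A) / 4
      h <- runif(4)
    })
    theta <- solve_l2(H, h, 0.1)
    oracle <- stats::optim(rep(0, 4),
                           fn = function(x) 0.5 * drop(t(x) %*% H %*% x) -
                             sum(h * x) + 0.05 * sum(x^2),
                           method = "BFGS",
                           control = list(maxit = 1000, reltol = 1e-14))
    expect_equal(theta, oracle$par, tolerance = 1e-6)
  }

  # duplicated basis columns make H exactly singular at lambda = 0
  K <- cbind(c(1, 0.5), c(1, 0.5))
  H_sing <- crossprod(K) / 2
  expect_error(solve_l2(H_sing, c(0.7, 0.7), 0), class = "plsbd_error_singular")
})

test_that("objective functions agree with independent arithmetic", {
  expect_equal(l1_objective(0.3, 0.7, 0, 0.5), 1)
  expect_equal(l1_objective(0.9, 0.5, 2, 0), 0)
  expect_equal(l1_objective(0.2, 0.4, 1, 0.5), 0.7)

  expect_equal(l2_objective(diag(1), 1, 0), 0)
  expect_equal(l2_objective(diag(1), 1, 1), -0.5)

  withr::with_seed(7, {
    A <- matrix(rnorm(25), 5); H <- crossprod(A); h <- runif(5); th <- rnorm(5)
  })
  quad <- 0
  for (i in 1:5) for (j in 1:5) quad <- quad + th[i] * H[i, j] * th[j]
  expect_equal(l2_objective(H, h, th), 0.5 * quad - sum(h * th),
               tolerance = 1e-12)
})

test_that("ratio evaluation is the Gaussian kernel expansion", {
  ctr <- matrix(c(0, 2), ncol = 1)
  m0 <- ratio_model(ctr, 1, c(0, 0), 0.1)
  expect_equal(estimate_ratio(m0, matrix(c(-1, 0, 3))), c(0, 0, 0))

  m1 <- ratio_model(matrix(1.5), 2, 2, 0)
  expect_equal(estimate_ratio(m1, matrix(1.5)), 2)

  withr::with_seed(13, {
    ctr <- matrix(rnorm(8), 4, 2)
    th <- rnorm(4)
    pts <- matrix(rnorm(20), 10, 2)
  })
  m <- ratio_model(ctr, 0.8, th, 0.2)
  oracle <- numeric(10)
  for (i in 1:10) {
    for (l in 1:4) {
      oracle[i] <- oracle[i] +
        th[l] * exp(-sum((pts[i, ] - ctr[l, ])^2) / (2 * 0.8^2))
    }
  }
  expect_equal(estimate_ratio(m, pts), oracle, tolerance = 1e-12)
  expect_equal(predict(m, pts), estimate_ratio(m, pts))
})

test_that("cross-validation selects by held-out risk and is reproducible", {
  withr::with_seed(31, {
    train <- matrix(rnorm(60), ncol = 1)
    test <- matrix(rnorm(50), ncol = 1)
  })
  ctr <- select_centers(test, 10, seed = 1)

  hp1 <- hyper_params(alpha = 0.1, sigma_grid = 0.8, lambda_grid = 0.5)
  cv1 <- cross_validate(train, test, hp1, "L2", centers = ctr, seed = 5)
  expect_equal(cv1$sigma, 0.8)
  expect_equal(cv1$lambda, 0.5)

  hp2 <- hyper_params(alpha = 0.1, sigma_grid = c(0.5, 1.2), lambda_grid = 0.1)
  cv_a <- cross_validate(train, test, hp2, "L2", centers = ctr, seed = 5)
  cv_b <- cross_validate(train, test, hp2, "L2", centers = ctr, seed = 5)
  expect_identical(cv_a$sigma, cv_b$sigma)
  expect_identical(cv_a$cv_table, cv_b$cv_table)

  # independent re-implementation of the fold loop (same fold RNG protocol)
  folds <- withr::with_seed(5, list(
    tr = sample(rep_len(1:5, nrow(train))),
    te = sample(rep_len(1:5, nrow(test)))
  ))
  mean_score <- function(sigma) {
    scores <- numeric(5)
    for (f in 1:5) {
      Ktr <- naive_kernel_matrix(train[folds$tr != f, , drop = FALSE], ctr, sigma)
      Kte <- naive_kernel_matrix(test[folds$te != f, , drop = FALSE], ctr, sigma)
      Ktro <- naive_kernel_matrix(train[folds$tr == f, , drop = FALSE], ctr, sigma)
      Kteo <- naive_kernel_matrix(test[folds$te == f, , drop = FALSE], ctr, sigma)
      H <- 0.1 * crossprod(Ktr) / nrow(Ktr) + 0.9 * crossprod(Kte) / nrow(Kte)
      th <- solve(H + diag(0.1, 10), colMeans(Ktr))
      Ho <- 0.1 * crossprod(Ktro) / nrow(Ktro) + 0.9 * crossprod(Kteo) / nrow(Kteo)
      scores[f] <- 0.5 * drop(t(th) %*% Ho %*% th) - sum(colMeans(Ktro) * th)
    }
    mean(scores)
  }
  oracle_best <- c(0.5, 1.2)[which.min(c(mean_score(0.5), mean_score(1.2)))]
  expect_equal(cv_a$sigma, oracle_best)
  expect_equal(cv_a$cv_table$score, c(mean_score(0.5), mean_score(1.2)),
               tolerance = 1e-10)

  expect_error(cross_validate(train[1:3, , drop = FALSE], test, hp2, "L2"),
               class = "plsbd_error_parameter")
})

test_that("an L1 fit on identical samples averages to the number of bases", {
  # exact identity: mean of w-hat over the sample equals nb whenever
  # train == test, a sharp check of solve_l1 + estimate_ratio composed
  withr::with_seed(4, x <- matrix(rnorm(40), ncol = 2))
  m <- fit_ratio(x, x, x[1:10, ], sigma = 0.8, alpha = 0.3, loss = "L1")
  expect_equal(mean(estimate_ratio(m, x)), 10, tolerance = 1e-12)
})

test_that("the alpha = 0 L2 path computes exactly the uLSIF estimator", {
  rd <- random_design(30, 25, 8, 1, sigma = 1.1, seed = 77)
  h <- compute_h_vectors(rd$design)
  theta <- solve_l2(compute_H_matrix(rd$design, 0), h$h_tr, 0.2)

  # independent uLSIF: test-only Gram matrix, ridge-regularised
  Kte <- naive_kernel_matrix(rd$test, rd$centers, 1.1)
  Ktr <- naive_kernel_matrix(rd$train, rd$centers, 1.1)
  H_u <- t(Kte) %*% Kte / nrow(Kte)
  theta_u <- solve(H_u + 0.2 * diag(8), colMeans(Ktr))
  expect_equal(theta, drop(theta_u), tolerance = 1e-10)
})
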