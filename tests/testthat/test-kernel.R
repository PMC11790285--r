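test_that("Gaussian kernel matrix matches closed forms and a loop oracle", {
  expect_equal(gaussian_kernel_matrix(0, 0, 1), matrix(1))
  expect_equal(gaussian_kernel_matrix(0, 1, 1), matrix(exp(-0.5)))
  expect_equal(gaussian_kernel_matrix(matrix(c(0, 0), 1), matrix(c(3, 4), 1), 5),
               matrix(exp(-0.5)))

  withr::with_seed(11, {
    pts <- matrix(rnorm(15), 5, 3)
    ctr <- matrix(rnorm(12), 4, 3)
  })
  K <- gaussian_kernel_matrix(pts, ctr, 0.7)
  expect_equal(K, naive_kernel_matrix(pts, ctr, 0.7), tolerance = 1e-12)
  expect_true(all(K > 0 & K <= 1))

  # diagonal of a self-design is exactly one
  expect_equal(diag(gaussian_kernel_matrix(pts, pts, 0.7)), rep(1, 5))
})

test_that("center selection is a seeded without-replacement subsample", {
  withr::with_seed(2, test <- matrix(rnorm(40), 20, 2))

  # fewer rows than requested centers: all rows, original order
  expect_identical(select_centers(test, nb = 50), test)

  c1 <- select_centers(test, nb = 8, seed = 99)
  c2 <- select_centers(test, nb = 8, seed = 99)
  expect_identical(c1, c2)
  expect_equal(nrow(c1), 8)

  # every center is exactly one test row, and no row is used twice
  row_ids <- apply(c1, 1, function(r) {
    which(apply(test, 1, function(t) identical(unname(t), unname(r))))
  })
  expect_length(unique(row_ids), 8)

  expect_error(select_centers(test, nb = 0), class = "plsbd_error_parameter")
})

test_that("kernel sufficient statistics match naive recomputation", {
  # single point at its own center
  d0 <- kernel_design(matrix(0), matrix(0), matrix(0), 1)
  expect_equal(compute_h_vectors(d0)$h_tr, 1)

  # symmetric pair around a central basis
  ds <- kernel_design(matrix(c(-1, 1)), matrix(c(-1, 1)), matrix(0), 1)
  expect_equal(compute_h_vectors(ds)$h_tr, exp(-0.5))

  rd <- random_design(5, 6, 3, 2, sigma = 0.9, seed = 21)
  h <- compute_h_vectors(rd$design)
  expect_equal(h$h_tr, naive_h(rd$design$K_train), tolerance = 1e-12)
  expect_equal(h$h_te, naive_h(rd$design$K_test), tolerance = 1e-12)

  H <- compute_H_matrix(rd$design, 0.1)
  expect_equal(H, naive_H(rd$design$K_train, rd$design$K_test, 0.1),
               tolerance = 1e-12)
  expect_equal(H, t(H))

  # uLSIF reduction: alpha = 0 uses the test sample only
  expect_equal(compute_H_matrix(rd$design, 0),
               crossprod(rd$design$K_test) / nrow(rd$design$K_test),
               tolerance = 1e-14)

  # all kernel values one: H is the all-ones matrix
  d1 <- kernel_design(matrix(0), matrix(0), matrix(0), 1)
  expect_equal(compute_H_matrix(d1, 0.3), matrix(1))
})

test_that("H is positive semidefinite and kernels saturate as sigma grows", {
  for (s in 1:50) {
    rd <- random_design(6, 7, 4, 2, sigma = runif(1, 0.3, 3), seed = s)
    ev <- eigen(compute_H_matrix(rd$design, runif(1, 0, 0.99)),
                symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), -1e-10)
  }

  rd <- random_design(10, 10, 5, 3, sigma = 1e6, seed = 3)
  h <- compute_h_vectors(rd$design)
  expect_equal(h$h_tr, rep(1, 5), tolerance = 1e-6)
  expect_equal(h$h_te, rep(1, 5), tolerance = 1e-6)
})

test_that("kernel-layer contracts reject bad input", {
  expect_error(gaussian_kernel_matrix(0, 0, 0), class = "plsbd_error_parameter")
  expect_error(gaussian_kernel_matrix(0, 0, -1), class = "plsbd_error_parameter")
  expect_error(gaussian_kernel_matrix(matrix(1, 2, 2), matrix(1, 2, 3), 1),
               class = "plsbd_error_shape")
  expect_error(gaussian_kernel_matrix(matrix(c(1, NA), 1), matrix(1, 1, 2), 1),
               class = "plsbd_error_format")
  expect_error(compute_h_vectors(list()), class = "plsbd_error_shape")
  rd <- random_design(4, 4, 2, 1, seed = 5)
  expect_error(compute_H_matrix(rd$design, 1), class = "plsbd_error_parameter")
  expect_error(compute_H_matrix(rd$design, -0.1), class = "plsbd_error_parameter")

  std <- standardize_features(rd$train, rd$test)
  expect_equal(colMeans(std$train), rep(0, 1), tolerance = 1e-12)
  expect_equal(apply(std$train, 2, sd), rep(1, 1), tolerance = 1e-12)
})
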