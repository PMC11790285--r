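#' Gaussian kernel design matrix
#'
#' Evaluates the Gaussian kernel \eqn{K_\sigma(x, c) = \exp(-\|x - c\|^2 /
#' (2\sigma^2))} between every row of `points` and every row of `centers`.
#' This matrix is the design matrix of the kernel density-ratio model
#' \eqn{\hat w(x; \theta) = \sum_l \theta_l K_\sigma(x, c_l)}.
#'
#' Distances are plain squared Euclidean norms over all features; no implicit
#' feature scaling is applied (see [standardize_features()] for an explicit,
#' opt-in alternative).
#'
#' @param points Numeric matrix (m x d), data frame, or numeric vector
#'   (treated as a one-column matrix).
#' @param centers Numeric matrix (nb x d) of kernel centers, same column
#'   dimension as `points`.
#' @param sigma Positive kernel width.
#' @return An m x nb numeric matrix with entries in (0, 1]; an entry equals 1
#'   exactly when the point coincides with the center.
#' @examples
#' gaussian_kernel_matrix(0, 1, sigma = 1) # exp(-0.5)
#' @export
gaussian_kernel_matrix <- function(points, centers, sigma) {
  if (!is.numeric(sigma) || length(sigma) != 1L || is.na(sigma) || sigma <= 0) {
    abort_parameter("`sigma` must be a single positive number.")
  }
  points <- as_feature_matrix(points, "points")
  centers <- as_feature_matrix(centers, "centers")
  if (ncol(points) != ncol(centers)) {
    abort_shape(sprintf("`points` has %d columns but `centers` has %d.",
                        ncol(points), ncol(centers)))
  }
  d2 <- outer(rowSums(points^2), rep(1, nrow(centers))) +
    outer(rep(1, nrow(points)), rowSums(centers^2)) -
    2 * tcrossprod(points, centers)
  d2 <- pmax(d2, 0) # guard tiny negative values from cancellation
  exp(-d2 / (2 * sigma^2))
}

#' Draw kernel centers from the test sample
#'
#' Kernel centers are a uniform without-replacement subsample of the test
#' rows. When the test sample has at most `nb` rows, all rows are returned in
#' their original order, which also makes the downstream detector fully
#' deterministic. Sampling without replacement avoids duplicate centers,
#' which would make the Gram matrix singular at zero regularisation.
#'
#' @param test Numeric matrix (or data frame / vector) of test observations.
#' @param nb Number of basis functions requested (default 50).
#' @param seed Optional integer seed; the caller's RNG state is untouched.
#' @return A min(nb, nte) x d matrix of center rows.
#' @export
select_centers <- function(test, nb = 50L, seed = NULL) {
  nb <- check_scalar(nb, "nb", lower = 1, integerish = TRUE)
  test <- as_feature_matrix(test, "test")
  if (nrow(test) <= nb) return(test)
  idx <- with_seed_opt(seed, sample.int(nrow(test), nb))
  test[idx, , drop = FALSE]
}

#' Assemble a kernel design for a train/test sample pair
#'
#' Bundles the two Gaussian design matrices evaluated at shared centers; the
#' object feeds [compute_h_vectors()] and [compute_H_matrix()].
#'
#' @param train,test Numeric matrices with a common column dimension.
#' @inheritParams gaussian_kernel_matrix
#' @return A `kernel_design` list with elements `K_train`, `K_test`,
#'   `centers`, `sigma`.
#' @export
kernel_design <- function(train, test, centers, sigma) {
  train <- as_feature_matrix(train, "train")
  test <- as_feature_matrix(test, "test")
  structure(
    list(
      K_train = gaussian_kernel_matrix(train, centers, sigma),
      K_test = gaussian_kernel_matrix(test, centers, sigma),
      centers = as_feature_matrix(centers, "centers"),
      sigma = sigma
    ),
    class = "kernel_design"
  )
}

#' Kernel mean embeddings of the training and test samples
#'
#' Column means of the two design matrices: \eqn{\hat h^{tr}_l =
#' \frac{1}{n_{tr}} \sum_i K^{tr}_{il}} and likewise for the test sample.
#' These are the sufficient statistics of the closed-form L1 solver and the
#' linear term of the L2 objective.
#'
#' @param design A [kernel_design()] object.
#' @return List with numeric vectors `h_tr` and `h_te` of length nb.
#' @export
compute_h_vectors <- function(design) {
  if (!inherits(design, "kernel_design")) {
    abort_shape("`design` must be a `kernel_design` object.")
  }
  if (nrow(design$K_train) < 1L || nrow(design$K_test) < 1L ||
      ncol(design$K_train) < 1L) {
    abort_shape("`design` has an empty kernel matrix.")
  }
  list(h_tr = colMeans(design$K_train), h_te = colMeans(design$K_test))
}

#' Mixture Gram matrix of the kernel model
#'
#' The quadratic-term matrix of the L2 objective:
#' \deqn{\hat H = \frac{\alpha}{n_{tr}} K_{tr}^\top K_{tr} +
#'       \frac{1-\alpha}{n_{te}} K_{te}^\top K_{te},}
#' an empirical second moment of the basis functions under the mixture
#' reference density \eqn{m_\alpha = \alpha p_{tr} + (1-\alpha) p_{te}}. At
#' `alpha = 0` it reduces to the test-only Gram matrix used by uLSIF.
#'
#' @param design A [kernel_design()] object.
#' @param alpha Mixing weight of the training density, in [0, 1).
#' @return A symmetric positive semidefinite nb x nb matrix.
#' @export
compute_H_matrix <- function(design, alpha) {
  alpha <- check_alpha(alpha)
  if (!inherits(design, "kernel_design")) {
    abort_shape("`design` must be a `kernel_design` object.")
  }
  H <- alpha / nrow(design$K_train) * crossprod(design$K_train) +
    (1 - alpha) / nrow(design$K_test) * crossprod(design$K_test)
  (H + t(H)) / 2
}

#' Standardize features using training-sample statistics
#'
#' Optional pre-processing: centers and scales every feature by the training
#' block's mean and standard deviation, applying the same transform to the
#' test block. Off by default everywhere in the package; kernel distances are
#' otherwise computed on raw features.
#'
#' @param train,test Numeric matrices with matching columns.
#' @return List with standardized `train` and `test` matrices.
#' @export
standardize_features <- function(train, test) {
  train <- as_feature_matrix(train, "train")
  test <- as_feature_matrix(test, "test")
  if (ncol(train) != ncol(test)) abort_shape("`train` and `test` must share columns.")
  mu <- colMeans(train)
  sd <- apply(train, 2, stats::sd)
  sd[sd == 0] <- 1
  list(
    train = sweep(sweep(train, 2, mu), 2, sd, "/"),
    test = sweep(sweep(test, 2, mu), 2, sd, "/")
  )
}
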