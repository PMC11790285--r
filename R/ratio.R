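#' Closed-form L1 (least absolute deviation) coefficients
#'
#' Under the absolute-deviation loss the density-ratio coefficients have the
#' elementwise closed form \eqn{\hat\theta_l = 1 / (\alpha \hat h^{tr}_l +
#' (1-\alpha) \hat h^{te}_l)}: the reciprocal of the mixture kernel mean. No
#' matrix inversion is involved, which is what makes the L1 path cheap.
#'
#' @param h_tr,h_te Kernel mean vectors from [compute_h_vectors()].
#' @param alpha Mixing weight in [0, 1).
#' @return Numeric coefficient vector, strictly positive.
#' @export
solve_l1 <- function(h_tr, h_te, alpha) {
  alpha <- check_alpha(alpha)
  if (length(h_tr) != length(h_te)) {
    abort_shape("`h_tr` and `h_te` must have the same length.")
  }
  mix <- alpha * h_tr + (1 - alpha) * h_te
  if (any(!is.finite(mix)) || any(mix < 0)) {
    abort_degenerate("mixture kernel means must be strictly positive; input looks corrupted.")
  }
  # Gaussian kernel means are positive in exact arithmetic but can underflow
  # to 0 for centers isolated at small sigma; floor them so the reciprocal
  # stays finite (cross-validation then discards such widths on its own).
  1 / pmax(mix, .Machine$double.xmin)
}

#' Ridge-regularised L2 (least squares) coefficients
#'
#' Solves the normal equations \eqn{(\hat H + \lambda I)\theta = \hat
#' h^{tr}}, the unique minimiser of the regularised squared loss
#' \eqn{\frac{1}{2}\theta^\top \hat H \theta - \hat h^{tr\top}\theta +
#' \frac{\lambda}{2}\theta^\top\theta}. At `alpha = 0` (test-only `H`) this
#' is exactly the uLSIF estimator.
#'
#' @param H Symmetric Gram matrix from [compute_H_matrix()].
#' @param h_tr Training kernel mean vector.
#' @param lambda Non-negative ridge penalty.
#' @return Numeric coefficient vector (may contain negative entries; the
#'   estimator is unconstrained).
#' @export
solve_l2 <- function(H, h_tr, lambda) {
  lambda <- check_scalar(lambda, "lambda", lower = 0)
  if (!is.matrix(H) || nrow(H) != ncol(H)) abort_shape("`H` must be a square matrix.")
  if (length(h_tr) != nrow(H)) abort_shape("`h_tr` length must match `H`.")
  tryCatch(
    drop(solve(H + diag(lambda, nrow(H)), h_tr)),
    error = function(e) {
      abort_singular(paste0(
        "(H + lambda*I) is numerically singular; increase `lambda` above 0 ",
        "or remove duplicate kernel centers."
      ))
    }
  )
}

#' Plug-in L1 objective on held-out statistics
#'
#' The empirical absolute-deviation risk of a coefficient vector, up to the
#' constant that does not depend on theta:
#' \eqn{J_{L1} = 1 - \alpha \hat h^{tr\top}\theta - (1-\alpha)\hat
#' h^{te\top}\theta}. Used as the cross-validation criterion for the L1 path.
#'
#' @inheritParams solve_l1
#' @param theta Coefficient vector.
#' @return A single numeric score (smaller is better).
#' @export
l1_objective <- function(h_tr, h_te, theta, alpha) {
  alpha <- check_alpha(alpha)
  if (length(h_tr) != length(h_te) || length(theta) != length(h_tr)) {
    abort_shape("`h_tr`, `h_te` and `theta` must have equal lengths.")
  }
  1 - alpha * sum(h_tr * theta) - (1 - alpha) * sum(h_te * theta)
}

#' Held-out L2 objective
#'
#' The unregularised quadratic risk \eqn{\frac{1}{2}\theta^\top \hat H \theta
#' - \hat h^{tr\top}\theta}; the ridge term is excluded when scoring held-out
#' folds so that cross-validation compares predictive fit, not penalty.
#'
#' @inheritParams solve_l2
#' @param theta Coefficient vector.
#' @return A single numeric score (smaller is better).
#' @export
l2_objective <- function(H, h_tr, theta) {
  if (!is.matrix(H) || nrow(H) != ncol(H)) abort_shape("`H` must be a square matrix.")
  if (length(h_tr) != nrow(H) || length(theta) != nrow(H)) {
    abort_shape("`h_tr` and `theta` lengths must match `H`.")
  }
  0.5 * drop(crossprod(theta, H %*% theta)) - sum(h_tr * theta)
}

#' Construct a fitted density-ratio model
#'
#' Container for the Gaussian-kernel relative density-ratio estimator
#' \eqn{\hat w(x; \theta) = \sum_l \theta_l K_\sigma(x, c_l)} of
#' \eqn{w_\alpha(x) = p_{tr}(x) / (\alpha p_{tr}(x) + (1-\alpha) p_{te}(x))}.
#'
#' @param centers Kernel center matrix (nb x d).
#' @param sigma Positive kernel width.
#' @param theta Coefficient vector of length nb.
#' @param alpha Mixing weight in [0, 1).
#' @param loss `"L1"` or `"L2"` — how `theta` was learned.
#' @return An object of class `ratio_model`.
#' @export
ratio_model <- function(centers, sigma, theta, alpha, loss = c("L2", "L1")) {
  loss <- match.arg(loss)
  centers <- as_feature_matrix(centers, "centers")
  alpha <- check_alpha(alpha)
  sigma <- check_scalar(sigma, "sigma", lower = 0, strict_lower = TRUE)
  if (length(theta) != nrow(centers)) abort_shape("`theta` length must match the number of centers.")
  if (any(!is.finite(theta))) abort_degenerate("`theta` must be finite.")
  structure(
    list(centers = centers, sigma = sigma, theta = as.numeric(theta),
         alpha = alpha, loss = loss),
    class = "ratio_model"
  )
}

#' @export
print.ratio_model <- function(x, ...) {
  cat(sprintf(
    "<ratio_model> %s loss, %d Gaussian bases (d = %d), sigma = %.4g, alpha = %.3g\n",
    x$loss, nrow(x$centers), ncol(x$centers), x$sigma, x$alpha))
  invisible(x)
}

#' Evaluate a fitted density-ratio model
#'
#' Computes \eqn{\hat w(x_i; \theta)} for every row of `points`. Values are
#' strictly positive under L1 learning; under the unconstrained L2 estimator
#' they may be negative and are deliberately not clipped.
#'
#' @param model A [ratio_model()].
#' @param points Numeric matrix (m x d) of evaluation points.
#' @return Numeric vector of length m.
#' @export
estimate_ratio <- function(model, points) {
  if (!inherits(model, "ratio_model")) abort_shape("`model` must be a `ratio_model`.")
  K <- gaussian_kernel_matrix(points, model$centers, model$sigma)
  drop(K %*% model$theta)
}

#' @export
predict.ratio_model <- function(object, newdata, ...) {
  estimate_ratio(object, newdata)
}

#' Fit the density-ratio model at fixed hyperparameters
#'
#' One closed-form fit of theta on a train/test pair: the L1 path takes the
#' elementwise reciprocal of the mixture kernel means, the L2 path solves the
#' ridge normal equations.
#'
#' @param train,test Numeric matrices (rows are observations).
#' @param centers Kernel centers (rows drawn from the test sample; see
#'   [select_centers()]).
#' @param sigma Kernel width.
#' @param alpha Mixing weight in [0, 1).
#' @param loss `"L2"` (default) or `"L1"`.
#' @param lambda Ridge penalty (L2 only; ignored for L1).
#' @return A fitted [ratio_model()].
#' @export
fit_ratio <- function(train, test, centers, sigma, alpha,
                      loss = c("L2", "L1"), lambda = 0.1) {
  loss <- match.arg(loss)
  design <- kernel_design(train, test, centers, sigma)
  h <- compute_h_vectors(design)
  theta <- if (loss == "L1") {
    solve_l1(h$h_tr, h$h_te, alpha)
  } else {
    solve_l2(compute_H_matrix(design, alpha), h$h_tr, lambda)
  }
  ratio_model(centers, sigma, theta, alpha, loss)
}

#' Hyperparameter grids for cross-validation
#'
#' Defaults follow common practice for Gaussian-kernel ratio estimation: the
#' sigma grid is a set of multipliers of the median pairwise distance of the
#' pooled sample (the "median heuristic"), and the lambda grid spans five
#' decades. 50 basis functions and 5 folds are the package defaults.
#'
#' @param alpha Mixing weight in [0, 1).
#' @param sigma_grid Positive kernel widths to try, or `NULL` to derive the
#'   median-heuristic grid from the data at fit time.
#' @param lambda_grid Non-negative ridge penalties to try (L2 only).
#' @param folds Number of cross-validation folds (>= 2).
#' @param nb Number of Gaussian basis functions.
#' @return A `hyper_params` list.
#' @export
hyper_params <- function(alpha = 0.1, sigma_grid = NULL,
                         lambda_grid = 10^seq(-3, 1), folds = 5L, nb = 50L) {
  alpha <- check_alpha(alpha)
  folds <- check_scalar(folds, "folds", lower = 2, integerish = TRUE)
  nb <- check_scalar(nb, "nb", lower = 1, integerish = TRUE)
  if (!is.null(sigma_grid)) {
    if (length(sigma_grid) == 0 || any(sigma_grid <= 0)) {
      abort_parameter("`sigma_grid` must be non-empty and positive.")
    }
    sigma_grid <- sort(as.numeric(sigma_grid))
  }
  if (length(lambda_grid) == 0 || any(lambda_grid < 0)) {
    abort_parameter("`lambda_grid` must be non-empty and non-negative.")
  }
  structure(
    list(alpha = alpha, sigma_grid = sigma_grid,
         lambda_grid = sort(as.numeric(lambda_grid)),
         folds = folds, nb = nb),
    class = "hyper_params"
  )
}

# Median-heuristic sigma grid: multipliers of the median pairwise Euclidean
# distance of the pooled sample. Large samples are thinned deterministically
# (every k-th row) before the O(n^2) distance computation.
default_sigma_grid <- function(train, test,
                               multipliers = c(0.5, 0.75, 1, 1.25, 1.5, 2, 3, 4, 6),
                               max_points = 500L) {
  pooled <- rbind(as_feature_matrix(train, "train"), as_feature_matrix(test, "test"))
  if (nrow(pooled) > max_points) {
    pooled <- pooled[seq(1L, nrow(pooled), length.out = max_points), , drop = FALSE]
  }
  med <- stats::median(stats::dist(pooled))
  if (!is.finite(med) || med <= 0) med <- 1 # degenerate constant sample
  multipliers * med
}

#' Cross-validate the kernel width and ridge penalty
#'
#' k-fold cross-validation over the (sigma, lambda) grid. Training and test
#' rows are folded jointly (a seeded random permutation of each sample, split
#' as evenly as possible) so every held-out fold contains both training and
#' test points. For each candidate, theta is fitted on the retained folds
#' (by its configured loss) and scored on the held-out fold's kernel
#' statistics with the quadratic risk estimate [l2_objective()], which
#' measures how well the fitted ratio matches the relative density ratio on
#' unseen data regardless of the learning objective (the linear L1 plug-in
#' score is unbounded below and cannot rank kernel widths). The L1 solution
#' does not depend on lambda, so its lambda axis collapses to one candidate.
#' Ties
#' are broken towards the smaller sigma, then the smaller lambda, so the
#' selection is deterministic given the seed.
#'
#' @param train,test Numeric matrices (rows are observations).
#' @param hp A [hyper_params()] object.
#' @param loss `"L2"` or `"L1"`.
#' @param centers Optional fixed center matrix; if `NULL`, centers are drawn
#'   from `test` with [select_centers()].
#' @param seed Optional integer seed driving fold assignment (and center
#'   selection when `centers` is `NULL`).
#' @return A list with `sigma`, `lambda`, the `centers` used, and a tibble
#'   `cv_table` of mean held-out scores per grid point.
#' @export
cross_validate <- function(train, test, hp = hyper_params(),
                           loss = c("L2", "L1"), centers = NULL, seed = NULL) {
  loss <- match.arg(loss)
  train <- as_feature_matrix(train, "train")
  test <- as_feature_matrix(test, "test")
  if (!inherits(hp, "hyper_params")) abort_parameter("`hp` must be a `hyper_params` object.")
  ntr <- nrow(train); nte <- nrow(test)
  if (ntr < hp$folds || nte < hp$folds) {
    abort_parameter("each sample must have at least `folds` rows.")
  }
  with_seed_opt(seed, {
    if (is.null(centers)) centers <- select_centers(test, hp$nb)
    fold_tr <- sample(rep_len(seq_len(hp$folds), ntr))
    fold_te <- sample(rep_len(seq_len(hp$folds), nte))

    sigma_grid <- hp$sigma_grid %||% default_sigma_grid(train, test)
    lambda_grid <- if (loss == "L1") hp$lambda_grid[1] else hp$lambda_grid

    grid <- purrr::map_dfr(sigma_grid, function(sigma) {
      K_tr <- gaussian_kernel_matrix(train, centers, sigma)
      K_te <- gaussian_kernel_matrix(test, centers, sigma)
      scores <- purrr::map_dbl(lambda_grid, function(lambda) {
        fold_scores <- purrr::map_dbl(seq_len(hp$folds), function(f) {
          Ktr_fit <- K_tr[fold_tr != f, , drop = FALSE]
          Kte_fit <- K_te[fold_te != f, , drop = FALSE]
          Ktr_out <- K_tr[fold_tr == f, , drop = FALSE]
          Kte_out <- K_te[fold_te == f, , drop = FALSE]
          h_tr_fit <- colMeans(Ktr_fit); h_te_fit <- colMeans(Kte_fit)
          h_tr_out <- colMeans(Ktr_out); h_te_out <- colMeans(Kte_out)
          theta <- if (loss == "L1") {
            solve_l1(h_tr_fit, h_te_fit, hp$alpha)
          } else {
            H_fit <- hp$alpha * crossprod(Ktr_fit) / nrow(Ktr_fit) +
              (1 - hp$alpha) * crossprod(Kte_fit) / nrow(Kte_fit)
            solve_l2(H_fit, h_tr_fit, lambda)
          }
          # held-out quadratic risk of the fitted ratio for either loss; the
          # linear plug-in score is unbounded below and cannot rank sigma
          H_out <- hp$alpha * crossprod(Ktr_out) / nrow(Ktr_out) +
            (1 - hp$alpha) * crossprod(Kte_out) / nrow(Kte_out)
          l2_objective(H_out, h_tr_out, theta)
        })
        mean(fold_scores)
      })
      tibble::tibble(sigma = sigma, lambda = lambda_grid, score = scores)
    })
    best <- grid[order(grid$score, grid$sigma, grid$lambda), ][1, ]
    list(sigma = best$sigma, lambda = best$lambda, centers = centers,
         cv_table = tibble::as_tibble(grid))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
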