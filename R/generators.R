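# Seeded generators for the synthetic study designs. Every generator is a
# pure function of its parameters and seed and returns a labelled-series
# tibble: one row per observation, feature column(s), a 0/1 `label` column
# (1 = anomaly) and a `set` column marking the anomaly-free training block.

new_labeled_series <- function(values, labels, train_count) {
  values <- as_feature_matrix(values, "values")
  n <- nrow(values); d <- ncol(values)
  labels <- as.integer(labels)
  if (length(labels) != n) abort_shape("`labels` must match the number of rows.")
  train_count <- check_scalar(train_count, "train_count", lower = 1,
                              upper = n - 1, integerish = TRUE)
  if (any(labels[seq_len(train_count)] != 0L)) {
    abort_format("the training block must be anomaly-free (labels 0).")
  }
  colnames(values) <- if (d == 1) "value" else paste0("x", seq_len(d))
  out <- tibble::as_tibble(as.data.frame(values))
  out <- tibble::add_column(
    out,
    index = seq_len(n), .before = 1
  )
  out$label <- labels
  out$set <- ifelse(out$index <= train_count, "train", "test")
  attr(out, "train_count") <- train_count
  out
}

#' One-dimensional synthetic series with two point anomalies
#'
#' 300 observations: 298 draws from a standard normal \eqn{N(0,1)} plus two
#' injected anomalies with values 15 and 20, placed at indices 34 and 68 of
#' the 100-observation test block (global rows 234 and 268). The first 200
#' observations form the anomaly-free training block. This is the canonical
#' 1-D study design: the value-20 spike is the grosser anomaly, value 15 the
#' subtler one.
#'
#' @param seed Integer seed.
#' @return A labelled-series tibble (`index`, `value`, `label`, `set`) with a
#'   `train_count` attribute of 200.
#' @export
gen_dataset1 <- function(seed = 1L) {
  n <- 300L; train_count <- 200L
  anom_global <- train_count + c(34L, 68L)
  anom_value <- c(15, 20)
  values <- numeric(n)
  normal_idx <- setdiff(seq_len(n), anom_global)
  values[normal_idx] <- with_seed_opt(seed, stats::rnorm(n - 2L))
  values[anom_global] <- anom_value
  labels <- integer(n); labels[anom_global] <- 1L
  new_labeled_series(values, labels, train_count)
}

#' Two-dimensional synthetic series with two point anomalies
#'
#' 300 observations from a standard bivariate normal \eqn{N(0, I_2)}; the
#' anomalies sit at indices 40 and 80 of the 100-observation test block
#' (global rows 240 and 280) with both coordinates set to 10. Training block:
#' first 200 rows.
#'
#' @param seed Integer seed.
#' @return A labelled-series tibble (`index`, `x1`, `x2`, `label`, `set`).
#' @export
gen_dataset2 <- function(seed = 1L) {
  n <- 300L; train_count <- 200L
  anom_global <- train_count + c(40L, 80L)
  values <- matrix(0, n, 2L)
  normal_idx <- setdiff(seq_len(n), anom_global)
  values[normal_idx, ] <- with_seed_opt(seed, matrix(stats::rnorm(2L * (n - 2L)), ncol = 2L))
  values[anom_global, ] <- 10
  labels <- integer(n); labels[anom_global] <- 1L
  new_labeled_series(values, labels, train_count)
}

#' Periodic series with additive anomaly offsets
#'
#' Emulates a seasonal web-traffic-style series (the Yahoo-S5 A2 flavour): a
#' sinusoid of the given period and amplitude plus Gaussian noise, with
#' anomalies injected as additive offsets at listed indices. The defaults
#' mirror the layout used in the package's studies: 101 training points, 101
#' test points, and two clusters of three consecutive anomalous indices in
#' the test block.
#'
#' @param n Series length.
#' @param period Sinusoid period in observations (>= 2).
#' @param amplitude Sinusoid amplitude.
#' @param noise_sd Standard deviation of the additive Gaussian noise.
#' @param anomaly_spec Data frame with columns `index` (global row) and
#'   `offset` (additive shift); rows must fall inside the series and outside
#'   the training block.
#' @param train_count Length of the anomaly-free training block.
#' @param seed Integer seed.
#' @return A labelled-series tibble (`index`, `value`, `label`, `set`).
#' @export
gen_periodic <- function(n = 202L, period = 25L, amplitude = 10,
                         noise_sd = 0.5,
                         anomaly_spec = data.frame(
                           index = c(125:127, 160:162), offset = 30),
                         train_count = 101L, seed = 1L) {
  n <- check_scalar(n, "n", lower = 2, integerish = TRUE)
  period <- check_scalar(period, "period", lower = 2)
  noise_sd <- check_scalar(noise_sd, "noise_sd", lower = 0)
  idx <- seq_len(n)
  values <- amplitude * sin(2 * pi * idx / period)
  if (noise_sd > 0) {
    values <- values + with_seed_opt(seed, stats::rnorm(n, sd = noise_sd))
  }
  labels <- integer(n)
  if (!is.null(anomaly_spec) && nrow(anomaly_spec) > 0) {
    ai <- as.integer(anomaly_spec$index)
    if (any(ai < 1L | ai > n)) abort_parameter("anomaly indices must lie in [1, n].")
    values[ai] <- values[ai] + anomaly_spec$offset
    labels[ai] <- 1L
  }
  new_labeled_series(values, labels, train_count)
}

#' Tabular benchmark emulator with shifted anomalies
#'
#' Emulates the high-dimensional biomedical benchmark setup: normal samples
#' from a standard d-variate normal, anomalies from the same normal with
#' every coordinate's mean shifted by `shift`. The training block holds
#' `n_normal` normal rows; the test block holds another `n_normal` normal
#' rows plus `n_anomaly` anomalies, shuffled together. Defaults give a
#' 20% anomaly fraction in an 8-feature space, echoing the diabetes
#' benchmark's dimensionality.
#'
#' @param n_normal Normal sample size per block (train and test each).
#' @param n_anomaly Number of anomalies mixed into the test block.
#' @param d Feature dimensionality.
#' @param shift Mean shift of the anomalous distribution in every coordinate;
#'   `shift = 0` makes anomalies indistinguishable in distribution.
#' @param seed Integer seed.
#' @return A labelled-series tibble with feature columns `x1..xd`.
#' @export
gen_tabular <- function(n_normal = 100L, n_anomaly = 20L, d = 8L,
                        shift = 3, seed = 1L) {
  n_normal <- check_scalar(n_normal, "n_normal", lower = 1, integerish = TRUE)
  n_anomaly <- check_scalar(n_anomaly, "n_anomaly", lower = 0, integerish = TRUE)
  d <- check_scalar(d, "d", lower = 1, integerish = TRUE)
  shift <- check_scalar(shift, "shift", lower = 0)
  with_seed_opt(seed, {
    train <- matrix(stats::rnorm(n_normal * d), ncol = d)
    test_norm <- matrix(stats::rnorm(n_normal * d), ncol = d)
    test_anom <- matrix(stats::rnorm(n_anomaly * d, mean = shift), ncol = d)
    test <- rbind(test_norm, test_anom)
    lab_te <- c(integer(n_normal), rep(1L, n_anomaly))
    perm <- sample.int(nrow(test))
    new_labeled_series(rbind(train, test[perm, , drop = FALSE]),
                       c(integer(n_normal), lab_te[perm]), n_normal)
  })
}
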