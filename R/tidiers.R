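# broom-style tidiers and ggplot2 autoplot methods.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a detection: one row per window
#'
#' @param x A `plsbd_detection`.
#' @param ... Unused.
#' @return The window tibble (`window`, `start`, `end`, `score`,
#'   `normalized`, `flagged`).
#' @export
tidy.plsbd_detection <- function(x, ...) x$windows

#' One-row summary of a detection
#'
#' @param x A `plsbd_detection`.
#' @param ... Unused.
#' @return A one-row tibble with sample sizes, selected hyperparameters and
#'   flag counts.
#' @export
glance.plsbd_detection <- function(x, ...) {
  tibble::tibble(
    loss = x$config$loss, divergence = x$config$divergence,
    alpha = x$config$alpha, sigma = x$sigma, lambda = x$lambda,
    n_train = x$n_train, n_test = x$n_test,
    n_windows = nrow(x$windows), n_flagged = sum(x$windows$flagged),
    n_candidates = length(x$candidates),
    max_score = max(x$windows$score)
  )
}

#' Tidy repeated runs: per-observation flag frequencies
#'
#' @param x A `plsbd_detection_runs`.
#' @param ... Unused.
#' @return The frequency tibble (`index`, `count`, `freq`, `label`).
#' @export
tidy.plsbd_detection_runs <- function(x, ...) x$frequency

#' One-row summary of repeated runs
#'
#' @param x A `plsbd_detection_runs`.
#' @param ... Unused.
#' @return A one-row tibble with run count and candidate statistics.
#' @export
glance.plsbd_detection_runs <- function(x, ...) {
  tibble::tibble(
    runs = x$runs, loss = x$config$loss, divergence = x$config$divergence,
    alpha = x$config$alpha,
    n_ever_flagged = sum(x$frequency$count > 0),
    max_freq = max(x$frequency$freq)
  )
}

#' Plot normalised window scores with the detection threshold
#'
#' @param object A `plsbd_detection`.
#' @param ... Unused.
#' @return A ggplot: normalised score per window start, threshold line, and
#'   flagged windows highlighted.
#' @export
autoplot.plsbd_detection <- function(object, ...) {
  w <- object$windows
  ggplot2::ggplot(w, ggplot2::aes(x = .data$start, y = .data$normalized)) +
    ggplot2::geom_line(colour = "grey30") +
    ggplot2::geom_point(data = dplyr::filter(w, .data$flagged),
                        colour = "red", size = 2) +
    ggplot2::geom_hline(yintercept = object$config$tau, linetype = "dashed") +
    ggplot2::labs(x = "window start (test index)", y = "normalised score",
                  title = sprintf("%s + %s window scores",
                                  object$config$divergence, object$config$loss)) +
    ggplot2::theme_minimal()
}

#' Plot flag frequencies across repeated runs
#'
#' @param object A `plsbd_detection_runs`.
#' @param ... Unused.
#' @return A ggplot: per-observation flag count over runs, with true
#'   anomalies (if labels are known) marked by dashed vertical lines.
#' @export
autoplot.plsbd_detection_runs <- function(object, ...) {
  fr <- object$frequency
  p <- ggplot2::ggplot(fr, ggplot2::aes(x = .data$index, y = .data$count)) +
    ggplot2::geom_col(width = 0.8, fill = "grey20") +
    ggplot2::labs(x = "test observation index",
                  y = sprintf("flag count over %d runs", object$runs)) +
    ggplot2::theme_minimal()
  if (!all(is.na(fr$label)) && any(fr$label == 1, na.rm = TRUE)) {
    p <- p + ggplot2::geom_vline(xintercept = fr$index[fr$label == 1],
                                 colour = "red", linetype = "dashed")
  }
  p
}

#' Plot a labelled series
#'
#' @param series A labelled-series tibble from the generators or readers.
#' @return A ggplot of the first feature over the row index, anomalies in
#'   red, the train/test boundary dotted.
#' @export
plot_series <- function(series) {
  feat <- setdiff(names(series), c("index", "timestamp", "label", "set"))[1]
  boundary <- sum(series$set == "train") + 0.5
  ggplot2::ggplot(series, ggplot2::aes(x = .data$index, y = .data[[feat]])) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(data = dplyr::filter(series, .data$label == 1),
                        colour = "red", size = 2) +
    ggplot2::geom_vline(xintercept = boundary, linetype = "dotted") +
    ggplot2::labs(x = "index", y = feat) +
    ggplot2::theme_minimal()
}

#' Plot an ROC curve from an evaluation
#'
#' @param report A one-row tibble from [evaluate_detection()] (with a
#'   `roc_points` list column), or the list returned by [roc_auc()].
#' @return A ggplot of the ROC curve with the chance diagonal.
#' @export
plot_roc <- function(report) {
  pts <- if (is.data.frame(report) && "roc_points" %in% names(report)) {
    report$roc_points[[1]]
  } else if (is.list(report) && !is.null(report$roc_points)) {
    report$roc_points
  } else {
    abort_shape("`report` must carry `roc_points`.")
  }
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_step(colour = "steelblue") +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "false positive rate", y = "true positive rate") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
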