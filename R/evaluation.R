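#' ROC curve and AUC for observation-level anomaly scores
#'
#' Standard ROC over all score thresholds, with tied scores grouped into a
#' single threshold step, and the area under the curve by the trapezoid rule
#' (equivalent to the Mann-Whitney rank statistic: the probability that a
#' random anomaly outscores a random normal, ties counting one half).
#'
#' @param scores Numeric vector, one score per observation (higher = more
#'   anomalous).
#' @param labels 0/1 vector of the same length (1 = anomaly).
#' @return A list with `auc` and `roc_points`, a tibble of (`fpr`, `tpr`)
#'   pairs from (0, 0) to (1, 1), monotone in both coordinates.
#' @export
roc_auc <- function(scores, labels) {
  if (length(scores) != length(labels)) {
    abort_shape("`scores` and `labels` must have equal length.")
  }
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) abort_format("`labels` must be 0/1.")
  n_pos <- sum(labels == 1L); n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    abort_metric("ROC needs at least one normal and one anomalous observation.")
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  # collapse tied scores into single threshold steps
  last_of_group <- c(s[-1] != s[-length(s)], TRUE)
  tp <- cumsum(y)[last_of_group]
  fp <- cumsum(1L - y)[last_of_group]
  tpr <- c(0, tp / n_pos); fpr <- c(0, fp / n_neg)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(auc = auc, roc_points = tibble::tibble(fpr = fpr, tpr = tpr))
}

#' Map window scores to observation-level scores
#'
#' Each test observation inherits the maximum normalised score among the
#' windows covering it, giving an observation-granularity score vector that
#' an ROC can be drawn from. Observations covered by no window (possible in
#' the tail when `step > 1`) receive `-Inf`, ranking them least anomalous.
#'
#' @param detection A `plsbd_detection` from [detect_anomalies()] or
#'   [detect_windows()].
#' @return A tibble (`index`, `score`) over the test block, 1-based
#'   test-relative indices.
#' @export
observation_scores <- function(detection) {
  if (!inherits(detection, "plsbd_detection")) {
    abort_shape("`detection` must be a `plsbd_detection`.")
  }
  w <- detection$windows
  score <- rep(-Inf, detection$n_test)
  for (j in seq_len(nrow(w))) {
    idx <- w$start[j]:w$end[j]
    score[idx] <- pmax(score[idx], w$normalized[j])
  }
  tibble::tibble(index = seq_len(detection$n_test), score = score)
}

#' Threshold metrics with window-tolerant matching
#'
#' Confusion-matrix metrics where a true anomaly at test index i counts as
#' detected (TP) if any candidate falls in the tolerance interval
#' [i - window + 1, i] — the interval of window starts whose window covers i.
#' Candidates matching no true anomaly under the same tolerance are false
#' positives. Duplicated candidate indices are collapsed first. When a
#' metric's denominator is zero it is reported as 0 with a warning.
#'
#' @param candidates Integer vector of flagged observation indices (1-based,
#'   test-relative), e.g. `detection$candidates`.
#' @param labels 0/1 vector over the test block (1 = anomaly).
#' @param window Window size defining the matching tolerance (>= 1).
#' @return A one-row tibble: `tp`, `fp`, `fn`, `tn`, `accuracy`, `precision`,
#'   `recall`, `f1`, `detected_true_anomalies`, and a list column
#'   `false_positive_indices`.
#' @export
confusion_metrics <- function(candidates, labels, window = 3L) {
  window <- check_scalar(window, "window", lower = 1, integerish = TRUE)
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) abort_format("`labels` must be 0/1.")
  n <- length(labels)
  candidates <- sort(unique(as.integer(candidates)))
  if (any(candidates < 1L | candidates > n)) {
    abort_shape("`candidates` must be indices into `labels`.")
  }
  anomalies <- which(labels == 1L)
  detected <- vapply(anomalies, function(i) {
    any(candidates >= i - window + 1L & candidates <= i)
  }, logical(1))
  matched_cand <- vapply(candidates, function(cc) {
    any(anomalies >= cc & anomalies <= cc + window - 1L)
  }, logical(1))
  tp <- sum(detected)
  fn <- length(anomalies) - tp
  fp <- sum(!matched_cand)
  tn <- n - length(anomalies) - fp
  ratio0 <- function(num, den, name) {
    if (den == 0) {
      warning(sprintf("%s undefined (0/0); reported as 0.", name), call. = FALSE)
      0
    } else num / den
  }
  precision <- ratio0(tp, tp + fp, "precision")
  recall <- ratio0(tp, tp + fn, "recall")
  f1 <- ratio0(2 * precision * recall, precision + recall, "F1")
  tibble::tibble(
    tp = tp, fp = fp, fn = fn, tn = tn,
    accuracy = (tp + tn) / (tp + tn + fp + fn),
    precision = precision, recall = recall, f1 = f1,
    detected_true_anomalies = tp,
    false_positive_indices = list(candidates[!matched_cand])
  )
}

#' Evaluate a detection against its labels
#'
#' Convenience wrapper combining [observation_scores()], [roc_auc()] and
#' [confusion_metrics()] for a detection produced by [detect_anomalies()]
#' (which carries the test labels).
#'
#' @param detection A `plsbd_detection` with `test_labels` attached.
#' @param labels Optional 0/1 label vector overriding `detection$test_labels`.
#' @return A one-row tibble of metrics including `auc`, with the ROC points
#'   in a list column `roc_points`.
#' @export
evaluate_detection <- function(detection, labels = detection$test_labels) {
  if (is.null(labels)) abort_parameter("no labels available; supply `labels`.")
  roc <- roc_auc(observation_scores(detection)$score, labels)
  cm <- confusion_metrics(detection$candidates, labels, detection$config$window)
  cm$auc <- roc$auc
  cm$roc_points <- list(roc$roc_points)
  cm
}
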