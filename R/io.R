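# CSV readers and writers. Two dialects are supported: the Yahoo-S5-style
# time-series file (timestamp, value, is.anomaly) and a labelled feature
# matrix (numeric feature columns plus a +1/-1 label column). Readers reject
# incomplete rows rather than imputing: the method assumes complete data.

#' Read a Yahoo-S5-dialect time-series CSV
#'
#' Expects a header with columns `timestamp` (numeric, e.g. Unix time),
#' `value` (numeric) and `is.anomaly` (0/1). Rows are ordered by timestamp.
#' The file does not encode the train/test split, so the caller supplies
#' `train_count` (the first `train_count` ordered rows become the training
#' block and must be label-0).
#'
#' @param path Path to the CSV file.
#' @param train_count Number of leading (by timestamp) rows to treat as the
#'   anomaly-free training block.
#' @return A labelled-series tibble (`index`, `timestamp`, `value`, `label`,
#'   `set`).
#' @export
read_yahoo_csv <- function(path, train_count) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  for (col in c("timestamp", "value", "is.anomaly")) {
    if (!col %in% names(df)) {
      abort_format(sprintf("column `%s` is missing from %s.", col, path))
    }
  }
  bad <- which(is.na(df$timestamp) | is.na(df$value) | is.na(df$is.anomaly))
  if (length(bad) > 0) {
    abort_format(sprintf("missing value(s) in row(s) %s of %s; complete data are required.",
                         paste(utils::head(bad, 5), collapse = ", "), path))
  }
  if (!all(df$is.anomaly %in% c(0, 1))) {
    abort_format("`is.anomaly` must be binary 0/1.")
  }
  df <- df[order(df$timestamp), , drop = FALSE]
  out <- new_labeled_series(df$value, as.integer(df$is.anomaly), train_count)
  tibble::add_column(out, timestamp = df$timestamp, .after = "index")
}

#' Write a labelled series as a Yahoo-S5-dialect CSV
#'
#' Inverse of [read_yahoo_csv()] for one-dimensional series; the `timestamp`
#' column is the row index unless the series carries one.
#'
#' @param series A labelled-series tibble with a single `value` feature.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_yahoo_csv <- function(series, path) {
  if (!"value" %in% names(series)) {
    abort_shape("`series` must be one-dimensional (a `value` column).")
  }
  ts <- if ("timestamp" %in% names(series)) series$timestamp else series$index
  readr::write_csv(
    tibble::tibble(timestamp = ts, value = series$value,
                   `is.anomaly` = series$label),
    path)
  invisible(path)
}

#' Read a labelled feature-matrix CSV
#'
#' Expects numeric feature columns plus a label column coded +1 (normal) /
#' -1 (anomaly), the convention of the biomedical benchmark repositories.
#' Labels are recoded internally to 0 (normal) / 1 (anomaly).
#'
#' @param path Path to the CSV file.
#' @param label_column Name of the label column (default `"label"`).
#' @param train_count Number of leading rows forming the training block.
#' @return A labelled-series tibble with feature columns `x1..xd`.
#' @export
read_feature_csv <- function(path, label_column = "label", train_count) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!label_column %in% names(df)) {
    abort_format(sprintf("label column `%s` is missing from %s.", label_column, path))
  }
  lab_raw <- df[[label_column]]
  if (!all(lab_raw %in% c(-1, 1))) {
    abort_format(sprintf("label column `%s` must be coded +1 (normal) / -1 (anomaly).",
                         label_column))
  }
  feat <- df[setdiff(names(df), label_column)]
  for (j in seq_along(feat)) {
    if (!is.numeric(feat[[j]])) {
      abort_format(sprintf("non-numeric feature in column `%s` of %s.",
                           names(feat)[j], path))
    }
    if (anyNA(feat[[j]])) {
      abort_format(sprintf("missing value at row %d, column `%s` of %s.",
                           which(is.na(feat[[j]]))[1], names(feat)[j], path))
    }
  }
  new_labeled_series(as.matrix(feat), ifelse(lab_raw == -1, 1L, 0L), train_count)
}

#' Write a labelled series as a feature-matrix CSV
#'
#' Features are written as columns plus a `label` column coded +1 (normal) /
#' -1 (anomaly); inverse of [read_feature_csv()].
#'
#' @param series A labelled-series tibble.
#' @param path Output path.
#' @param label_column Name for the label column.
#' @return `path`, invisibly.
#' @export
write_feature_csv <- function(series, path, label_column = "label") {
  feat <- setdiff(names(series), c("index", "timestamp", "label", "set"))
  out <- series[feat]
  out[[label_column]] <- ifelse(series$label == 1L, -1L, 1L)
  readr::write_csv(out, path)
  invisible(path)
}

#' Write window scores and anomaly candidates to CSV
#'
#' Writes the per-window score table (`window_start`, `score`, `normalized`,
#' `flagged`) with numbers in a fixed 12-significant-digit format for
#' reproducible diffs, plus a companion `*_candidates.csv` listing the
#' flagged observation indices (1-based, test-relative). Output is bit-stable
#' across runs for identical inputs.
#'
#' @param detection A `plsbd_detection`.
#' @param path Output path for the score table; the candidates file is
#'   derived by inserting `_candidates` before the extension.
#' @return A character vector of the two paths written, invisibly.
#' @export
write_scores <- function(detection, path) {
  if (!inherits(detection, "plsbd_detection")) {
    abort_shape("`detection` must be a `plsbd_detection`.")
  }
  w <- detection$windows
  fmt <- function(x) ifelse(is.na(x), "NA", sprintf("%.12g", x))
  lines <- c(
    "window_start,score,normalized,flagged",
    sprintf("%d,%s,%s,%d", w$start, fmt(w$score), fmt(w$normalized),
            as.integer(w$flagged))
  )
  writeLines(lines, path)
  cand_path <- sub("(\\.[^.]+)?$", "_candidates\\1", path)
  writeLines(c("index", as.character(detection$candidates)), cand_path)
  invisible(c(path, cand_path))
}
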