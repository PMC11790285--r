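# Internal helpers: argument checking, error classes, seed scoping.
#
# Error subclasses let callers distinguish bad parameters from malformed
# shapes or files: plsbd_error_parameter, plsbd_error_shape,
# plsbd_error_format, plsbd_error_singular, plsbd_error_degenerate,
# plsbd_error_metric, plsbd_error_inconsistent.

abort_parameter <- function(msg) rlang::abort(msg, class = "plsbd_error_parameter")
abort_shape     <- function(msg) rlang::abort(msg, class = "plsbd_error_shape")
abort_format    <- function(msg) rlang::abort(msg, class = "plsbd_error_format")
abort_singular  <- function(msg) rlang::abort(msg, class = "plsbd_error_singular")
abort_degenerate <- function(msg) rlang::abort(msg, class = "plsbd_error_degenerate")
abort_metric    <- function(msg) rlang::abort(msg, class = "plsbd_error_metric")
abort_inconsistent <- function(msg) rlang::abort(msg, class = "plsbd_error_inconsistent")

# Coerce vectors / data frames to a numeric matrix; missing values are
# rejected (the method assumes complete data).
as_feature_matrix <- function(x, arg = "x") {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.vector(x) && is.numeric(x)) x <- matrix(x, ncol = 1L)
  if (!is.matrix(x) || !is.numeric(x)) {
    abort_shape(sprintf("`%s` must be a numeric vector, matrix or data frame.", arg))
  }
  if (nrow(x) < 1L) abort_shape(sprintf("`%s` must contain at least one row.", arg))
  if (anyNA(x) || any(!is.finite(x))) {
    abort_format(sprintf("`%s` contains missing or non-finite values; complete data are required.", arg))
  }
  x
}

check_alpha <- function(alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) ||
      alpha < 0 || alpha >= 1) {
    abort_parameter("`alpha` must be a single number in [0, 1).")
  }
  as.numeric(alpha)
}

check_scalar <- function(x, arg, lower = -Inf, upper = Inf,
                         integerish = FALSE, strict_lower = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) &&
    (if (strict_lower) x > lower else x >= lower) && x <= upper &&
    (!integerish || x == round(x))
  if (!ok) {
    abort_parameter(sprintf("`%s` must be a single %s in %s%s, %s].",
                            arg, if (integerish) "integer" else "number",
                            if (strict_lower) "(" else "[",
                            format(lower), format(upper)))
  }
  if (integerish) as.integer(x) else as.numeric(x)
}

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# random state; seed = NULL leaves the current stream untouched.
with_seed_opt <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}
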