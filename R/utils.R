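#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive an independent RNG substream seed from a master seed and a label
#'
#' Each synthetic dataset draws from its own substream so that, e.g.,
#' enlarging the calibration design never perturbs the incurred-sample
#' stream. The label is hashed with a small multiplicative scheme that is
#' stable across platforms (integer arithmetic kept below 2^31 throughout).
#'
#' @param seed integer master seed.
#' @param label character scalar naming the dataset/stream.
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' substream_seed(1, "calibration")
substream_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label))
  m <- 2147483647 # 2^31 - 1, prime
  h <- 0
  for (ch in utf8ToInt(label)) h <- (h * 31 + ch) %% m
  as.integer(((seed %% m) * 48271 + h) %% m)
}

#' @noRd
assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                 strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  if (strict_lower && x <= lower) {
    stop(sprintf("`%s` must be > %s", name, lower), call. = FALSE)
  }
  if (!strict_lower && x < lower) {
    stop(sprintf("`%s` must be >= %s", name, lower), call. = FALSE)
  }
  if (x > upper) {
    stop(sprintf("`%s` must be <= %s", name, upper), call. = FALSE)
  }
  invisible(x)
}

#' @noRd
assert_columns <- function(df, cols, name = deparse(substitute(df))) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop(sprintf("`%s` is missing column(s): %s", name,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}

#' Format a measurement as "value +/- U (k = 2)"
#'
#' The expanded uncertainty is rounded to two significant figures and the
#' value to the same decimal place; internal values keep full precision.
#'
#' @param x measured value.
#' @param U expanded uncertainty (same units).
#' @param k coverage factor used to obtain `U`.
#' @return a character scalar.
#' @export
format_measurement <- function(x, U, k = 2) {
  U2 <- signif(U, 2)
  digits <- max(0, -floor(log10(U2)) + 1)
  sprintf("%s ± %s (k = %d)",
          formatC(round(x, digits), format = "f", digits = digits),
          formatC(U2, format = "f", digits = digits), k)
}
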