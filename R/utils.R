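#' Unscaled median absolute deviation
#'
#' The robust spread statistic used throughout this package:
#' \code{median(|x - median(x)|)}, with no consistency factor. This is the
#' convention paired with medians in contact-site literature, where the MAD
#' of a quantity is reported on the same scale as the quantity itself.
#'
#' @param x numeric vector.
#' @param na.rm drop \code{NA} values first.
#' @return A single number, the unscaled MAD.
#' @examples
#' mad_unscaled(c(10, 20, 30)) # 10
#' @export
mad_unscaled <- function(x, na.rm = FALSE) {
  if (na.rm) x <- x[!is.na(x)]
  stats::median(abs(x - stats::median(x)))
}

#' Median and unscaled MAD summary
#'
#' @param x numeric vector.
#' @return Named list with \code{median}, \code{mad} (unscaled) and \code{n}.
#' @export
median_mad <- function(x) {
  list(median = stats::median(x), mad = mad_unscaled(x), n = length(x))
}

stop_mcsarch <- function(msg, class) {
  stop(structure(
    class = c(class, "mcsarch_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

check_finite_coords <- function(m, what = "coordinates") {
  if (!all(is.finite(m))) {
    stop_mcsarch(sprintf("non-finite %s", what), "invalid_input_error")
  }
  invisible(TRUE)
}

check_unit_vector <- function(v, tol = 1e-6, what = "vector") {
  if (length(v) != 3L || !all(is.finite(v))) {
    stop_mcsarch(sprintf("%s must be a finite 3-vector", what),
                 "invalid_input_error")
  }
  n <- sqrt(sum(v^2))
  if (abs(n - 1) > tol) {
    stop_mcsarch(sprintf("%s is not a unit vector (|v| = %.8g)", what, n),
                 "invalid_input_error")
  }
  invisible(TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic sub-seed derivation: one seeded generator per call, with
# sub-streams derived from (seed, index) kept below 2^31.
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(index) * 16807) %%
               2147483647)
}
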