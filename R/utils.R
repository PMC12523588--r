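#' Round half away from zero
#'
#' Decimal rounding with ties going up (0.125 -> 0.13 at 2 digits), the
#' convention used in the printed tables this package reproduces. Base R's
#' `round()` rounds half to even, which differs on exact ties.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 2).
#' @return Rounded numeric vector.
#' @export
#' @examples
#' round_half_up(1.525)   # 1.53
#' round(1.525, 2)        # 1.52 on most platforms
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Admissible Saaty judgment values
#'
#' The 17 admissible values of the 9-point ratio scale used for pairwise
#' comparisons: 1/9, 1/8, ..., 1/2, 1, 2, ..., 9.
#'
#' @return Sorted numeric vector of length 17.
#' @export
saaty_scale <- function() {
  sort(c(1 / (9:2), 1, 2:9))
}

#' Snap ratios to the nearest Saaty value
#'
#' Maps positive ratios to the nearest admissible scale value, with
#' "nearest" measured in log space so that e.g. 2.9 and 1/2.9 snap to
#' reciprocal values.
#'
#' @param x Positive numeric vector of judgment ratios.
#' @return Numeric vector with every element in `saaty_scale()`.
#' @export
snap_to_saaty <- function(x) {
  stopifnot(is.numeric(x), all(x > 0))
  s <- saaty_scale()
  s[apply(abs(outer(log(x), log(s), "-")), 1, which.min)]
}

# internal: stop with a consistent message prefix
abort_mcda <- function(...) stop(..., call. = FALSE)

# internal: check a scalar probability-like value
check_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    abort_mcda(sprintf("`%s` must be a single number in [0, 1], got %s",
                       name, paste(format(x), collapse = ", ")))
  }
  invisible(x)
}
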