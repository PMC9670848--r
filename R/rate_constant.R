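#' Rate constant with 1-sigma uncertainty and units
#'
#' Light container for a (pseudo-)first- or second-order rate constant.
#' Units are restricted to the three used throughout the chamber and fate
#' analyses; conversions between `"s-1"` and `"day-1"` use exactly
#' 86400 s per day.
#'
#' @param value Numeric scalar, the rate constant.
#' @param sigma Non-negative numeric scalar, the 1-sigma standard
#'   uncertainty. All uncertainties in this package are stored as 1-sigma;
#'   doubling for 2-sigma display is the caller's concern.
#' @param units One of `"cm3 molecule-1 s-1"` (second order, gas phase),
#'   `"s-1"` or `"day-1"` (first order).
#' @return An object of class `rate_constant`: a list with elements
#'   `value`, `sigma` and `units`.
#' @examples
#' k <- rate_constant(4.67e-12, 0.36e-12, "cm3 molecule-1 s-1")
#' convert_rate(rate_constant(5.3e-6, units = "s-1"), "day-1")
#' @export
rate_constant <- function(value, sigma = 0,
                          units = c("cm3 molecule-1 s-1", "s-1", "day-1")) {
  units <- match.arg(units)
  stopifnot(is.numeric(value), length(value) == 1L, is.finite(value),
            is.numeric(sigma), length(sigma) == 1L, is.finite(sigma))
  if (sigma < 0) stop("'sigma' must be >= 0")
  structure(list(value = value, sigma = sigma, units = units),
            class = "rate_constant")
}

SECONDS_PER_DAY <- 86400

#' Convert a first-order rate constant between s-1 and day-1
#'
#' @param k A [rate_constant()] with units `"s-1"` or `"day-1"`.
#' @param to Target units, `"s-1"` or `"day-1"`.
#' @return A `rate_constant` in the requested units; value and sigma are
#'   both scaled by exactly 86400.
#' @export
convert_rate <- function(k, to = c("day-1", "s-1")) {
  to <- match.arg(to)
  stopifnot(inherits(k, "rate_constant"))
  if (k$units == "cm3 molecule-1 s-1")
    stop("second-order rate constants have no day-1 equivalent; ",
         "multiply by an oxidant concentration first (see pseudo_first_order)")
  if (k$units == to) return(k)
  fac <- if (to == "day-1") SECONDS_PER_DAY else 1 / SECONDS_PER_DAY
  rate_constant(k$value * fac, k$sigma * fac, to)
}

#' @export
print.rate_constant <- function(x, ...) {
  cat(sprintf("<rate constant> %.4g +/- %.3g %s (1 sigma)\n",
              x$value, x$sigma, x$units))
  invisible(x)
}

#' Inverse-variance weighted average of rate constants
#'
#' Combines independent determinations of the same rate constant using
#' inverse-variance weights \eqn{w_i = 1/\sigma_i^2}; the combined value is
#' \eqn{\sum w_i v_i / \sum w_i} and its standard uncertainty
#' \eqn{(\sum w_i)^{-1/2}}. This is how the chamber study's per-reference
#' determinations are pooled into a single recommended value.
#'
#' @param values A non-empty list of [rate_constant()] objects, all in the
#'   same units, all with `sigma > 0` (a zero sigma would carry infinite
#'   weight and is rejected).
#' @return A single `rate_constant`.
#' @examples
#' ks <- lapply(list(c(4.40, 0.53), c(5.17, 0.70), c(4.63, 0.71)),
#'              function(p) rate_constant(p[1] * 1e-12, p[2] * 1e-12))
#' weighted_average(ks)  # 4.67 +/- 0.36 x 10^-12
#' @export
weighted_average <- function(values) {
  if (!is.list(values) || length(values) == 0L)
    stop("'values' must be a non-empty list of rate_constant objects")
  ok <- vapply(values, inherits, logical(1), "rate_constant")
  if (!all(ok)) stop("all elements must be rate_constant objects")
  units <- unique(vapply(values, `[[`, character(1), "units"))
  if (length(units) != 1L)
    stop("mixed units in weighted_average: ", paste(units, collapse = ", "))
  v <- vapply(values, `[[`, numeric(1), "value")
  s <- vapply(values, `[[`, numeric(1), "sigma")
  if (any(s <= 0))
    stop("all sigmas must be > 0 to form inverse-variance weights")
  w <- 1 / s^2
  rate_constant(sum(w * v) / sum(w), 1 / sqrt(sum(w)), units)
}
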