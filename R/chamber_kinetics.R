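#' Chamber decay series
#'
#' One compound's concentration-time trace from a smog-chamber run (or a
#' synthetic equivalent). The first sample defines the reference point
#' \eqn{t_0} and \eqn{C_0} used by all log-depletion constructions.
#'
#' @param compound_id Character label for the compound.
#' @param times Numeric vector of sampling times in seconds, strictly
#'   increasing, at least 3 points.
#' @param concentrations Numeric vector of concentrations in
#'   molecule cm-3, same length as `times`, all strictly positive.
#' @return An object of class `decay_series`.
#' @export
decay_series <- function(compound_id, times, concentrations) {
  stopifnot(is.character(compound_id), length(compound_id) == 1L)
  times <- as.numeric(times)
  concentrations <- as.numeric(concentrations)
  if (length(times) != length(concentrations))
    stop("'times' and 'concentrations' must have equal length")
  if (length(times) < 3L)
    stop("a decay series needs at least 3 points, got ", length(times))
  if (any(!is.finite(times)) || any(!is.finite(concentrations)))
    stop("non-finite values in decay series")
  if (any(diff(times) <= 0))
    stop("'times' must be strictly increasing")
  if (any(concentrations <= 0))
    stop("all concentrations must be > 0 (log-depletion analysis)")
  structure(list(compound_id = compound_id, times = times,
                 concentrations = concentrations),
            class = "decay_series")
}

#' @export
print.decay_series <- function(x, ...) {
  cat(sprintf("<decay series> %s: %d points, t = %g..%g s, C0 = %.3g molecule cm-3\n",
              x$compound_id, length(x$times), x$times[1],
              x$times[length(x$times)], x$concentrations[1]))
  invisible(x)
}

#' Reference compound for relative-rate work
#'
#' A compound with a recommended OH rate constant, used as the kinetic
#' yardstick in relative-rate experiments. The recommended values carry a
#' relative uncertainty (default 10%) that is propagated into every derived
#' second-order rate constant.
#'
#' @param name Character label.
#' @param k_ref Second-order OH rate constant, cm3 molecule-1 s-1, > 0.
#' @param rel_unc Relative 1-sigma uncertainty of `k_ref`, in `[0, 1)`.
#' @return An object of class `reference_compound`.
#' @seealso [reference_compounds()] for the built-in table.
#' @export
reference_compound <- function(name, k_ref, rel_unc = 0.10) {
  stopifnot(is.character(name), length(name) == 1L,
            is.numeric(k_ref), length(k_ref) == 1L,
            is.numeric(rel_unc), length(rel_unc) == 1L)
  if (k_ref <= 0) stop("'k_ref' must be > 0")
  if (rel_unc < 0 || rel_unc >= 1) stop("'rel_unc' must be in [0, 1)")
  structure(list(name = name, k_ref = k_ref, rel_unc = rel_unc),
            class = "reference_compound")
}

#' Built-in reference compounds
#'
#' Recommended OH rate constants for the three reference compounds used in
#' the chamber study: dimethyl ether (DME, 2.83e-12), cyclohexane
#' (CyHex, 6.38e-12) and para-benzoquinone (p-Bq, 4.60e-12), all in
#' cm3 molecule-1 s-1, each with a 10% recommended-value uncertainty.
#'
#' @param name Optional: return just one compound by name (`"DME"`,
#'   `"CyHex"`, `"p-Bq"`).
#' @return A named list of [reference_compound()] objects, or a single one
#'   if `name` is given.
#' @export
reference_compounds <- function(name = NULL) {
  tbl <- list(
    DME     = reference_compound("DME",     2.83e-12),
    CyHex   = reference_compound("CyHex",   6.38e-12),
    `p-Bq`  = reference_compound("p-Bq",    4.60e-12)
  )
  if (is.null(name)) return(tbl)
  if (!name %in% names(tbl))
    stop("unknown reference compound '", name, "'; available: ",
         paste(names(tbl), collapse = ", "))
  tbl[[name]]
}

#' Fit a single first-order loss process
#'
#' Ordinary least squares of \eqn{\ln(C_0/C_t)} against \eqn{t - t_0} with
#' a free intercept. This is how chamber wall-loss and 254 nm photolysis
#' constants are measured: in the absence of chemistry the log-depletion is
#' linear in time with slope equal to the first-order loss constant. The
#' intercept is left free so that a mis-specified \eqn{t_0} biases the
#' intercept, not the slope; on clean data it is ~0.
#'
#' @param series A [decay_series()].
#' @return An object of class `first_order_fit` with elements `k_loss`
#'   (s-1), `sigma_k` (1-sigma standard error of the slope, s-1),
#'   `intercept`, `n_points` and `r_squared`.
#' @examples
#' t <- seq(0, 900, by = 60)
#' s <- decay_series("X", t, 5e13 * exp(-5e-4 * t))
#' fit_first_order_loss(s)$k_loss  # 5e-4
#' @export
fit_first_order_loss <- function(series) {
  stopifnot(inherits(series, "decay_series"))
  dt <- series$times - series$times[1]
  y <- log(series$concentrations[1] / series$concentrations)
  fit <- stats::lm(y ~ dt)
  sm <- suppressWarnings(summary(fit))  # perfect synthetic fits are fine
  r2 <- if (all(abs(y - y[1]) < .Machine$double.eps * 100)) 1 else sm$r.squared
  structure(list(k_loss = unname(stats::coef(fit)[2]),
                 sigma_k = unname(sm$coefficients[2, "Std. Error"]),
                 intercept = unname(stats::coef(fit)[1]),
                 n_points = length(dt),
                 r_squared = r2),
            class = "first_order_fit")
}

#' @export
print.first_order_fit <- function(x, ...) {
  cat(sprintf("<first-order loss> k = %.4g +/- %.3g s-1 (1 sigma), n = %d, R2 = %.4f\n",
              x$k_loss, x$sigma_k, x$n_points, x$r_squared))
  invisible(x)
}

#' Wall-loss-corrected log depletion
#'
#' The relative-rate construction requires the chemical part of the
#' depletion only, so any independently measured first-order loss (wall
#' loss, photolysis) is subtracted from the raw log depletion:
#' \eqn{y(t) = \ln(C_0/C_t) - k_{extra}(t - t_0)}. By construction
#' \eqn{y(t_0) = 0}.
#'
#' @param series A [decay_series()].
#' @param k_extra Non-negative first-order constant to subtract, s-1.
#' @return A data frame with columns `time_s` (original clock) and `y`
#'   (corrected log depletion, dimensionless).
#' @export
corrected_log_loss <- function(series, k_extra = 0) {
  stopifnot(inherits(series, "decay_series"),
            is.numeric(k_extra), length(k_extra) == 1L, is.finite(k_extra))
  if (k_extra < 0) stop("'k_extra' must be >= 0")
  dt <- series$times - series$times[1]
  y <- log(series$concentrations[1] / series$concentrations) - k_extra * dt
  data.frame(time_s = series$times, y = y)
}

#' Relative-rate regression of target against reference depletion
#'
#' Both compounds see the same OH history, so after wall-loss correction
#' their log depletions obey
#' \deqn{\ln([T]_0/[T]_t) - k_{WL,T}(t-t_0) =
#'   \frac{k_T}{k_{ref}} \left[\ln([R]_0/[R]_t) - k_{WL,R}(t-t_0)\right]}
#' for any OH time profile. The slope of the OLS line (free intercept) of
#' target vs reference corrected depletion is the rate-constant ratio
#' \eqn{k_T/k_{ref}}; its standard error is the 1-sigma ratio uncertainty.
#'
#' The two series must share sample times: they are matched by exact
#' timestamp intersection, never interpolated.
#'
#' @param target,reference [decay_series()] objects sampled on a common
#'   time grid (at least 3 shared timestamps).
#' @param k_wl_target,k_wl_reference Independently measured first-order
#'   wall-loss constants, s-1 (reference default 0: typically only the
#'   target shows wall loss).
#' @return An object of class `relative_rate_fit` with `slope`,
#'   `sigma_slope`, `intercept`, `r_squared`, `n_points`.
#' @export
relative_rate_fit <- function(target, reference,
                              k_wl_target = 0, k_wl_reference = 0) {
  stopifnot(inherits(target, "decay_series"),
            inherits(reference, "decay_series"))
  common <- intersect(target$times, reference$times)
  if (length(common) < 3L)
    stop("target and reference share only ", length(common),
         " timestamps; need >= 3 common sample times (no interpolation is done)")
  common <- sort(common)
  sub <- function(s) {
    i <- match(common, s$times)
    decay_series(s$compound_id, s$times[i], s$concentrations[i])
  }
  yt <- corrected_log_loss(sub(target), k_wl_target)$y
  yr <- corrected_log_loss(sub(reference), k_wl_reference)$y
  if (max(abs(yr)) < 1e-12)
    stop("reference series shows no depletion after correction; ",
         "the relative-rate fit is degenerate")
  fit <- stats::lm(yt ~ yr)
  sm <- suppressWarnings(summary(fit))  # noise-free pairs fit exactly
  structure(list(slope = unname(stats::coef(fit)[2]),
                 sigma_slope = unname(sm$coefficients[2, "Std. Error"]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = sm$r.squared,
                 n_points = length(common)),
            class = "relative_rate_fit")
}

#' Construct a relative-rate result from a known ratio
#'
#' Wraps an already-determined rate-constant ratio (e.g. a published slope
#' with its regression uncertainty) in the same container that
#' [relative_rate_fit()] returns, so it can flow into
#' [ratio_to_rate_constant()] and [reference_consistency_check()].
#'
#' @param slope Dimensionless rate-constant ratio.
#' @param sigma_slope 1-sigma uncertainty of the ratio (default 0).
#' @return A `relative_rate_fit` object (with `intercept`, `r_squared`,
#'   `n_points` set to `NA`).
#' @export
rate_ratio <- function(slope, sigma_slope = 0) {
  stopifnot(is.numeric(slope), length(slope) == 1L,
            is.numeric(sigma_slope), length(sigma_slope) == 1L)
  if (sigma_slope < 0) stop("'sigma_slope' must be >= 0")
  structure(list(slope = slope, sigma_slope = sigma_slope,
                 intercept = NA_real_, r_squared = NA_real_,
                 n_points = NA_integer_),
            class = "relative_rate_fit")
}

#' @export
print.relative_rate_fit <- function(x, ...) {
  cat(sprintf("<relative-rate fit> slope = %.4g +/- %.3g (1 sigma)",
              x$slope, x$sigma_slope))
  if (!is.na(x$r_squared))
    cat(sprintf(", intercept = %.3g, R2 = %.5f, n = %d",
                x$intercept, x$r_squared, x$n_points))
  cat("\n")
  invisible(x)
}

#' Convert a rate-constant ratio into a second-order rate constant
#'
#' Multiplies the fitted ratio by the reference compound's recommended rate
#' constant and propagates both the regression uncertainty and the
#' recommended-value uncertainty in quadrature:
#' \deqn{k = slope \cdot k_{ref}, \qquad
#'   \sigma_k = k \sqrt{(\sigma_{slope}/slope)^2 + relunc^2}}
#' so the derived constant can never be more certain than the reference it
#' leans on.
#'
#' @param fit A `relative_rate_fit` (from [relative_rate_fit()] or
#'   [rate_ratio()]) with `slope > 0`.
#' @param ref A [reference_compound()].
#' @return A [rate_constant()] in cm3 molecule-1 s-1.
#' @examples
#' ratio_to_rate_constant(rate_ratio(0.81, 0.07), reference_compounds("CyHex"))
#' @export
ratio_to_rate_constant <- function(fit, ref) {
  stopifnot(inherits(fit, "relative_rate_fit"),
            inherits(ref, "reference_compound"))
  if (fit$slope <= 0)
    stop("ratio must be > 0 to convert to a rate constant (got ",
         fit$slope, ")")
  value <- fit$slope * ref$k_ref
  sigma <- value * sqrt((fit$sigma_slope / fit$slope)^2 + ref$rel_unc^2)
  rate_constant(value, sigma, "cm3 molecule-1 s-1")
}

#' Consistency check of a measured reference-vs-reference ratio
#'
#' Control experiments measure one reference compound against another; the
#' fitted ratio should agree with the ratio of the recommended rate
#' constants. Returns the relative deviation
#' \eqn{|measured - k_a/k_b| / (k_a/k_b)} alongside the literature ratio.
#'
#' @param fit A `relative_rate_fit` of compound `ref_a` measured relative
#'   to compound `ref_b`.
#' @param ref_a,ref_b [reference_compound()] objects (numerator and
#'   denominator of the literature ratio).
#' @return A list with `measured`, `literature` and `deviation`.
#' @examples
#' refs <- reference_compounds()
#' reference_consistency_check(rate_ratio(1.95, 0.23),
#'                             refs$CyHex, refs$DME)
#' @export
reference_consistency_check <- function(fit, ref_a, ref_b) {
  stopifnot(inherits(fit, "relative_rate_fit"),
            inherits(ref_a, "reference_compound"),
            inherits(ref_b, "reference_compound"))
  lit <- ref_a$k_ref / ref_b$k_ref
  list(measured = fit$slope,
       literature = lit,
       deviation = abs(fit$slope - lit) / lit)
}
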