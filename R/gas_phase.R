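#' Default 24 h average tropospheric OH concentration
#'
#' The canonical global-average OH radical concentration used for lifetime
#' estimates, 1.13e6 molecule cm-3. Exposed as a function so that the
#' value is citable and overridable rather than buried in defaults.
#'
#' @return Numeric scalar, molecule cm-3.
#' @export
oh_24h_average <- function() 1.13e6

#' Pseudo-first-order gas-phase loss rate
#'
#' Multiplies a second-order rate constant by a quasi-constant oxidant
#' concentration to give the effective first-order loss rate
#' \eqn{k_g = k_2 [OH]}, returned in s-1 (use [convert_rate()] for the
#' day-1 view used by the fate model).
#'
#' @param k2 Second-order rate constant, cm3 molecule-1 s-1, > 0. A bare
#'   numeric or a [rate_constant()] (whose sigma is scaled along).
#' @param oh OH concentration, molecule cm-3, >= 0
#'   (default [oh_24h_average()]).
#' @return A [rate_constant()] in s-1.
#' @examples
#' k <- pseudo_first_order(4.7e-12)     # 5.3e-6 s-1
#' convert_rate(k, "day-1")             # 0.46 day-1
#' @export
pseudo_first_order <- function(k2, oh = oh_24h_average()) {
  sig <- 0
  if (inherits(k2, "rate_constant")) {
    if (k2$units != "cm3 molecule-1 s-1")
      stop("'k2' must be a second-order rate constant (cm3 molecule-1 s-1)")
    sig <- k2$sigma
    k2 <- k2$value
  }
  stopifnot(is.numeric(k2), length(k2) == 1L,
            is.numeric(oh), length(oh) == 1L)
  if (k2 <= 0) stop("'k2' must be > 0")
  if (oh < 0) stop("'oh' must be >= 0")
  rate_constant(k2 * oh, sig * oh, "s-1")
}

#' Atmospheric lifetime against OH oxidation
#'
#' The e-folding lifetime \eqn{\tau = 1/(k_2 [OH])}, the exact reciprocal
#' of [pseudo_first_order()], expressed in days.
#'
#' @inheritParams pseudo_first_order
#' @return Lifetime in days (numeric scalar).
#' @examples
#' atmospheric_lifetime(4.67e-12)  # ~2.2 days
#' atmospheric_lifetime(2.91e-12)  # ~3.5 days
#' @export
atmospheric_lifetime <- function(k2, oh = oh_24h_average()) {
  if (inherits(k2, "rate_constant")) k2 <- k2$value
  stopifnot(is.numeric(k2), length(k2) == 1L,
            is.numeric(oh), length(oh) == 1L)
  if (k2 <= 0) stop("'k2' must be > 0")
  if (oh <= 0)
    stop("lifetime is unbounded at zero OH concentration; ",
         "supply oh > 0 or treat the compound as inert")
  1 / (k2 * oh) / SECONDS_PER_DAY
}

#' TME ozonolysis OH source description
#'
#' Dark ozonolysis of 2,3-dimethyl-2-butene (tetramethylethylene, TME)
#' produces OH radicals with a yield Y close to unity, and TME itself is
#' the dominant OH sink; the balance of production against loss fixes a
#' steady-state OH level that depends on ozone but not on TME.
#'
#' @param o3 Ozone concentration in the reactor, molecule cm-3, >= 0.
#' @param yield_Y OH yield per TME + O3 reaction, in (0, 1]; default 1.
#' @param k_tme_o3 Rate constant of TME + O3, cm3 molecule-1 s-1
#'   (default 1.1e-15).
#' @param k_tme_oh Rate constant of TME + OH, cm3 molecule-1 s-1
#'   (default 1.1e-10).
#' @param extra_scavenging Dimensionless ratio of any additional
#'   pseudo-first-order OH sinks to the TME sink (default 0: TME dominates).
#' @return An object of class `tme_source`.
#' @export
tme_source <- function(o3, yield_Y = 1, k_tme_o3 = 1.1e-15,
                       k_tme_oh = 1.1e-10, extra_scavenging = 0) {
  stopifnot(is.numeric(o3), length(o3) == 1L,
            is.numeric(yield_Y), is.numeric(k_tme_o3),
            is.numeric(k_tme_oh), is.numeric(extra_scavenging))
  if (o3 < 0) stop("'o3' must be >= 0")
  if (yield_Y <= 0 || yield_Y > 1) stop("'yield_Y' must be in (0, 1]")
  if (k_tme_o3 <= 0 || k_tme_oh <= 0) stop("rate constants must be > 0")
  if (extra_scavenging < 0) stop("'extra_scavenging' must be >= 0")
  structure(list(o3 = o3, yield_Y = yield_Y, k_tme_o3 = k_tme_o3,
                 k_tme_oh = k_tme_oh, extra_scavenging = extra_scavenging),
            class = "tme_source")
}

#' Steady-state OH concentration from TME ozonolysis
#'
#' Balancing OH production \eqn{Y k_{O_3}[O_3][TME]} against OH loss on
#' TME (plus optional extra sinks) gives
#' \deqn{[OH]_{ss} = \frac{Y \, k_{TME+O_3} \, [O_3]}
#'       {k_{TME+OH} (1 + s)}}
#' where \eqn{s} is the extra-scavenging ratio. [TME] cancels, so the
#' level is linear in ozone and in the yield, and monotone decreasing in
#' the scavenging term.
#'
#' @param src A [tme_source()].
#' @return Steady-state OH concentration, molecule cm-3.
#' @examples
#' oh_steady_state(tme_source(o3 = 4.92e13))  # ~4.9e8
#' @export
oh_steady_state <- function(src) {
  stopifnot(inherits(src, "tme_source"))
  src$yield_Y * src$k_tme_o3 * src$o3 /
    (src$k_tme_oh * (1 + src$extra_scavenging))
}
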