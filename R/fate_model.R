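#' Two-media fate scenario
#'
#' The five (pseudo-)first-order rate constants of the surface-water +
#' atmosphere reaction network: ibuprofen (IBP) degrades in water with
#' overall constant `k_d`, a fraction of which (`k_f`) forms the
#' photoproduct IBAP; aqueous IBAP is destroyed photochemically (`k_d_prime`)
#' or volatilizes (`k_vol`); gas-phase IBAP is removed by OH (`k_g`).
#' All constants are in day-1.
#'
#' @param k_d Overall IBP aqueous photodegradation constant, >= 0.
#' @param k_f IBAP formation constant from IBP, `0 <= k_f <= k_d` (the
#'   formation channel is part of the overall loss, so the branching
#'   fraction `k_f/k_d` cannot exceed 1).
#' @param k_d_prime Overall IBAP aqueous photodegradation constant, >= 0.
#' @param k_vol IBAP volatilization constant, >= 0.
#' @param k_g Gas-phase IBAP + OH pseudo-first-order constant, >= 0.
#' @param pathway_split Optional named list or vector partitioning
#'   `k_d_prime` into aqueous pathways `k_OH_w` (OH radicals), `k_3CDOM`
#'   (excited triplet dissolved organic matter) and `k_dp` (direct
#'   photolysis); the components must sum to `k_d_prime` (1e-9 relative).
#' @return An object of class `fate_scenario`.
#' @seealso [load_scenario()] for the built-in fast/slow parameter sets.
#' @export
fate_scenario <- function(k_d, k_f, k_d_prime, k_vol, k_g,
                          pathway_split = NULL) {
  ks <- c(k_d = k_d, k_f = k_f, k_d_prime = k_d_prime,
          k_vol = k_vol, k_g = k_g)
  stopifnot(is.numeric(ks), all(is.finite(ks)))
  if (any(ks < 0)) stop("all rate constants must be >= 0")
  if (k_f > k_d * (1 + 1e-12))
    stop("'k_f' must not exceed 'k_d' (formation is a branch of the ",
         "overall IBP loss)")
  if (!is.null(pathway_split)) {
    pathway_split <- unlist(pathway_split)
    need <- c("k_OH_w", "k_3CDOM", "k_dp")
    if (!setequal(names(pathway_split), need))
      stop("'pathway_split' must have exactly the components ",
           paste(need, collapse = ", "))
    pathway_split <- pathway_split[need]
    if (any(pathway_split < 0)) stop("pathway rates must be >= 0")
    tot <- sum(pathway_split)
    if (abs(tot - k_d_prime) > 1e-9 * max(k_d_prime, 1e-300))
      stop("pathway_split components sum to ", tot,
           " but k_d_prime = ", k_d_prime)
  }
  structure(list(k_d = k_d, k_f = k_f, k_d_prime = k_d_prime,
                 k_vol = k_vol, k_g = k_g,
                 pathway_split = pathway_split),
            class = "fate_scenario")
}

#' @export
print.fate_scenario <- function(x, ...) {
  cat(sprintf(paste0("<fate scenario> k_d = %g, k_f = %g, k_d' = %g, ",
                     "k_vol = %g, k_g = %g day-1\n"),
              x$k_d, x$k_f, x$k_d_prime, x$k_vol, x$k_g))
  if (!is.null(x$pathway_split))
    cat("  aqueous split:",
        paste(sprintf("%s = %g", names(x$pathway_split), x$pathway_split),
              collapse = ", "), "day-1\n")
  invisible(x)
}

# (exp(-a*t) - exp(-b*t)) / (b - a), computed without cancellation;
# exact limit t*exp(-a*t) as b -> a.
.exp_diff_ratio <- function(a, b, t) {
  d <- b - a
  if (abs(d) < 1e-9) t * exp(-a * t)
  else exp(-a * t) * (-expm1(-d * t)) / d
}

#' Aqueous IBP time trend
#'
#' Simple first-order disappearance of the parent compound:
#' \eqn{[IBP_w](t)/[IBP_w]_0 = e^{-k_d t}}.
#'
#' @param s A [fate_scenario()].
#' @param t Time(s) in days, >= 0 (vectorized).
#' @return Fraction(s) of the initial aqueous IBP concentration.
#' @export
ibp_water <- function(s, t) {
  stopifnot(inherits(s, "fate_scenario"), is.numeric(t))
  if (any(t < 0)) stop("'t' must be >= 0")
  exp(-s$k_d * t)
}

#' Aqueous IBAP time trend
#'
#' The intermediate of the chain: formed from IBP at rate `k_f`, removed
#' with total constant \eqn{K = k_{vol} + k_d'}. The closed form is
#' \deqn{\frac{[IBAP_w](t)}{[IBP_w]_0} =
#'   \frac{k_f}{K - k_d}\left(e^{-k_d t} - e^{-K t}\right)}
#' evaluated through a cancellation-free `expm1` construction; in the
#' degenerate limit \eqn{K \to k_d} it becomes \eqn{k_f t e^{-k_d t}}.
#'
#' @inheritParams ibp_water
#' @return Fraction(s) of the initial aqueous IBP concentration.
#' @export
ibap_water <- function(s, t) {
  stopifnot(inherits(s, "fate_scenario"), is.numeric(t))
  if (any(t < 0)) stop("'t' must be >= 0")
  K <- s$k_vol + s$k_d_prime
  s$k_f * .exp_diff_ratio(s$k_d, K, t)
}

#' Gas-phase IBAP time trend
#'
#' The third member of the chain: fed by volatilization of aqueous IBAP
#' and removed by gas-phase OH. With eigenvalues
#' \eqn{\lambda = (k_d, K, k_g)}, \eqn{K = k_{vol} + k_d'}, the
#' three-exponential solution is
#' \deqn{\frac{[IBAP_g](t)}{[IBP_w]_0} = k_f k_{vol}
#'   \sum_{i=1}^{3} \frac{e^{-\lambda_i t}}
#'        {\prod_{j \ne i} (\lambda_j - \lambda_i)}}
#' (the classical sequential-decay chain solution). When any two
#' eigenvalues are closer than 1e-3 day-1 the partial-fraction sum loses
#' precision, and the value is computed instead from the exact matrix
#' exponential of the network's rate matrix.
#'
#' @inheritParams ibp_water
#' @return Fraction(s) of the initial aqueous IBP concentration.
#' @export
ibap_gas <- function(s, t) {
  stopifnot(inherits(s, "fate_scenario"), is.numeric(t))
  if (any(t < 0)) stop("'t' must be >= 0")
  if (s$k_vol == 0 || s$k_f == 0) return(rep(0, length(t)))
  lam <- c(s$k_d, s$k_vol + s$k_d_prime, s$k_g)
  gaps <- abs(c(lam[1] - lam[2], lam[1] - lam[3], lam[2] - lam[3]))
  if (min(gaps) < 1e-3) return(.ibap_gas_expm(s, t))
  pre <- s$k_f * s$k_vol
  terms <- vapply(1:3, function(i) {
    others <- lam[-i]
    exp(-lam[i] * t) / prod(others - lam[i])
  }, numeric(length(t)))
  if (length(t) == 1L) pre * sum(terms) else pre * rowSums(terms)
}

# Exact solution through the matrix exponential of the (lower-triangular)
# rate matrix; handles repeated or nearly repeated eigenvalues without
# cancellation.
.ibap_gas_expm <- function(s, t) {
  M <- rbind(c(-s$k_d,               0,                          0),
             c( s$k_f,  -(s$k_vol + s$k_d_prime),                0),
             c(      0,   s$k_vol,                          -s$k_g))
  vapply(t, function(ti) as.matrix(Matrix::expm(M * ti))[3, 1], numeric(1))
}

#' Fate summary fractions
#'
#' Time-integrated bookkeeping of the network:
#' * `f = k_f / k_d` — the fraction of degraded IBP that is converted to
#'   IBAP (the formation yield).
#' * `v = k_vol / (k_vol + k_d_prime)` — the fraction of aqueous IBAP
#'   removal that proceeds by volatilization rather than aqueous
#'   photodegradation.
#' * `pathway_fractions` — if the scenario carries a `pathway_split`, the
#'   fraction of IBAP degraded by each process \eqn{j}:
#'   \eqn{F_j = k_j / (k_{OH_w} + k_{3CDOM} + k_{dp} + k_{vol})}, with
#'   `volatilization` identically equal to `v`. The four fractions sum
#'   to 1.
#'
#' @param s A [fate_scenario()] with `k_d > 0` and
#'   `k_vol + k_d_prime > 0`.
#' @return A list with `f`, `v` and `pathway_fractions` (the latter `NULL`
#'   with a message-free pass when the scenario has no pathway split).
#' @examples
#' fractions(load_scenario("fast"))$v   # ~0.115
#' fractions(load_scenario("slow"))$v   # ~0.634
#' @export
fractions <- function(s) {
  stopifnot(inherits(s, "fate_scenario"))
  if (s$k_d <= 0) stop("'k_d' must be > 0 to define the formation yield f")
  K <- s$k_vol + s$k_d_prime
  if (K <= 0) stop("'k_vol + k_d_prime' must be > 0 to define v")
  f <- s$k_f / s$k_d
  v <- s$k_vol / K
  pf <- NULL
  if (!is.null(s$pathway_split)) {
    rates <- c(s$pathway_split, volatilization = unname(s$k_vol))
    pf <- rates / sum(rates)
  }
  list(f = f, v = v, pathway_fractions = pf)
}

#' Numerical integration of the fate network
#'
#' Solves the three coupled linear ODEs of the network with a stiff-safe
#' solver (`deSolve::ode`, lsoda, tight tolerances). This is the package's
#' independent ground truth for the closed-form trend functions and is
#' used as such throughout the test suite.
#'
#' @param s A [fate_scenario()].
#' @param t_grid Sorted non-negative times in days.
#' @param rtol,atol Solver tolerances (defaults 1e-10 / 1e-12).
#' @return A data frame with columns `time_d`, `ibp_w`, `ibap_w`,
#'   `ibap_g`, all as fractions of the initial aqueous IBP concentration.
#' @export
simulate_ode <- function(s, t_grid, rtol = 1e-10, atol = 1e-12) {
  stopifnot(inherits(s, "fate_scenario"), is.numeric(t_grid))
  if (any(t_grid < 0)) stop("'t_grid' must be non-negative")
  if (is.unsorted(t_grid, strictly = TRUE))
    stop("'t_grid' must be strictly increasing")
  K <- s$k_vol + s$k_d_prime
  deriv <- function(t, y, p) {
    list(c(-s$k_d * y[1],
           s$k_f * y[1] - K * y[2],
           s$k_vol * y[2] - s$k_g * y[3]))
  }
  times <- t_grid
  prepend0 <- FALSE
  if (times[1] > 0) {            # lsoda needs the initial time in the grid
    times <- c(0, times)
    prepend0 <- TRUE
  }
  sol <- deSolve::ode(y = c(1, 0, 0), times = times, func = deriv,
                      parms = NULL, method = "lsoda",
                      rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1] < 0)
    stop("ODE solver failed for scenario: ",
         paste(utils::capture.output(print(s)), collapse = " "))
  sol <- as.data.frame(sol)
  if (prepend0) sol <- sol[-1, , drop = FALSE]
  data.frame(time_d = sol[[1]], ibp_w = sol[[2]],
             ibap_w = sol[[3]], ibap_g = sol[[4]], row.names = NULL)
}

#' Closed-form time trends of the fate network
#'
#' Evaluates [ibp_water()], [ibap_water()] and [ibap_gas()] on a time
#' grid. Gas-phase levels are typically orders of magnitude below the
#' aqueous ones (plots conventionally scale them up for display).
#'
#' @inheritParams simulate_ode
#' @return A data frame with columns `time_d`, `ibp_w`, `ibap_w`,
#'   `ibap_g` (fractions of the initial aqueous IBP concentration).
#' @examples
#' trends(load_scenario("slow"), t_grid = seq(0, 300, by = 10))
#' @export
trends <- function(s, t_grid) {
  stopifnot(inherits(s, "fate_scenario"), is.numeric(t_grid))
  if (any(t_grid < 0)) stop("'t_grid' must be non-negative")
  data.frame(time_d = t_grid,
             ibp_w = ibp_water(s, t_grid),
             ibap_w = ibap_water(s, t_grid),
             ibap_g = ibap_gas(s, t_grid))
}
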