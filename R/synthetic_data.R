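#' Recipe for a synthetic relative-rate chamber experiment
#'
#' Describes the generating process for a target/reference compound pair
#' exposed to the same OH history in a chamber: per-compound first-order
#' depletion by OH (with a possibly time-varying OH profile) plus wall
#' loss on the target, sampled at a fixed cadence with multiplicative
#' lognormal measurement noise. Spectroscopy-derived concentrations are
#' positive and analyzed on a log scale, which is what a mean-one
#' lognormal error model reflects.
#'
#' @param true_ratio Generating rate-constant ratio
#'   `k_target / k_reference`, > 0.
#' @param k_ref_oh Reference compound's OH rate constant,
#'   cm3 molecule-1 s-1 (default: the DME recommendation, 2.83e-12).
#' @param oh_profile OH concentration, molecule cm-3: either a scalar
#'   (constant exposure) or a vector with one value per sampling interval
#'   (piecewise constant), to exercise time-varying exposure.
#' @param k_wl_target First-order wall-loss constant of the target, s-1
#'   (default 3.1e-4, a typical measured chamber value for a sticky
#'   semivolatile; references are assumed wall-loss free).
#' @param duration Experiment length, s (default 1800: a ~40% total
#'   conversion at typical exposures).
#' @param sample_interval Sampling cadence, s (default 60: one spectrum
#'   per minute).
#' @param noise_cv Coefficient of variation of the multiplicative
#'   lognormal noise (default 0.02).
#' @param c0_target,c0_reference Initial concentrations, molecule cm-3
#'   (defaults 5e13 and 6e13, typical chamber loadings).
#' @param seed Integer seed; generation is deterministic given the seed.
#' @return An object of class `chamber_recipe`.
#' @export
chamber_recipe <- function(true_ratio, k_ref_oh = 2.83e-12,
                           oh_profile = 2e8, k_wl_target = 3.1e-4,
                           duration = 1800, sample_interval = 60,
                           noise_cv = 0.02, c0_target = 5e13,
                           c0_reference = 6e13, seed = 1L) {
  stopifnot(is.numeric(true_ratio), length(true_ratio) == 1L,
            is.numeric(oh_profile), is.numeric(k_wl_target),
            is.numeric(duration), is.numeric(sample_interval),
            is.numeric(noise_cv))
  if (true_ratio <= 0) stop("'true_ratio' must be > 0")
  if (k_ref_oh <= 0) stop("'k_ref_oh' must be > 0")
  if (any(oh_profile < 0)) stop("'oh_profile' must be >= 0")
  if (k_wl_target < 0) stop("'k_wl_target' must be >= 0")
  if (sample_interval <= 0) stop("'sample_interval' must be > 0")
  if (duration < 2 * sample_interval)
    stop("'duration' must cover at least 2 sampling intervals")
  if (noise_cv < 0) stop("'noise_cv' must be >= 0")
  structure(list(true_ratio = true_ratio, k_ref_oh = k_ref_oh,
                 oh_profile = oh_profile, k_wl_target = k_wl_target,
                 duration = duration, sample_interval = sample_interval,
                 noise_cv = noise_cv, c0_target = c0_target,
                 c0_reference = c0_reference, seed = as.integer(seed)),
            class = "chamber_recipe")
}

# run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# mean-one multiplicative lognormal factors with coefficient of variation cv
.lognormal_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Generate a synthetic target/reference chamber pair
#'
#' Integrates the generating kinetics exactly: with OH exposure integral
#' \eqn{E(t) = \int_0^t [OH](u)\,du} (closed form for constant or
#' piecewise-constant profiles),
#' \deqn{\ln C_T(t) = \ln C_{T,0} - r\, k_{ref} E(t) - k_{WL,T}\, t,
#'  \qquad \ln C_R(t) = \ln C_{R,0} - k_{ref} E(t)}
#' where \eqn{r} is the true ratio. i.i.d. mean-one lognormal noise is
#' then applied multiplicatively to both series. At `noise_cv = 0` the
#' pair is the exact inverse test surface of [relative_rate_fit()]: the
#' fitted slope equals the generating ratio to machine precision for any
#' OH profile.
#'
#' @param r A [chamber_recipe()].
#' @return A list with elements `target` and `reference`
#'   ([decay_series()] objects) and the echoed `recipe`.
#' @examples
#' pair <- generate_chamber_pair(chamber_recipe(true_ratio = 1.55,
#'                                              noise_cv = 0, seed = 7))
#' relative_rate_fit(pair$target, pair$reference,
#'                   k_wl_target = 3.1e-4)$slope  # 1.55
#' @export
generate_chamber_pair <- function(r) {
  stopifnot(inherits(r, "chamber_recipe"))
  times <- seq(0, r$duration, by = r$sample_interval)
  n_int <- length(times) - 1L
  oh <- r$oh_profile
  if (length(oh) == 1L) oh <- rep(oh, n_int)
  if (length(oh) != n_int)
    stop("'oh_profile' must be scalar or have one value per sampling ",
         "interval (", n_int, "), got ", length(oh))
  exposure <- c(0, cumsum(oh * r$sample_interval))  # E(t), molecule cm-3 s
  log_ct <- log(r$c0_target) - r$true_ratio * r$k_ref_oh * exposure -
    r$k_wl_target * times
  log_cr <- log(r$c0_reference) - r$k_ref_oh * exposure
  noise <- .with_seed(r$seed,
                      .lognormal_noise(2 * length(times), r$noise_cv))
  ct <- exp(log_ct) * noise[seq_along(times)]
  cr <- exp(log_cr) * noise[length(times) + seq_along(times)]
  list(target = decay_series("target", times, ct),
       reference = decay_series("reference", times, cr),
       recipe = r)
}

#' Generate noisy fate-model observations
#'
#' Evaluates the closed-form [trends()] on a grid and applies i.i.d.
#' mean-one multiplicative lognormal noise to the three concentration
#' columns, emulating monitoring data for end-to-end recovery tests
#' (e.g. re-fitting `k_d` from the parent decay).
#'
#' @param s A [fate_scenario()].
#' @param t_grid Non-negative times, days.
#' @param noise_cv Lognormal coefficient of variation (default 0.05).
#' @param seed Integer seed.
#' @return A data frame like [trends()] with noise applied
#'   (`noise_cv = 0` returns the exact trends).
#' @export
generate_fate_observations <- function(s, t_grid, noise_cv = 0.05,
                                       seed = 1L) {
  tr <- trends(s, t_grid)
  if (noise_cv == 0) return(tr)
  noise <- .with_seed(seed, .lognormal_noise(3 * nrow(tr), noise_cv))
  n <- nrow(tr)
  tr$ibp_w <- tr$ibp_w * noise[1:n]
  tr$ibap_w <- tr$ibap_w * noise[n + 1:n]
  tr$ibap_g <- tr$ibap_g * noise[2 * n + 1:n]
  tr
}
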