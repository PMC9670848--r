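test_that("decay_series rejects malformed inputs", {
  expect_error(decay_series("X", c(0, 60), c(1e13, 9e12)), "at least 3")
  expect_error(decay_series("X", c(0, 60, 60), rep(1e13, 3)),
               "strictly increasing")
  expect_error(decay_series("X", c(0, 60, 120), c(1e13, 0, 9e12)), "> 0")
  expect_error(decay_series("X", c(0, 60, 120), c(1e13, NA, 9e12)),
               "non-finite")
})

test_that("first-order loss fit recovers exact and trivial kinetics", {
  t <- seq(0, 900, by = 60)

  flat <- fit_first_order_loss(decay_series("flat", t, rep(4e13, length(t))))
  expect_identical(flat$k_loss, 0)
  expect_equal(flat$r_squared, 1)

  k_true <- 5e-4
  fit <- fit_first_order_loss(
    decay_series("exp", t, 5e13 * exp(-k_true * t)))
  expect_equal(fit$k_loss, k_true, tolerance = 1e-12)
  expect_lt(abs(fit$intercept), 1e-12)
  expect_equal(fit$n_points, 16L)
})

test_that("wall-loss constant is recovered from a noisy synthetic run", {
  # pure wall-loss chamber run: no OH exposure, 2% measurement noise
  pair <- generate_chamber_pair(chamber_recipe(
    true_ratio = 1, oh_profile = 0, k_wl_target = 3.1e-4,
    duration = 29 * 60, sample_interval = 60, noise_cv = 0.02, seed = 42))
  fit <- fit_first_order_loss(pair$target)
  expect_equal(fit$n_points, 30L)
  expect_lt(abs(fit$k_loss - 3.1e-4), 2 * fit$sigma_k)
})

test_that("corrected log depletion subtracts exactly what it is told", {
  t <- seq(0, 1200, by = 60)
  k_wl <- 3.1e-4
  s_wl <- decay_series("wl", t, 5e13 * exp(-k_wl * t))

  raw <- corrected_log_loss(s_wl, k_extra = 0)
  expect_equal(raw$y, log(5e13 / s_wl$concentrations))
  expect_identical(raw$y[1], 0)

  cancelled <- corrected_log_loss(s_wl, k_extra = k_wl)
  expect_lt(max(abs(cancelled$y)), 1e-12)

  # combined OH-equivalent + wall loss: correction leaves the chemical slope
  k_chem <- 2e-4
  s_both <- decay_series("both", t, 5e13 * exp(-(k_chem + k_wl) * t))
  y <- corrected_log_loss(s_both, k_extra = k_wl)
  slope <- coef(lm(y$y ~ y$time_s))[[2]]
  expect_equal(slope, k_chem, tolerance = 1e-10)

  expect_error(corrected_log_loss(s_wl, k_extra = -1e-5), ">= 0")
})

test_that("relative-rate regression returns the rate-constant ratio", {
  t <- seq(0, 1800, by = 60)
  ref <- decay_series("ref", t, 6e13 * exp(-4e-4 * t))

  self <- relative_rate_fit(ref, ref)
  expect_equal(self$slope, 1, tolerance = 1e-12)
  expect_lt(abs(self$intercept), 1e-12)

  pair <- generate_chamber_pair(chamber_recipe(true_ratio = 1.55,
                                               noise_cv = 0, seed = 1))
  fit <- relative_rate_fit(pair$target, pair$reference,
                           k_wl_target = pair$recipe$k_wl_target)
  expect_equal(fit$slope, 1.55, tolerance = 1e-12)
  expect_lt(abs(fit$intercept), 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
})

test_that("relative-rate slope is invariant to the OH time profile", {
  mk <- function(profile) {
    pair <- generate_chamber_pair(chamber_recipe(
      true_ratio = 0.45, oh_profile = profile, k_wl_target = 3.1e-4,
      duration = 1200, noise_cv = 0, seed = 1))
    relative_rate_fit(pair$target, pair$reference,
                      k_wl_target = 3.1e-4)$slope
  }
  constant <- mk(2e8)
  ramping <- mk(seq(5e7, 4e8, length.out = 20))
  bursty <- mk(rep(c(0, 6e8), 10))
  expect_equal(ramping, constant, tolerance = 1e-12)
  expect_equal(bursty, constant, tolerance = 1e-12)
  expect_equal(constant, 0.45, tolerance = 1e-12)
})

test_that("noisy relative-rate fit recovers the generating ratio", {
  pair <- generate_chamber_pair(chamber_recipe(
    true_ratio = 0.45, duration = 24 * 60, noise_cv = 0.02, seed = 99))
  fit <- relative_rate_fit(pair$target, pair$reference,
                           k_wl_target = pair$recipe$k_wl_target)
  expect_equal(fit$n_points, 25L)
  expect_lt(abs(fit$slope - 0.45), 2 * fit$sigma_slope)
})

test_that("relative-rate fit detects degenerate inputs", {
  t <- seq(0, 600, by = 60)
  dec <- decay_series("a", t, 5e13 * exp(-3e-4 * t))
  flat <- decay_series("b", t, rep(6e13, length(t)))
  expect_error(relative_rate_fit(dec, flat), "no depletion")

  shifted <- decay_series("c", t + 7, 5e13 * exp(-3e-4 * t))
  expect_error(relative_rate_fit(dec, shifted), "common sample times")
})

test_that("ratio-to-rate-constant conversion propagates both uncertainties", {
  refs <- reference_compounds()

  k <- ratio_to_rate_constant(rate_ratio(0.81, 0.07), refs$CyHex)
  expect_equal(k$value, 5.1678e-12, tolerance = 1e-10)
  expect_equal(k$sigma, 0.683018e-12, tolerance = 1e-5)

  ident <- ratio_to_rate_constant(rate_ratio(1, 0),
                                  reference_compound("u", 3e-12, rel_unc = 0))
  expect_equal(ident$value, 3e-12)
  expect_identical(ident$sigma, 0)

  hand <- ratio_to_rate_constant(rate_ratio(2, 0.2),
                                 reference_compound("w", 1e-12))
  expect_equal(hand$value, 2e-12)
  expect_equal(hand$sigma, 2e-12 * sqrt(0.01 + 0.01), tolerance = 1e-12)

  expect_error(ratio_to_rate_constant(rate_ratio(1), refs$DME),
               NA)  # valid baseline
  expect_error(ratio_to_rate_constant(
    structure(list(slope = -0.1, sigma_slope = 0.01),
              class = "relative_rate_fit"), refs$DME), "> 0")
})

test_that("derived rate constants are never more certain than the reference", {
  refs <- reference_compounds()
  for (slope in c(0.3, 0.81, 1.55, 4)) {
    for (se in c(0, 0.02, 0.3)) {
      k <- ratio_to_rate_constant(rate_ratio(slope, se), refs$DME)
      expect_gte(k$sigma / k$value, refs$DME$rel_unc - 1e-12)
    }
  }
})

test_that("inverse-variance weighted average pools independent estimates", {
  mk <- function(v, s) rate_constant(v * 1e-12, s * 1e-12)

  pooled <- weighted_average(list(mk(4.40, 0.53), mk(5.17, 0.70),
                                  mk(4.63, 0.71)))
  expect_equal(pooled$value, 4.667345e-12, tolerance = 1e-6)
  expect_equal(pooled$sigma, 0.363108e-12, tolerance = 1e-6)

  single <- weighted_average(list(mk(3.1, 0.2)))
  expect_equal(single$value, 3.1e-12)
  expect_equal(single$sigma, 0.2e-12)

  twin <- weighted_average(list(mk(2, 0.4), mk(2, 0.4)))
  expect_equal(twin$value, 2e-12)
  expect_equal(twin$sigma, 0.4e-12 / sqrt(2))

  expect_error(weighted_average(list()), "non-empty")
  expect_error(weighted_average(list(mk(2, 0), mk(3, 0.1))), "> 0")
  expect_error(weighted_average(list(
    rate_constant(1, 0.1, "s-1"), rate_constant(2, 0.1, "day-1"))),
    "mixed units")
})

test_that("weighted average stays inside the input range with smaller sigma", {
  set.seed(7)
  for (i in 1:25) {
    n <- sample(2:6, 1)
    v <- runif(n, 1, 10)
    s <- runif(n, 0.1, 2)
    pooled <- weighted_average(mapply(rate_constant, v, s,
                                      SIMPLIFY = FALSE))
    expect_gte(pooled$value, min(v))
    expect_lte(pooled$value, max(v))
    expect_lte(pooled$sigma, min(s) + 1e-12)
  }
})

test_that("reference consistency check compares to the literature ratio", {
  refs <- reference_compounds()
  chk <- reference_consistency_check(rate_ratio(1.95, 0.23),
                                     refs$CyHex, refs$DME)
  expect_equal(chk$literature, 6.38 / 2.83, tolerance = 1e-12)
  expect_equal(chk$deviation, abs(1.95 - 6.38 / 2.83) / (6.38 / 2.83),
               tolerance = 1e-12)
  expect_lt(chk$deviation, 0.15)  # the control-test acceptability bound

  exact <- reference_consistency_check(rate_ratio(6.38 / 2.83),
                                       refs$CyHex, refs$DME)
  expect_equal(exact$deviation, 0)
})
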