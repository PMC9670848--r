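fast <- load_scenario("fast")
slow <- load_scenario("slow")

test_that("aqueous parent follows simple exponential decay", {
  expect_equal(ibp_water(fast, 0), 1)
  expect_equal(ibp_water(fast, log(2) / fast$k_d), 0.5, tolerance = 1e-12)
  expect_equal(ibp_water(slow, 50), exp(-1), tolerance = 1e-12)
  expect_error(ibp_water(fast, -1), ">= 0")
})

test_that("aqueous intermediate has the two-exponential closed form", {
  expect_equal(ibap_water(fast, 0), 0)
  no_formation <- fate_scenario(0.3, 0, 0.4, 0.052, 0.46)
  expect_equal(ibap_water(no_formation, c(0, 1, 10, 100)), rep(0, 4))

  # peak position ln(K/k_d)/(K - k_d) for the fast scenario
  K <- fast$k_vol + fast$k_d_prime
  t_star <- log(K / fast$k_d) / (K - fast$k_d)
  expect_equal(t_star, 2.696709, tolerance = 1e-6)
  opt <- optimize(function(t) ibap_water(fast, t), c(0, 20), maximum = TRUE)
  expect_equal(opt$maximum, t_star, tolerance = 1e-4)

  ode <- simulate_ode(fast, c(t_star / 2, t_star, 2 * t_star))
  expect_equal(ibap_water(fast, t_star), ode$ibap_w[2], tolerance = 1e-8)
})

test_that("degenerate equal-rate limit of the intermediate is continuous", {
  s_eq <- fate_scenario(k_d = 0.3, k_f = 0.05, k_d_prime = 0.248,
                        k_vol = 0.052, k_g = 0.46)   # K == k_d exactly
  t <- c(0.5, 2, 8)
  expect_equal(ibap_water(s_eq, t), 0.05 * t * exp(-0.3 * t),
               tolerance = 1e-12)
  s_near <- fate_scenario(k_d = 0.3, k_f = 0.05, k_d_prime = 0.248 + 1e-11,
                          k_vol = 0.052, k_g = 0.46)
  expect_equal(ibap_water(s_near, t), ibap_water(s_eq, t),
               tolerance = 1e-8)
})

test_that("gas-phase product matches the numerical oracle", {
  expect_equal(ibap_gas(fast, 0), 0)
  no_vol <- fate_scenario(0.3, 0.05, 0.4, 0, 0.46)
  expect_equal(ibap_gas(no_vol, c(0, 5, 50)), rep(0, 3))

  ode <- simulate_ode(slow, 10)
  expect_equal(ibap_gas(slow, 10), ode$ibap_g, tolerance = 1e-8)

  # near-degenerate eigenvalues route through the matrix exponential
  s_deg <- fate_scenario(k_d = 0.46, k_f = 0.1, k_d_prime = 0.408,
                         k_vol = 0.052, k_g = 0.46)  # k_d == K == k_g
  ode_deg <- simulate_ode(s_deg, c(1, 5, 20))
  expect_equal(ibap_gas(s_deg, c(1, 5, 20)), ode_deg$ibap_g,
               tolerance = 1e-8)
})

test_that("summary fractions follow the rate-constant ratios", {
  fr_fast <- fractions(fast)
  expect_equal(fr_fast$f, 0.05 / 0.3, tolerance = 1e-12)
  expect_equal(fr_fast$v, 0.052 / 0.452, tolerance = 1e-12)
  expect_null(fr_fast$pathway_fractions)

  fr_slow <- fractions(slow)
  expect_equal(fr_slow$v, 0.052 / 0.082, tolerance = 1e-12)

  # equal rates across the four removal processes -> 25% each
  s_eq <- fate_scenario(k_d = 0.3, k_f = 0.05, k_d_prime = 0.156,
                        k_vol = 0.052, k_g = 0.46,
                        pathway_split = c(k_OH_w = 0.052, k_3CDOM = 0.052,
                                          k_dp = 0.052))
  pf <- fractions(s_eq)$pathway_fractions
  expect_equal(unname(pf), rep(0.25, 4))
  expect_equal(sum(pf), 1)
  expect_equal(pf[["volatilization"]], fractions(s_eq)$v)

  # removing a pathway zeroes its fraction and renormalizes the rest
  s_no_cdom <- fate_scenario(k_d = 0.3, k_f = 0.05, k_d_prime = 0.104,
                             k_vol = 0.052, k_g = 0.46,
                             pathway_split = c(k_OH_w = 0.052,
                                               k_3CDOM = 0, k_dp = 0.052))
  pf2 <- fractions(s_no_cdom)$pathway_fractions
  expect_equal(pf2[["k_3CDOM"]], 0)
  expect_equal(sum(pf2), 1)
  expect_equal(unname(pf2[c("k_OH_w", "k_dp", "volatilization")]),
               rep(1 / 3, 3))
})

test_that("scenario constructor enforces the network's structure", {
  expect_error(fate_scenario(0.3, 0.4, 0.4, 0.052, 0.46), "k_f")
  expect_error(fate_scenario(-0.1, 0, 0.4, 0.052, 0.46), ">= 0")
  expect_error(fate_scenario(0.3, 0.05, 0.4, 0.052, 0.46,
                             pathway_split = c(k_OH_w = 0.1, k_3CDOM = 0.1,
                                               k_dp = 0.1)),
               "sum to")
  expect_error(fate_scenario(0.3, 0.05, 0.4, 0.052, 0.46,
                             pathway_split = c(bad = 0.4)),
               "components")
})

test_that("ODE simulation handles inert systems and matches analytics", {
  inert <- fate_scenario(0, 0, 0, 0, 0)
  tr <- simulate_ode(inert, c(1, 10, 100))
  expect_equal(tr$ibp_w, rep(1, 3), tolerance = 1e-9)
  expect_equal(tr$ibap_w, rep(0, 3))
  expect_equal(tr$ibap_g, rep(0, 3))

  grid <- seq(0.5, 30, by = 0.5)
  ode <- simulate_ode(fast, grid)
  an <- trends(fast, grid)
  rel <- function(a, b) max(abs(a - b) / pmax(abs(b), 1e-12))
  expect_lt(rel(an$ibp_w, ode$ibp_w), 1e-6)
  expect_lt(rel(an$ibap_w, ode$ibap_w), 1e-6)
  expect_lt(rel(an$ibap_g, ode$ibap_g), 1e-6)
})

test_that("flux quadrature recovers the formation yield and volatilized share", {
  for (s in list(fast, slow)) {
    formed <- integrate(function(t) s$k_f * ibp_water(s, t), 0, Inf,
                        rel.tol = 1e-10)$value
    expect_equal(formed, fractions(s)$f, tolerance = 1e-9)

    volatilized <- integrate(function(t) s$k_vol * ibap_water(s, t), 0, Inf,
                             rel.tol = 1e-10)$value
    expect_equal(volatilized / formed, fractions(s)$v, tolerance = 1e-9)
  }
})

test_that("aqueous intermediate is non-negative and single-peaked", {
  set.seed(11)
  grid <- seq(0, 60, by = 0.25)
  for (i in 1:40) {
    k <- 10^runif(4, -3, 1)   # k_d, k_d_prime, k_vol, k_g
    s <- fate_scenario(k_d = k[1], k_f = 0.5 * k[1], k_d_prime = k[2],
                       k_vol = k[3], k_g = k[4])
    b <- ibap_water(s, grid)
    expect_true(all(b >= 0))
    d <- diff(b)
    sign_changes <- sum(diff(sign(d[d != 0])) != 0)
    expect_lte(sign_changes, 1)
  }
})

test_that("trend grids reproduce the qualitative two-media picture", {
  expect_equal(unlist(trends(fast, 0)[1, -1], use.names = FALSE),
               c(1, 0, 0))

  grid <- seq(0.1, 50, by = 0.1)
  tr_fast <- trends(fast, grid)
  expect_true(all(tr_fast$ibap_w < tr_fast$ibp_w))

  tr_slow <- trends(slow, seq(0, 400, by = 1))
  expect_lt(max(tr_slow$ibap_g), 0.01)   # gas phase stays below 1% of IBP0
  expect_true(all(diff(tr_slow$ibp_w) <= 0))
})
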