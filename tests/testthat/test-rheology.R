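test_that("shear rate magnitude matches brute-force sqrt(2 D:D)", {
  expect_identical(shear_rate_magnitude(matrix(0, 2, 2)), 0)
  # simple shear du/dy = k
  k <- 3.7
  expect_equal(shear_rate_magnitude(matrix(c(0, 0, k, 0), 2, 2, byrow = TRUE)),
               abs(k))
  set.seed(42)
  for (rep in 1:20) {
    L <- matrix(rnorm(4, sd = 10), 2, 2)
    D <- (L + t(L)) / 2
    oracle <- sqrt(2 * sum(D^2))  # elementwise brute force
    expect_equal(shear_rate_magnitude(L), oracle, tolerance = 1e-12)
    expect_equal(
      shear_rate_magnitude(matrix(c(L[1, 1], L[1, 2], L[2, 1], L[2, 2]), 1, 4)),
      oracle, tolerance = 1e-12)
  }
})

test_that("generalized power law consistency and index match direct evaluation", {
  m <- gpl_model()
  # gdot = 1000: exp(-b/gdot) ~ 0.997, exponent ~ -20.9 -> lambda -> mu_inf
  lam_1000 <- 0.035 + 0.25 * exp(-(1 + 1000 / 50) * exp(-3 / 1000))
  expect_equal(gpl_lambda(1000, m), lam_1000, tolerance = 1e-12)
  expect_equal(gpl_lambda(1000, m), 0.035, tolerance = 1e-6)
  # gdot = 0.1: exp(-30) ~ 0 -> lambda -> mu_inf + delta_mu
  expect_equal(gpl_lambda(0.1, m), 0.285, tolerance = 1e-6)
  expect_equal(gpl_n(1000, m), 1.0, tolerance = 1e-6)
  expect_equal(gpl_n(0.1, m), 0.55, tolerance = 1e-6)
  # bounds and monotonicity on a dense grid over the validity range
  g <- exp(seq(log(0.1), log(1000), length.out = 1000))
  lam <- gpl_lambda(g, m); nn <- gpl_n(g, m)
  expect_true(all(lam >= m$mu_inf - 1e-12 & lam <= m$mu_inf + m$delta_mu + 1e-12))
  expect_true(all(diff(lam) <= 1e-12))            # non-increasing
  expect_true(all(nn >= m$n_inf - m$delta_n - 1e-12 & nn <= m$n_inf + 1e-12))
  expect_true(all(diff(nn) >= -1e-12))            # non-decreasing
})

test_that("apparent viscosity: Newtonian constant, GPL shear-thinning with Newtonian high-shear limit", {
  newt <- newtonian_model()
  gpl <- gpl_model()
  expect_equal(apparent_viscosity(c(0.01, 1, 500, 1e6), newt),
               rep(0.0035, 4))
  # low-shear value: 0.285 * 0.1^(-0.45) poise = 0.8031 poise = 0.08031 Pa s
  mu_low <- 0.1 * gpl_lambda(0.1, gpl) * 0.1^(gpl_n(0.1, gpl) - 1)
  expect_equal(apparent_viscosity(0.1, gpl), mu_low, tolerance = 1e-12)
  expect_equal(apparent_viscosity(0.1, gpl), 0.0803, tolerance = 1e-3)
  # clamping: far beyond the validity bound evaluates at the bound
  expect_equal(apparent_viscosity(1e6, gpl), apparent_viscosity(1000, gpl))
  expect_equal(apparent_viscosity(1e6, gpl), 0.0035, tolerance = 1e-5)
  # high-shear agreement with the Newtonian model within 0.1%
  expect_lt(abs(apparent_viscosity(1000, gpl) / 0.0035 - 1), 0.001)
  # shear-thinning: non-increasing over the validity range; finite everywhere
  g <- exp(seq(log(0.1), log(1000), length.out = 1000))
  mu <- apparent_viscosity(g, gpl)
  expect_true(all(diff(mu) <= 1e-15))
  expect_true(all(is.finite(apparent_viscosity(c(1e-300, 1e-8, 1e8, 1e300), gpl))))
})

test_that("model constructors reject invalid parameters", {
  expect_error(newtonian_model(mu = 0), "mu")
  expect_error(gpl_model(delta_n = 1.2), "delta_n")
  expect_error(gpl_model(gamma_range = c(10, 1)), "gamma_range")
})
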