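test_that("Lindley density and CDF match their closed forms", {
  # F(0) = 0 for any parameter
  for (xi in c(0.001, 0.6459, 1, 50)) expect_identical(plindley(0, xi), 0)
  # closed form at z = 1, xi = 1 (high-precision reference value)
  expect_equal(plindley(1, 1), 1 - 1.5 * exp(-1), tolerance = 1e-15)
  # the baseline CDF exponent of the worked reliability example
  expect_equal(round(plindley(300, 0.001), 4), 0.0372)
  # density integrates to the CDF
  expect_equal(integrate(dlindley, 0, 2, xi = 0.7)$value, plindley(2, 0.7),
               tolerance = 1e-8)
  expect_error(dlindley(1, -1), "positive")
  expect_error(plindley(-1, 1), "non-negative")
})

test_that("DUS transform density and CDF are normalised and consistent", {
  for (xi in c(0.1, 0.6459, 1.1188, 5, 50)) {
    expect_equal(integrate(ddus, 0, Inf, xi = xi, rel.tol = 1e-10)$value, 1,
                 tolerance = 1e-8)
    # CDF equals the integral of the density
    for (z in c(0.5, 2)) {
      expect_equal(integrate(ddus, 0, z, xi = xi, rel.tol = 1e-10)$value,
                   pdus(z, xi), tolerance = 1e-7)
    }
    # generic transform equals the directly coded specific density
    z <- seq(0, 8, length.out = 40)
    expect_equal(ddus(z, xi), ddus_direct(z, xi), tolerance = 1e-12)
  }
  # boundary values of the transform
  expect_identical(pdus(0, 1), 0)
  expect_equal(pdus(1e6, 0.5), 1, tolerance = 1e-12)
  expect_equal(ddus(0, 1), 1 / (2 * (exp(1) - 1)), tolerance = 1e-14)
  # worked example: G(300; 0.002) = 1 - 0.9241
  expect_equal(round(pdus(300, 0.002), 4), 1 - 0.9241)
  # DUS exponential base reproduces its closed form
  z <- seq(0, 6, length.out = 30)
  expect_equal(ddus(z, 1.3, base = "exponential"), ddusexp_direct(z, 1.3),
               tolerance = 1e-13)
  # monotone CDF
  zg <- seq(0, 20, length.out = 200)
  expect_true(all(diff(pdus(zg, 0.8)) >= 0))
})

test_that("quantile inversion round-trips and both routes agree", {
  u <- c(0.001, 0.05, 0.5, 0.95, 0.999)
  for (xi in c(0.1, 0.6459, 1.1188, 2, 50)) {
    z <- qdus(u, xi)
    expect_equal(pdus(z, xi), u, tolerance = 1e-9)
    expect_true(all(diff(z) > 0))
    # Lambert-W closed form vs bracketed root finding on the baseline
    pl <- log1p(u * (exp(1) - 1))
    expect_equal(qlindley(pl, xi), qlindley(pl, xi, method = "root"),
                 tolerance = 1e-9)
  }
  expect_identical(qdus(0, 1), 0)
  expect_error(qdus(1, 1), "\\[0, 1\\)")
  expect_error(qdus(-0.1, 1), "\\[0, 1\\)")
  # inverting the worked survival value recovers the mission time
  expect_lt(abs(qdus(1 - 0.9241, 0.002) - 300), 0.5)
  # exponential base round trip
  expect_equal(pdus(qdus(u, 2, base = "exponential"), 2,
                    base = "exponential"), u, tolerance = 1e-12)
})

test_that("inverse-CDF sampling is reproducible and matches its own CDF", {
  set.seed(42)
  a <- rdus(500, 1.5)
  set.seed(42)
  b <- rdus(500, 1.5)
  expect_identical(a, b)
  expect_true(all(a > 0))
  set.seed(7)
  z <- rdus(1e5, 2)
  ks <- dus_ks_test(z, function(q) pdus(q, 2))
  expect_lt(ks$statistic, 0.01)
  # Lindley mixture sampler agrees with its CDF too
  set.seed(8)
  y <- rlindley(1e5, 0.9)
  expect_lt(dus_ks_test(y, function(q) plindley(q, 0.9))$statistic, 0.01)
})

test_that("reliability bundle identities hold with infinity sentinels", {
  xi <- 0.8
  z <- c(0, 0.3, 1, 4, 12)
  rb <- dus_reliability(z, xi)
  expect_equal(rb$survival + rb$cdf, rep(1, length(z)), tolerance = 1e-12)
  expect_equal(rb$hazard * rb$survival, rb$density, tolerance = 1e-10)
  pos <- z > 0
  expect_equal(rb$mills_ratio[pos] * rb$reverse_hazard[pos],
               rep(1, sum(pos)), tolerance = 1e-10)
  # z = 0 sentinels: +Inf reverse hazard, zero Mills ratio, no NaN
  expect_identical(rb$reverse_hazard[1], Inf)
  expect_identical(rb$mills_ratio[1], 0)
  expect_false(anyNA(as.matrix(rb)))
  # survival matches the worked example to one unit in its last printed
  # place (the published computation rounds e to 2.718 midway)
  expect_lt(abs(dus_reliability(300, 0.001)$survival - 0.9779), 1.5e-4)
  # deep tail: hazard stays finite and positive in log-space computation
  deep <- dus_reliability(60, 1)
  expect_true(is.finite(deep$hazard) && deep$hazard > 0)
})
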