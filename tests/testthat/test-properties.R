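test_that("raw moments agree across quadrature, series and sampling routes", {
  for (xi in c(0.5, 1, 2, 5)) {
    mq <- dus_moment(xi, 1:4)
    ms <- dus_moment(xi, 1:4, method = "series")
    expect_true(all(abs(mq - ms) <= pmax(1e-6, 1e-4 * mq)))
    expect_gte(mq[2], mq[1]^2)  # nonnegative variance
  }
  # Monte-Carlo oracle for the mean
  set.seed(11)
  z <- rdus(1e6, 1)
  se <- sd(z) / sqrt(length(z))
  expect_lt(abs(mean(z) - dus_moment(1, 1)), 3 * se)
})

test_that("summary statistics obey moment identities on both routes", {
  s <- dus_stats(2)
  mu <- dus_moment(2, 1:2)
  expect_equal(s$variance, mu[2] - mu[1]^2, tolerance = 1e-10)
  expect_gte(s$kurtosis, s$skewness^2 + 1)
  ss <- dus_stats(2, method = "series")
  expect_equal(unlist(s), unlist(ss), tolerance = 1e-6)
})

test_that("conditional moments restrict correctly and match a Riemann oracle", {
  xi <- 1
  expect_equal(dus_conditional_moment(xi, 1L, 0), dus_moment(xi, 1L),
               tolerance = 1e-10)
  for (r in 1:2) {
    cm <- dus_conditional_moment(xi, r, 1.5)
    expect_gte(cm, 1.5^r)
  }
  # midpoint-rule oracle for E(Z | Z > 1)
  step <- 1e-3
  z <- seq(1 + step / 2, 60, by = step)
  oracle <- sum(z * ddus(z, xi)) * step / pdus(1, xi, lower.tail = FALSE)
  expect_equal(dus_conditional_moment(xi, 1L, 1), oracle, tolerance = 1e-5)
  # series route
  expect_equal(dus_conditional_moment(xi, 1L, 1, method = "series"),
               dus_conditional_moment(xi, 1L, 1), tolerance = 1e-5)
  expect_error(dus_conditional_moment(1, 1L, 80), "degenerate")
})

test_that("generating functions behave at zero and bound the cf modulus", {
  g0 <- dus_generating(0, 1)
  expect_equal(g0$mgf, 1, tolerance = 1e-9)
  expect_equal(g0$cgf, 0, tolerance = 1e-9)
  expect_equal(c(g0$cf_re, g0$cf_im), c(1, 0), tolerance = 1e-8)
  gt <- dus_generating(seq(-3, 0.9, by = 0.65), 1)
  expect_true(all(sqrt(gt$cf_re^2 + gt$cf_im^2) <= 1 + 1e-8))
  # central difference of the mgf reproduces the mean
  h <- 1e-4
  gd <- dus_generating(c(-h, h), 2)
  expect_equal((gd$mgf[2] - gd$mgf[1]) / (2 * h), dus_moment(2, 1L),
               tolerance = 1e-4)
  expect_error(dus_generating(1.2, 1), "diverge")
})

test_that("mean residual and past life are coherent and match oracles", {
  xi <- 1
  expect_equal(dus_mrl(0, xi), dus_moment(xi, 1L), tolerance = 1e-9)
  t <- c(0.5, 1, 3)
  mpl <- dus_mpl(t, xi)
  expect_true(all(mpl > 0 & mpl < t))
  # midpoint-rule oracle for the MRL at t = 1
  step <- 1e-3
  z <- seq(1 + step / 2, 60, by = step)
  oracle <- sum(z * ddus(z, xi)) * step /
    pdus(1, xi, lower.tail = FALSE) - 1
  expect_equal(dus_mrl(1, xi), oracle, tolerance = 1e-4)
  # series routes agree with quadrature
  expect_equal(dus_mrl(t, xi, method = "series"), dus_mrl(t, xi),
               tolerance = 1e-4)
  expect_equal(dus_mpl(t, xi, method = "series"), dus_mpl(t, xi),
               tolerance = 1e-4)
})

test_that("order statistics reduce, normalise and satisfy the sum identity", {
  xi <- 1.5
  z <- c(0.2, 0.8, 1.7, 3.1)
  # a single observation is the parent law
  expect_equal(ddus_order(z, xi, 1, 1), ddus(z, xi), tolerance = 1e-13)
  expect_equal(pdus_order(z, xi, 1, 1), pdus(z, xi), tolerance = 1e-13)
  # maximum of n has CDF G^n
  expect_equal(pdus_order(z, xi, 5, 5), pdus(z, xi)^5, tolerance = 1e-12)
  # density of the (2, 5) order statistic integrates to one
  expect_equal(integrate(ddus_order, 0, Inf, xi = xi, r = 2, n = 5,
                         rel.tol = 1e-9)$value, 1, tolerance = 1e-7)
  # sum over ranks of the order-statistic densities is n * g
  n <- 6
  tot <- Reduce(`+`, lapply(1:n, function(r) ddus_order(z, xi, r, n)))
  expect_equal(tot, n * ddus(z, xi), tolerance = 1e-10)
  expect_error(ddus_order(1, 1, 3, 2), "1 <= r <= n")
})

test_that("Renyi and Tsallis entropies converge to Shannon and decrease", {
  xi <- 1
  shannon <- integrate(function(z) {
    d <- ddus(z, xi)
    ifelse(d > 0, -d * log(d), 0)
  }, 0, Inf, rel.tol = 1e-10)$value
  for (kind in c("renyi", "tsallis")) {
    lo <- dus_entropy(xi, 1 - 1e-3, kind)
    hi <- dus_entropy(xi, 1 + 1e-3, kind)
    expect_equal((lo + hi) / 2, shannon, tolerance = 5e-3)
  }
  # Renyi entropy is nonincreasing in its order
  ren <- vapply(c(0.5, 0.9, 2, 3), function(s) dus_entropy(xi, s, "renyi"),
                numeric(1))
  expect_true(all(diff(ren) <= 1e-10))
  # Riemann oracle for the order-2 Renyi entropy
  step <- 1e-3
  z <- seq(step / 2, 60, by = step)
  oracle <- -log(sum(ddus(z, xi)^2) * step)
  expect_equal(dus_entropy(xi, 2, "renyi"), oracle, tolerance = 1e-5)
  # series route cross-check
  for (s in c(0.5, 2, 3)) {
    expect_equal(dus_entropy(xi, s, "renyi", method = "series"),
                 dus_entropy(xi, s, "renyi"), tolerance = 1e-4)
    expect_equal(dus_entropy(xi, s, "tsallis", method = "series"),
                 dus_entropy(xi, s, "tsallis"), tolerance = 1e-4)
  }
  expect_error(dus_entropy(1, 1), "Shannon")
  expect_error(dus_entropy(1, -2), "positive")
})

test_that("Lorenz and Bonferroni curves are bounded, convex and MC-consistent", {
  xi <- 1
  # boundary behaviour
  expect_lt(dus_inequality(1e-6, xi)$lorenz, 1e-5)
  expect_gt(dus_inequality(1 - 1e-6, xi)$lorenz, 1 - 1e-4)
  eta <- seq(0.1, 0.9, by = 0.1)
  curves <- dus_inequality(eta, xi)
  expect_true(all(curves$lorenz <= eta))
  expect_equal(curves$bonferroni, curves$lorenz / eta, tolerance = 1e-12)
  # convexity: nonnegative second differences on a uniform grid
  fine <- dus_inequality(seq(0.05, 0.95, by = 0.05), xi)$lorenz
  expect_true(all(diff(fine, differences = 2) >= -1e-9))
  # Monte-Carlo oracle for L(0.5)
  set.seed(13)
  z <- rdus(1e6, xi)
  psi <- qdus(0.5, xi)
  mu <- mean(z)
  L <- mean(z * (z <= psi)) / mu
  infl <- (z * (z <= psi) - L * z) / mu
  se <- sd(infl) / sqrt(length(z))
  expect_lt(abs(dus_inequality(0.5, xi)$lorenz - L), 3 * se)
  expect_error(dus_inequality(1.2, 1), "inside")
})
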