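precip <- load_dataset("precipitation_hinkley")
leuk <- load_dataset("leukaemia_saudi")

test_that("log-likelihood equals summed log densities and is additive", {
  z <- c(0.4, 1.1, 2.7, 0.9, 3.3)
  for (xi in c(0.3, 1, 4)) {
    expect_equal(dus_loglik(z, xi), sum(ddus(z, xi, log = TRUE)),
                 tolerance = 1e-10)
  }
  expect_equal(dus_loglik(z, 1),
               dus_loglik(z[1:2], 1) + dus_loglik(z[3:5], 1),
               tolerance = 1e-12)
  # published fit: -2 logL = 82.9530 at xi = 1.1188 on the precipitation data
  expect_equal(dus_loglik(precip, 1.1188), -82.9530 / 2, tolerance = 1e-3)
  expect_error(dus_loglik(c(1, -2), 1), "positive")
})

test_that("the MLE satisfies first-order conditions and recovers parameters", {
  for (d in list(precip, leuk)) {
    fit <- fit_dus(d)
    expect_true(fit$converged)
    ll <- function(xi) dus_loglik(d, xi)
    h <- 1e-6 * fit$estimate
    score <- (ll(fit$estimate + h) - ll(fit$estimate - h)) / (2 * h)
    expect_lt(abs(score), 1e-6 * (1 + abs(fit$loglik)))
    # likelihood dominance on a grid around the optimum
    grid <- fit$estimate * exp(seq(-0.5, 0.5, length.out = 200))
    expect_true(all(ll(grid) <= fit$loglik + 1e-10))
  }
  # parameter recovery on a large simulated sample
  set.seed(21)
  z <- rdus(50000, 3)
  fit <- fit_dus(z)
  expect_lt(abs(fit$estimate - 3) / 3, 0.02)
  # tidy/glance interfaces
  td <- tidy(fit)
  expect_identical(td$term, "xi")
  expect_equal(td$estimate, fit$estimate)
  gl <- glance(fit)
  expect_equal(gl$AIC, -2 * fit$loglik + 2, tolerance = 1e-12)
})

test_that("minimum-distance estimators match a brute-force grid search", {
  grid <- exp(seq(log(0.01), log(100), length.out = 1e4))
  log_step <- diff(log(grid[1:2]))
  xs <- sort(as.numeric(precip$value))
  n <- length(xs)
  r <- seq_len(n)
  objectives <- list(
    lse = function(xi) sum((pdus(xs, xi) - r / (n + 1))^2),
    wlse = function(xi) sum((n + 1)^2 * (n + 2) / (r * (n - r + 1)) *
                              (pdus(xs, xi) - r / (n + 1))^2),
    cvme = function(xi) 1 / (12 * n) +
      sum((pdus(xs, xi) - (2 * r - 1) / (2 * n))^2),
    ade = function(xi) -n - sum((2 * r - 1) *
      (log(pdus(xs, xi)) + log(pdus(rev(xs), xi, lower.tail = FALSE)))) / n)
  mle <- fit_dus(precip)$estimate
  for (m in names(objectives)) {
    fit <- fit_dus(precip, method = m)
    vals <- vapply(grid, objectives[[m]], numeric(1))
    best <- grid[which.min(vals)]
    expect_lt(abs(log(fit$estimate) - log(best)), log_step)
    # all estimators land near the MLE on this sample
    expect_lt(abs(fit$estimate - mle), 0.3)
  }
  # the CVM objective is bounded below by 1/(12n) everywhere
  cv <- vapply(c(0.05, 0.5, 1.1, 10), objectives$cvme, numeric(1))
  expect_true(all(cv >= 1 / (12 * n)))
  # the as-printed objective variant runs and gives a finite estimate
  fap <- fit_dus(precip, method = "lse", as_printed = TRUE)
  expect_true(is.finite(fap$estimate) && fap$estimate > 0)
  expect_error(fit_dus(rep(2, 10), method = "lse"), "degenerate")
})

test_that("likelihood-ratio statistic identities hold", {
  e <- exp(1)
  # a single observation near zero: the summand vanishes
  lr <- suppressWarnings(dus_lrt(1e-9, xi = 1, n_boot = 100))
  expect_equal(lr$statistic, 1 / (e - 1), tolerance = 1e-6)
  # exact log identity and monotonicity in the sufficient statistic
  set.seed(5)
  z <- rdus(40, 1.2)
  lr2 <- dus_lrt(z, xi = 1.2, n_boot = 150)
  expect_gt(lr2$statistic, 0)
  expect_equal(lr2$log_statistic,
               40 * log(1 / (e - 1)) + (40 - lr2$suff_stat),
               tolerance = 1e-12)
  expect_identical(lr2$reject, lr2$suff_stat < lr2$critical_value)
  # smaller sufficient statistic implies larger statistic at fixed n
  zb <- z * 2
  lr3 <- dus_lrt(zb, xi = 1.2, n_boot = 150)
  expect_identical(lr3$suff_stat < lr2$suff_stat,
                   lr3$log_statistic > lr2$log_statistic)
  expect_warning(dus_lrt(z, xi = 1, n_boot = 50), "calibrated")
  # default null parameter is the closed-form Lindley MLE
  lr4 <- dus_lrt(z, n_boot = 150)
  zbar <- mean(z)
  expect_equal(lr4$xi,
               (-(zbar - 1) + sqrt((zbar - 1)^2 + 8 * zbar)) / (2 * zbar),
               tolerance = 1e-12)
})
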