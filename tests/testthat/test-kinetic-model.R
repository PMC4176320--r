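test_that("switched fraction is the exponential CDF and matches Monte Carlo", {
  lam <- fitted_lam
  expect_identical(switched_fraction(0, lam), 0)
  expect_equal(switched_fraction(log(2) / lam, lam), 0.5)
  # monotone nondecreasing, saturates at 1
  tt <- seq(0, 1e6, length.out = 200)
  f <- switched_fraction(tt, lam)
  expect_true(all(diff(f) >= 0))
  expect_true(all(f >= 0 & f <= 1))
  expect_equal(switched_fraction(Inf, lam), 1)
  # empirical oracle: fraction of exponential draws below t = 1 day
  t1 <- 86400
  emp <- withr::with_seed(101, mean(rexp(1e6, lam) <= t1))
  se <- sqrt(emp * (1 - emp) / 1e6)
  expect_lt(abs(switched_fraction(t1, lam) - emp), 3 * se)
  expect_error(switched_fraction(-1, lam), "non-negative")
  expect_error(switched_fraction(10, -1), "rate")
})

test_that("dsDNA rate matches quadrature of the switch-time density over [t/2, t]", {
  p <- model_params(lam = fitted_lam, amplitude = 1)
  expect_identical(dsdna_rate(0, p), 0)
  tt <- c(600, 3600, 86400, 3e5, 2e6)
  for (t in tt) {
    quad <- integrate(function(s) p$amplitude * p$lam * exp(-p$lam * s),
                      lower = t / 2, upper = t, rel.tol = 1e-10)$value
    expect_equal(dsdna_rate(t, p), quad, tolerance = 1e-8)
  }
  expect_true(all(dsdna_rate(tt, p) >= 0))
  expect_lt(dsdna_rate(1e8, p), 1e-12)
  # rate identity against the CDF
  expect_equal(dsdna_rate(tt, p),
               p$amplitude * (switched_fraction(tt, p$lam) -
                              switched_fraction(tt / 2, p$lam)),
               tolerance = 1e-12)
  expect_error(dsdna_rate(-5, p), "non-negative")
})

test_that("dsDNA mass equals the time integral of its rate and saturates at A/lambda", {
  p <- model_params(lam = fitted_lam, amplitude = 1)
  expect_identical(mass_ds(0, p), 0)
  for (t in c(3600, 86400, 6e5)) {
    quad <- integrate(function(s) dsdna_rate(s, p), 0, t, rel.tol = 1e-10)$value
    expect_equal(mass_ds(t, p), quad, tolerance = 1e-8)
  }
  expect_equal(mass_ds(1e9, p), p$amplitude / p$lam, tolerance = 1e-6)
  tt <- seq(0, 2e6, length.out = 500)
  m <- mass_ds(tt, p)
  expect_true(all(diff(m) >= 0))
  expect_true(all(m <= p$amplitude / p$lam + 1e-12))
})

test_that("ssDNA mass rises, peaks at 2 ln2 / lambda, and decays to zero", {
  p <- model_params(lam = fitted_lam, amplitude = 1)
  expect_identical(mass_ss(0, p), 0)
  tpk <- ss_peak_time(p$lam)
  expect_equal(tpk, 2 * log(2) / p$lam)
  # numerical maximizer agrees within a second
  num <- optimize(function(t) mass_ss(t, p), c(0, 1e6), maximum = TRUE,
                  tol = 1e-3)
  expect_lt(abs(num$maximum - tpk), 1)
  expect_equal(mass_ss(tpk, p), num$objective, tolerance = 1e-9)
  tt <- seq(1, 3e6, length.out = 2000)
  m <- mass_ss(tt, p)
  expect_true(all(m >= 0))
  expect_true(all(diff(m[tt < tpk]) > 0))
  expect_true(all(diff(m[tt > tpk]) < 0))
  expect_lt(mass_ss(1e9, p), 1e-12)
})

test_that("small-rate limits reduce to unswitched linear production", {
  # lam -> 0 with n0*phi fixed: N_ss -> n0*phi*t, N_ds/t^2 -> n0*phi*lam/2
  p <- model_params(lam = 1e-12, n0 = 1, phi = 1)
  t <- 1e5
  expect_equal(mass_ss(t, p), t, tolerance = 1e-3)
  expect_equal(mass_ds(t, p) / t^2, p$lam / 2, tolerance = 1e-3)
  # exact lam = 0 branch
  p0 <- model_params(lam = 0, n0 = 1, phi = 1)
  expect_equal(mass_ss(100, p0), 100)
  expect_identical(mass_ds(100, p0), 0)
  expect_equal(total_mass(100, p0), 100)
})

test_that("half-life follows the rate constant", {
  expect_equal(half_life(log(2)), 1)
  expect_equal(half_life(1e-5), log(2) / 1e-5)
  expect_equal(ss_peak_time(2 * log(2)), 1)
  expect_error(half_life(0), "positive")
  expect_error(half_life(-1), "positive")
  expect_error(ss_peak_time(0), "positive")
})

test_that("predicted curves conserve mass and cross exactly once", {
  p <- plateau50_params()
  tt <- seq(0, 72, length.out = 1000) * 3600
  ts <- rcr_predict(tt, p)
  # conservation: ss + ds = (A/lam)(1 - e^(-lam t/2))
  expected_total <- (p$amplitude / p$lam) * (1 - exp(-p$lam * tt / 2))
  expect_equal(ts$total_mass, expected_total, tolerance = 1e-12)
  expect_equal(ts$total_mass, ts$ss_mass + ts$ds_mass, tolerance = 1e-12)
  expect_true(all(diff(ts$total_mass) >= 0))
  expect_true(all(diff(ts$ds_mass) >= 0))
  # ss starts above ds, ds overtakes exactly once
  d <- (ts$ss_mass - ts$ds_mass)[-1]  # drop the 0,0 point
  expect_equal(sum(diff(sign(d)) != 0), 1)
  # degenerate and invalid inputs
  one <- rcr_predict(0, p)
  expect_equal(unlist(one[1, c("ss_mass", "ds_mass")], use.names = FALSE), c(0, 0))
  expect_error(rcr_predict(c(10, 5), p), "increasing")
  expect_error(rcr_predict(-1, p), "non-negative")
})

test_that("parameter container enforces its invariants", {
  expect_error(model_params(lam = -1, amplitude = 1), "non-negative")
  expect_error(model_params(lam = 1, amplitude = 0), "positive")
  expect_error(model_params(lam = 1), "supply")
  expect_error(model_params(lam = 1, amplitude = 5, n0 = 1, phi = 1),
               "inconsistent")
  p <- model_params(lam = 1.95e-5, n0 = 100, phi = 0.5)
  expect_equal(p$amplitude, 100)
  # JSON round trip
  p2 <- params_from_json(params_to_json(p))
  expect_equal(p2$lam, p$lam)
  expect_equal(p2$amplitude, p$amplitude)
})

test_that("time series container validates masses and totals", {
  expect_error(rcr_timeseries(c(0, 1), c(0, -1), c(0, 0)), "non-negative")
  expect_error(rcr_timeseries(c(1, 1), c(0, 0), c(0, 0)), "increasing")
  expect_error(rcr_timeseries(c(0, 1), c(1, 2), c(1, 2), total_mass = c(9, 9)),
               "total_mass")
  ts <- rcr_timeseries(c(0, 1), c(1, 2), c(3, 4))
  expect_equal(ts$total_mass, c(4, 6))
})
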