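test_that("closure fit recovers planted slopes and lags", {
  t <- seq(0, 18, 0.25)
  # pure line, no lag
  s1 <- wound_time_series(t, 1e5 * (1 - 0.05 * t))
  f1 <- fit_closure_velocity(s1)
  expect_equal(f1$alpha, 0.05, tolerance = 1e-9)
  expect_equal(f1$t_lag, 0)
  expect_false(f1$no_closure)
  expect_gte(f1$r_squared, 0.999)
  # flat for 2 h, then slope -0.1 / h
  t2 <- seq(0, 10, 0.25)
  a2 <- ifelse(t2 <= 2, 1, 1 - 0.1 * (t2 - 2))
  f2 <- fit_closure_velocity(wound_time_series(t2, 1e5 * a2))
  expect_equal(f2$alpha, 0.1, tolerance = 0.05)
  expect_equal(f2$t_lag, 2, tolerance = 0.25 / 2 + 1e-9)
})

test_that("closure fit flags series that never close and refuses short ones", {
  t <- seq(0, 10, 0.5)
  fc <- fit_closure_velocity(wound_time_series(t, rep(1000, length(t))))
  expect_true(fc$no_closure)
  expect_identical(fc$alpha, 0)
  expect_error(fit_closure_velocity(wound_time_series(0:3, c(4, 3, 2, 1))),
               "at least 5 points")
  # a lag beyond half the record is fit but flagged
  a <- ifelse(t <= 7, 1, 1 - 0.1 * (t - 7))
  expect_warning(fl <- fit_closure_velocity(wound_time_series(t, 1e3 * a)),
                 "half the record")
  expect_equal(fl$alpha, 0.1, tolerance = 0.05)
})

test_that("edge speed is the closure velocity scaled by half the wound width", {
  expect_equal(edge_speed(0.05, 400), 10)
  expect_equal(edge_speed(0, 400), 0)
  # alpha scales linearly with the planted edge speed, slope 2/b
  b <- 600
  t <- seq(0, 10, 0.5)
  alphas <- vapply(c(5, 10, 20), function(v) {
    areas <- (b - 2 * v * t) * 100
    fit_closure_velocity(wound_time_series(t, areas))$alpha
  }, numeric(1))
  expect_equal(alphas, 2 * c(5, 10, 20) / b, tolerance = 1e-9)
})

test_that("doubling-time fit is exact on noiseless curves", {
  g <- simulate_growth_curve(5e3, tau = 24, times = seq(0, 96, 12), noise_cv = 0)
  expect_equal(fit_doubling_time(g)$tau, 24, tolerance = 1e-9)
  g2 <- growth_curve(c(0, 24, 48), c(100, 200, 400))
  expect_equal(fit_doubling_time(g2)$tau, 24, tolerance = 1e-12)
  expect_error(fit_doubling_time(growth_curve(c(0, 1, 2), c(100, 90, 80))),
               "do not increase")
})

test_that("doubling-time fit is accurate under multiplicative noise", {
  taus <- vapply(1:200, function(s) {
    g <- simulate_growth_curve(1e4, tau = 20, times = seq(0, 72, 12),
                               noise_cv = 0.05, seed = s)
    fit_doubling_time(g)$tau
  }, numeric(1))
  expect_equal(median(taus), 20, tolerance = 0.03)
})

test_that("growth rate is ln2 over the doubling time", {
  expect_equal(growth_rate(log(2)), 1)
  expect_equal(growth_rate(24), log(2) / 24)
  expect_equal(growth_rate(Inf), 0)
})

test_that("wave-speed relation and its inverse are exact inverses", {
  expect_equal(motility_from_speed(1, 4 * log(2)), 1)
  expect_equal(motility_from_speed(10, 24), 24 * 100 / (4 * log(2)))
  expect_equal(forward_speed(1, 4 * log(2)), 1)
  expect_equal(forward_speed(0, 10), 0)
  set.seed(99)
  v <- runif(200, 0.01, 50)
  tau <- runif(200, 1, 100)
  back <- forward_speed(motility_from_speed(v, tau), tau)
  expect_lt(max(abs(back / v - 1)), 1e-12)
})

test_that("Thiele modulus is dimensionally consistent and scales with b", {
  expect_equal(thiele_modulus(1, 1, 1), 1)
  D <- 24 * 100 / (4 * log(2))  # from v = 10 um/h, tau = 24 h
  expect_equal(thiele_modulus(400, log(2) / 24, D),
               400 * sqrt((log(2) / 24) / D))
  expect_equal(thiele_modulus(800, 0.3, 50), 2 * thiele_modulus(400, 0.3, 50))
  expect_equal(thiele_modulus(400, 0.1, 200, literal = TRUE),
               400^2 * 0.1 / 200)
})

test_that("estimated motility is increasing in the measured closure velocity", {
  alphas <- seq(0.01, 0.08, by = 0.01)
  D <- vapply(alphas, function(a) motility_estimate(a, b = 500, tau = 20)$D,
              numeric(1))
  expect_true(all(diff(D) > 0))
  # round-trip identity through the estimate object
  est <- motility_estimate(0.03, b = 800, tau = 18)
  expect_equal(forward_speed(est$D, est$tau), est$v, tolerance = 1e-12)
})
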