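brute_acf <- function(z, L) {
  n <- length(z)
  zc <- z - mean(z)
  vapply(0:L, function(lag)
    sum(zc[seq_len(n - lag)] * zc[seq_len(n - lag) + lag]) / n, numeric(1))
}

test_that("autocovariance matches a brute-force double loop", {
  a <- 0.7
  alt <- mk_trace(rep(c(a, -a), 3))
  ac <- autocorrelation(alt, max_lag = 0.3)
  expect_equal(ac$values, brute_acf(alt$z, 3), tolerance = 1e-12)
  expect_equal(ac$values[1], a^2)                 # population variance
  expect_equal(ac$values[2], -a^2 * 5 / 6)        # biased normalisation

  set.seed(2)
  z <- as.numeric(stats::arima.sim(list(ar = 0.8), 1000))
  tr <- mk_trace(z)
  ac <- autocorrelation(tr, max_lag = 5)
  bf <- brute_acf(z, 50)
  expect_lt(max(abs(ac$values - bf)) / abs(bf[1]), 1e-10)
  expect_lt(abs(ac$values[1] / mean((z - mean(z))^2) - 1), 1e-12)
})

test_that("a constant series has zero autocovariance at every lag", {
  ac <- autocorrelation(mk_trace(rep(2.5, 100)), max_lag = 1)
  expect_equal(ac$values, rep(0, 11), tolerance = 1e-20)
  expect_error(integrate_acf(ac), "positive at lag 0")
})

test_that("max_lag beyond half the trace length is rejected", {
  expect_error(autocorrelation(mk_trace(rnorm(100)), max_lag = 6),
               "half the trace")
})

test_that("ACF integration truncation rules", {
  # exact exponential: integral = v * tau_c
  tauc <- 2; v <- 0.3
  lags <- seq(0, 20 * tauc, by = 0.05)
  ac <- structure(list(lags = lags, values = v * exp(-lags / tauc),
                       n_origin = length(lags), dt = 0.05),
                  class = "acf_series")
  expect_lt(abs(as.numeric(integrate_acf(ac, "full")) / (v * tauc) - 1), 0.01)

  # constant-zero beyond lag 0: a single trapezoid
  az <- structure(list(lags = c(0, 0.1, 0.2), values = c(0.4, 0, 0),
                       n_origin = 3, dt = 0.1), class = "acf_series")
  expect_equal(as.numeric(integrate_acf(az, "first_zero")), 0.5 * 0.4 * 0.1)

  # full integrates at least as much as first_zero on a positive tail
  pos <- structure(list(lags = c(0, 0.1, 0.2, 0.3),
                        values = c(0.4, 0.2, 0.1, 0.05),
                        n_origin = 4, dt = 0.1), class = "acf_series")
  expect_gte(as.numeric(integrate_acf(pos, "full")),
             as.numeric(integrate_acf(pos, "first_zero")))
})

test_that("restrained OU fluctuations have the analytic correlation time", {
  flat <- make_reference_landscape("flat", D0 = 0.04)
  proto <- umbrella_protocol(base_seed = 13)
  tr <- simulate_window(flat$landscape, flat$diffusivity, 0, proto, 1)
  ac <- autocorrelation(tr, max_lag = 1.5)
  tauc <- RT310 / (proto$force_constant * 0.04)
  fit <- stats::lm(log(v) ~ lag, data.frame(lag = ac$lags, v = ac$values))
  expect_lt(abs(-1 / stats::coef(fit)[["lag"]] / tauc - 1), 0.1)
})

test_that("the variance/autocorrelation estimator recovers D", {
  flat <- make_reference_landscape("flat", D0 = 0.04)
  proto <- umbrella_protocol(base_seed = 27)
  tr <- simulate_window(flat$landscape, flat$diffusivity, 0, proto, 1)
  wd <- window_diffusivity(tr)
  expect_lt(abs(wd$D / 0.04 - 1), 0.10)
  expect_lt(abs(wd$z_mean), 0.05)

  # doubling the true D doubles the estimate, within stochastic tolerance
  flat8 <- make_reference_landscape("flat", D0 = 0.08)
  wd8 <- window_diffusivity(
    simulate_window(flat8$landscape, flat8$diffusivity, 0, proto, 1))
  expect_lt(abs(wd8$D / wd$D - 2), 0.4)
})

test_that("window estimates track a position-dependent D at the sample mean", {
  land <- make_reference_landscape("flat")$landscape
  dlin <- make_diffusivity(0.04, "linear", slope = 0.01)
  proto <- umbrella_protocol(base_seed = 33)
  for (c0 in c(-1, 0, 1)) {
    tr <- simulate_window(land, dlin, c0, proto, round(c0 * 10) + 20)
    wd <- window_diffusivity(tr)
    expect_lt(abs(wd$D / dlin$value(wd$z_mean) - 1), 0.15)
  }
})

test_that("estimator error shrinks with trace length", {
  flat <- make_reference_landscape("flat", D0 = 0.04)
  err <- sapply(1:20, function(s) {
    vapply(c(2e4, 2e5), function(n) {
      proto <- umbrella_protocol(n_steps = n, base_seed = 100 + s)
      wd <- window_diffusivity(
        simulate_window(flat$landscape, flat$diffusivity, 0, proto, 1))
      abs(wd$D / 0.04 - 1)
    }, numeric(1))
  })
  expect_lt(stats::median(err[2, ]), stats::median(err[1, ]))
})

test_that("diffusivity profiles interpolate and mirror the window estimates", {
  grid <- seq(-1.5, 1.5, by = 0.1)
  flat <- make_reference_landscape("flat", D0 = 0.04)
  proto <- umbrella_protocol(n_steps = 5e4, base_seed = 41)
  traces <- lapply(c(-1, 1), function(c0)
    simulate_window(flat$landscape, flat$diffusivity, c0, proto,
                    as.integer(c0 + 2)))
  dp <- diffusivity_profile(traces, grid)
  expect_equal(dp$z, grid)
  expect_true(all(dp$D > 0))
  # constant-D truth: interpolated profile close to 0.04 everywhere
  expect_lt(max(abs(dp$D / 0.04 - 1)), 0.15)
  # linear interpolation between the two window estimates at the midpoint
  i0 <- which.min(abs(grid))
  expect_equal(dp$D[i0], mean(dp$windows$D), tolerance = 0.02)

  # cancer-side mirroring is exact on mirrored grid points
  outer_traces <- lapply(c(-1.5, -0.5), function(c0)
    simulate_window(flat$landscape, flat$diffusivity, c0, proto,
                    as.integer(10 - c0)))
  dpc <- diffusivity_profile(outer_traces, grid, side = "cancer")
  expect_equal(dpc$D, rev(dpc$D))

  expect_error(diffusivity_profile(traces[1], grid), "two windows")
})

test_that("a linear-in-z diffusivity is recovered across the window span", {
  land <- make_reference_landscape("flat")$landscape
  dlin <- make_diffusivity(0.05, "linear", slope = 0.012)
  proto <- umbrella_protocol(window_centers = seq(-1.5, 1.5, by = 0.5),
                             base_seed = 55)
  sim <- simulate_protocol(land, dlin, proto)
  grid <- seq(-1.5, 1.5, by = 0.05)
  dp <- diffusivity_profile(sim$traces, grid)
  expect_lt(max(abs(dp$D / dlin$value(grid) - 1)), 0.15)
})
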