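test_that("half-maximum latency of a linear ramp is the analytic midpoint", {
  # response: 0 until 5 ms after onset, linear rise to max at 20 ms, hold
  rate <- 1000
  onset <- 0.1
  tt <- (0:(rate - 1)) / rate
  rel <- (tt - onset) * 1000
  resp <- pmin(1, pmax(0, (rel - 5) / 15))
  erg <- time_series(resp, rate)
  lat <- pulse_latency_half_max(erg, onsets = onset, window = 100)
  expect_equal(as.numeric(lat), 12.5, tolerance = 1e-6)

  # invariance to amplitude scaling (and to sign: ERG is negative-going)
  lat2 <- pulse_latency_half_max(time_series(-7.3 * resp, rate),
                                 onsets = onset, window = 100)
  expect_equal(as.numeric(lat2), as.numeric(lat), tolerance = 1e-12)

  # identical responses across pulses: mean equals the single-pulse value
  five <- time_series(rep(resp, 5), rate)
  lat5 <- pulse_latency_half_max(five, onsets = onset + 0:4, window = 100)
  expect_equal(as.numeric(lat5), as.numeric(lat), tolerance = 1e-9)
  expect_length(attr(lat5, "per_pulse"), 5)
})

test_that("cross-correlation identifies identical and inverted waveforms", {
  x <- bandlimited_noise(5, 2000, seed = 11)
  cg <- cross_correlate(x, x, max_lag = 20)
  expect_equal(cg$values[cg$lags == 0], 1, tolerance = 1e-9)
  expect_true(all(cg$values >= -1 & cg$values <= 1))
  expect_true(all(diff(cg$lags) > 0))

  # inverted copy shifted by 6.5 ms (13 samples at 2 kHz)
  y <- time_series(-c(rep(0, 13), x$samples[1:(length(x$samples) - 13)]),
                   2000)
  cg2 <- cross_correlate(x, y, max_lag = 20)
  i <- which.min(cg2$values)
  expect_equal(cg2$lags[i], 6.5, tolerance = 1e-9)
  expect_lt(cg2$values[i], -0.99)
  expect_equal(as.numeric(xcorr_latency(cg2)), 6.5, tolerance = 0.1)

  # inverted copy, zero shift
  cg3 <- cross_correlate(x, time_series(-x$samples, 2000), max_lag = 20)
  expect_equal(as.numeric(suppressWarnings(xcorr_latency(cg3))), 0,
               tolerance = 0.1)

  expect_error(cross_correlate(x, time_series(rep(1, 10000), 2000)),
               "zero-variance")
  expect_error(cross_correlate(x, time_series(x$samples, 1000)), "rate")
})

test_that("independent noise stays inside the Fisher bound", {
  for (s in 1:5) {
    n <- 4000
    x <- generate_white_noise(2, 2000, seed = 100 + s)
    y <- generate_white_noise(2, 2000, seed = 200 + s)
    cg <- cross_correlate(x, y, max_lag = 20)
    expect_lt(max(abs(cg$values)), 5 / sqrt(n))
  }
})

test_that("latency survives noise and fractional delays within one sample", {
  # oracle: exhaustive lag scan at 10x the analysis rate
  rate_hi <- 10000; rate <- 1000
  x_hi <- bandlimited_noise(8, rate_hi, seed = 31)
  y_hi <- time_series(shift_signal(x_hi$samples, rate_hi, 8.3,
                                   invert = TRUE), rate_hi)
  cg_hi <- cross_correlate(x_hi, y_hi, max_lag = 30)
  oracle <- cg_hi$lags[which.min(cg_hi$values)]
  expect_equal(oracle, 8.3, tolerance = 1e-6)

  # analysis-rate estimate with SNR 3 noise, parabolic refinement
  dec <- seq(1, length(x_hi$samples), by = rate_hi / rate)
  x <- time_series(x_hi$samples[dec], rate)
  yv <- y_hi$samples[dec]
  set.seed(77)
  y <- time_series(yv + rnorm(length(yv), sd = sd(yv) / sqrt(3)), rate)
  est <- as.numeric(xcorr_latency(cross_correlate(x, y, max_lag = 30)))
  expect_lt(abs(est - oracle), 1000 / rate)  # one sample at 1 kHz
})

test_that("round-trip latency holds across band-limited delays", {
  x <- bandlimited_noise(5, 3000, seed = 13)
  for (d in c(3.2, 7.7, 12.1)) {
    y <- time_series(shift_signal(x$samples, 3000, d, invert = TRUE), 3000)
    lat <- as.numeric(xcorr_latency(cross_correlate(x, y, max_lag = 25)))
    expect_lt(abs(lat - d), 1000 / 3000)
  }
})

test_that("boundary extrema raise a warning", {
  x <- bandlimited_noise(2, 1000, seed = 41)
  y <- time_series(shift_signal(x$samples, 1000, 21, invert = TRUE), 1000)
  cg <- cross_correlate(x, y, max_lag = 30)
  expect_warning(xcorr_latency(cg, search = c(0, 20)), "boundary")
})

test_that("the sliding monitor tracks the walking latency dip", {
  s <- simulate_session("walking", epoch_durations = c(before = 15,
                                                       active = 15,
                                                       after = 15),
                        seed = 17)
  sl <- sliding_latency(s, window = 5, step = 2.5)
  expect_true(all(!is.na(sl$latency_ms)))
  med <- tapply(sl$latency_ms, sl$condition, median)
  expect_lt(med[["active"]], med[["before"]] - 0.5)
  # temperature and latency move in opposite directions
  expect_lt(cor(sl$latency_ms, sl$temperature_C), -0.7)

  # stationary session: latency flat within estimator noise
  s0 <- simulate_session("walking", temp_rise = 0,
                         epoch_durations = c(before = 10, active = 10,
                                             after = 10), seed = 18)
  sl0 <- sliding_latency(s0, window = 5, step = 2.5)
  expect_lt(diff(range(sl0$latency_ms)), 0.4)
})
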