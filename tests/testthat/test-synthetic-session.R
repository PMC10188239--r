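test_that("forward model has the second-order low-pass transfer function", {
  rate <- 3000
  # constant stimulus, zero noise, polarity -1: steady output = -beta * c
  const <- time_series(rep(0.4, rate), rate)
  p <- photoreceptor_params(beta = 3, tau_ms = 2, zeta = 0.3, delay_ms = 5)
  y <- second_order_response(const, p)
  expect_equal(y$samples, rep(-3 * 0.4, rate), tolerance = 1e-10)

  # probe at w * tau = 1: amplitude ratio beta / (2 zeta)
  n <- 8192
  tau <- 2; zeta <- 0.5
  f1 <- 1000 / (2 * pi * tau)                 # Hz at w*tau = 1
  fbin <- round(f1 * n / rate) * rate / n     # snap to an FFT bin
  tt <- (0:(n - 1)) / rate
  probe <- time_series(sin(2 * pi * fbin * tt), rate)
  resp <- second_order_response(probe,
                                photoreceptor_params(beta = 1, tau_ms = tau,
                                                     zeta = zeta,
                                                     delay_ms = 0))
  ratio <- sqrt(mean(resp$samples^2) / mean(probe$samples^2))
  expect_equal(ratio, 1 / (2 * zeta), tolerance = 0.01)
})

test_that("empirical gain peak matches the closed-form resonance", {
  # oracle: dense grid maximization of |H|
  fg <- seq(50, 200, by = 0.01)
  f_star <- fg[which.max(model_gain(fg, 1, 1.41, 0.15))]
  expect_equal(f_star, sqrt(1 - 2 * 0.15^2) / (2 * pi * 1.41e-3),
               tolerance = 1e-4)
  expect_equal(f_star, 110.3, tolerance = 0.002)

  stim <- bandlimited_noise(10, 3000, seed = 2)
  y <- second_order_response(stim, photoreceptor_params(beta = 1,
                                                        tau_ms = 1.41,
                                                        zeta = 0.15,
                                                        delay_ms = 8))
  est <- estimate_spectra(resample_uniform(stim), resample_uniform(y),
                          segment_len = 2048)
  gm <- gain_magnitude(est)
  emp_peak <- gm$freq_Hz[which.max(gm$gain_mag)]
  expect_lt(abs(emp_peak - f_star), 2)
})

test_that("temperature models reproduce the fitted relations", {
  expect_equal(latency_from_temperature(30), 22.21 - 0.48 * 30)
  expect_equal(latency_from_temperature(30), 7.81)
  m0 <- temperature_model(slope_ms_per_C = 0)
  expect_equal(latency_from_temperature(c(25, 30, 35), m0),
               rep(22.21, 3))
  expect_warning(latency_from_temperature(40), "range")

  expect_equal(tau_from_temperature(26.9), 1.48)
  expect_equal(tau_from_temperature(31.9), 1.14)
  expect_equal(tau_from_temperature(29.4), 1.31)  # midpoint interpolation
  expect_error(tau_from_temperature(60), "non-positive")
})

test_that("noiseless sessions round-trip the configured latency and tau", {
  s <- simulate_session("walking", noise_frac = 0, artefact_frac = 0,
                        epoch_durations = c(before = 10, active = 10,
                                            after = 10), seed = 21)
  res <- analyze_session(s)
  tr <- s$truth
  one_sample_ms <- 1000 / s$channels$erg$rate
  for (cond in c("before", "active")) {
    seg <- res[res$condition == cond, ]
    blk <- tr[abs(tr$block_start - seg$seg_start) < 1e-6, ]
    expect_lt(abs(seg$latency_ms - blk$target_latency_ms), one_sample_ms)
    expect_lt(abs(seg$tau_ms - blk$tau_ms) / blk$tau_ms, 0.02)
  }
})

test_that("walking sessions heat up by the configured rise and gate motion", {
  s <- simulate_session("walking", epoch_durations = c(before = 20,
                                                       active = 20,
                                                       after = 20),
                        seed = 5)
  temp <- s$channels$temperature$samples
  rate <- s$channels$temperature$rate
  act <- (20 * rate + 1):(40 * rate)
  before <- 1:(20 * rate)
  expect_equal(median(temp[act]) - median(temp[before]), 2.3,
               tolerance = 0.01)
  mo <- s$channels$motion$samples
  expect_true(all(mo[before] == 0))
  expect_true(all(mo[(40 * rate + 1):(60 * rate)] == 0))
  expect_gt(mean(mo[act] > 0), 0.99)
})

test_that("heating sessions peak near 37 degC and cool past the eval window", {
  s <- simulate_session("heating", epoch_durations = c(before = 10,
                                                       active = 10,
                                                       after = 20),
                        seed = 6)
  temp <- s$channels$temperature$samples
  expect_equal(max(temp), 37, tolerance = 0.01)
  # post-active evaluation block sits near the heated-condition temperature
  blk <- s$truth[s$truth$block_start == 20, ]
  expect_equal(blk$temperature_C, 31.8, tolerance = 0.2)
  expect_true(all(s$channels$motion$samples == 0))
})

test_that("a null protocol (zero temperature rise) leaves latency flat", {
  s <- simulate_session("walking", temp_rise = 0,
                        epoch_durations = c(before = 10, active = 10,
                                            after = 10), seed = 8)
  res <- analyze_session(s)
  lat <- res$latency_ms[res$condition %in% c("before", "active")]
  expect_lt(abs(diff(lat)), 0.2)  # estimator noise only
})

test_that("cohorts are reproducible and median-pinned", {
  sp <- cohort_spec(4, "walking", seed = 42)
  c1 <- simulate_cohort(sp, epoch_durations = c(before = 10, active = 10,
                                                after = 10))
  c2 <- simulate_cohort(sp, epoch_durations = c(before = 10, active = 10,
                                                after = 10))
  expect_identical(lapply(c1, function(s) s$channels$erg$samples),
                   lapply(c2, function(s) s$channels$erg$samples))
  # median-pinning: the generating before-condition temperature median is
  # exactly the condition mean
  bt <- vapply(c1, function(s) s$truth$temperature_C[1], numeric(1))
  expect_equal(median(bt), 27.6, tolerance = 1e-9)

  # sds = 0 and no centring: all animals share the same ground truth
  sp0 <- cohort_spec(3, "walking", latency_intercept_sd = 0,
                     latency_slope_sd = 0, tau_scale_sd = 0, beta_sd = 0,
                     zeta_sd = 0, before_temp_sd = 0, active_temp_sd = 0,
                     center = FALSE, seed = 1)
  c0 <- simulate_cohort(sp0, epoch_durations = c(before = 10, active = 10,
                                                 after = 10))
  tr <- lapply(c0, function(s) s$truth[, c("tau_ms", "target_latency_ms")])
  expect_equal(tr[[1]], tr[[2]])
  expect_equal(tr[[1]], tr[[3]])
})

test_that("the intensity series follows the log-intensity calibration", {
  ss <- simulate_intensity_series(duration = 10, seed = 3, noise_frac = 0)
  expect_length(ss, 4)
  lat_truth <- vapply(ss, function(s) s$truth$target_latency_ms[1],
                      numeric(1))
  expect_equal(lat_truth[1] - lat_truth[4], 1.4, tolerance = 1e-9)
  # measured latencies track the configured adaptation model
  lat_meas <- vapply(ss, function(s) {
    cg <- cross_correlate(ts_window(s$channels$stimulus, 0, 5),
                          ts_window(s$channels$erg, 0, 5))
    as.numeric(xcorr_latency(cg))
  }, numeric(1))
  expect_equal(lat_meas, lat_truth, tolerance = 0.05)

  one <- simulate_intensity_series(intensities = 1.74e14, duration = 10,
                                   seed = 3)
  expect_length(one, 1)
  expect_error(simulate_intensity_series(c(2e14, 1e14)), "ascending")
})
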