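test_that("resampling reaches the target grid without shifting time", {
  wn <- generate_white_noise(10, 3000, seed = 3)
  rs <- resample_uniform(wn, interval = 1)
  expect_equal(rs$rate, 1000)
  expect_length(rs$samples, 10000)

  # identity at the native interval
  expect_identical(resample_uniform(rs, interval = 1)$samples, rs$samples)
  expect_error(resample_uniform(rs, interval = 0.5), "upsampling")
})

test_that("resampling passes 400 Hz and rejects 600 Hz", {
  rate <- 3000
  tt <- (0:(4 * rate - 1)) / rate
  for (f0 in c(400, 600)) {
    tone <- time_series(sin(2 * pi * f0 * tt), rate)
    rs <- resample_uniform(tone, interval = 1)
    amp <- sqrt(2 * mean(rs$samples[1000:3000]^2))
    if (f0 == 400) expect_gt(amp, 0.95)   # < 5% amplitude loss
    else expect_lt(amp, 0.1)              # > 90% attenuation
  }
})

test_that("coherence separates linear transfer from noise", {
  rate <- 1000
  x <- generate_white_noise(16, rate, seed = 5)
  y <- time_series(shift_signal(x$samples, rate, 4, invert = TRUE), rate)
  est <- estimate_spectra(x, y)
  expect_true(all(est$coherence >= 0 & est$coherence <= 1))
  expect_gt(min(est$coherence[-1]), 0.98)   # noiseless linear system

  z <- generate_white_noise(16, rate, seed = 6)
  est0 <- estimate_spectra(x, z)
  expect_true(all(est0$coherence >= 0 & est0$coherence <= 1))
  expect_lt(mean(est0$coherence), 0.1)      # independent channels

  expect_error(estimate_spectra(time_series(x$samples[1:600], rate), y),
               "2 segments")
})

test_that("coherence approximates SNR / (1 + SNR)", {
  rate <- 1000
  for (snr in c(0.5, 2, 9)) {
    coh <- numeric(20)
    for (s in 1:20) {
      x <- generate_white_noise(8, rate, seed = 1000 + s)
      ns <- generate_white_noise(8, rate, seed = 5000 + s)
      y <- time_series(2 * x$samples + ns$samples * 2 / sqrt(snr), rate)
      est <- estimate_spectra(x, y)
      band <- est$freqs > 10 & est$freqs < 450
      coh[s] <- mean(est$coherence[band])
    }
    expect_lt(abs(mean(coh) - snr / (1 + snr)), 0.05)
  }
})

test_that("gain recovers known transfer functions", {
  rate <- 1000
  x <- generate_white_noise(16, rate, seed = 7)
  y2 <- time_series(2 * x$samples, rate)
  est <- estimate_spectra(x, y2)
  gm <- gain_magnitude(est)
  expect_equal(gm$gain_mag[-1], rep(2, nrow(gm) - 1), tolerance = 1e-6)

  # second-order system: |G| matches |H| within 2% to 220 Hz
  stim <- bandlimited_noise(25, 3000, seed = 8)
  resp <- second_order_response(stim,
                                photoreceptor_params(beta = 1,
                                                     tau_ms = 1.41,
                                                     zeta = 0.15,
                                                     delay_ms = 8))
  est2 <- estimate_spectra(resample_uniform(stim), resample_uniform(resp))
  gm2 <- gain_magnitude(est2)
  sel <- gm2$freq_Hz >= 2 & gm2$freq_Hz <= 220
  truth <- model_gain(gm2$freq_Hz[sel], 1, 1.41, 0.15)
  expect_lt(max(abs(gm2$gain_mag[sel] - truth) / truth), 0.02)
})

test_that("gain of a known system is unbiased where coherence is high", {
  rate <- 1000
  g <- NULL
  for (s in 1:50) {
    x <- generate_white_noise(8, rate, seed = 300 + s)
    ns <- generate_white_noise(8, rate, seed = 800 + s)
    y <- time_series(2 * x$samples + 0.3 * ns$samples, rate)
    est <- estimate_spectra(x, y)
    g <- cbind(g, Mod(est$gain))
  }
  med <- apply(g, 1, median)
  hi <- est$coherence > 0.9 & est$freqs > 0
  expect_gt(sum(hi), 50)
  # unbiased: the median curve sits on the truth (bin-wise sampling noise
  # of the 50-seed median stays under a loose cap)
  expect_lt(mean(abs(med[hi] - 2) / 2), 0.01)
  expect_lt(max(abs(med[hi] - 2) / 2), 0.03)
})

test_that("spectral magnitudes are invariant to a common time shift", {
  rate <- 1000
  x <- bandlimited_noise(8, rate, seed = 9)
  y <- time_series(shift_signal(x$samples, rate, 5, invert = TRUE), rate)
  xs <- time_series(shift_signal(x$samples, rate, 7.3), rate)
  ys <- time_series(shift_signal(y$samples, rate, 7.3), rate)
  e1 <- estimate_spectra(x, y)
  e2 <- estimate_spectra(xs, ys)
  band <- e1$freqs > 5 & e1$freqs < 240
  expect_equal(Mod(e1$gain)[band], Mod(e2$gain)[band], tolerance = 0.02)
  expect_equal(e1$coherence[band], e2$coherence[band], tolerance = 0.02)
})
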