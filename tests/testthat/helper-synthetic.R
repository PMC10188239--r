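# Shared fixtures and independent oracles, built in code at test time.

# Exact fractional delay (and optional sign flip) of a sample vector via an
# FFT phase ramp - independent of the package's forward model internals.
shift_signal <- function(x, rate, delay_ms, invert = FALSE) {
  n <- length(x)
  k <- 0:(n - 1)
  f <- ifelse(k <= n / 2, k, k - n) * rate / n
  y <- Re(stats::fft(stats::fft(x) * exp(-1i * 2 * pi * f * delay_ms / 1000),
                     inverse = TRUE) / n)
  if (invert) -y else y
}

# Band-limited probe: filtered Gaussian noise, the standard test input.
bandlimited_noise <- function(duration, rate, seed, corner = 250) {
  butterworth_lowpass(generate_white_noise(duration, rate, seed),
                      corner_freq = corner, order = 9)
}

# Brute-force signed-rank oracle: enumerate all 2^n sign assignments of the
# paired differences and compute the exact two-sided p-value with the
# standard convention (2 * min(tail probs), capped at 1).
brute_force_signed_rank <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  stopifnot(n <= 16)  # enumeration guard
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.numeric(signs %*% r)
  p_le <- mean(v_all <= v_obs)
  p_ge <- mean(v_all >= v_obs)
  list(V = v_obs, p = min(1, 2 * min(p_le, p_ge)))
}

# Small, fast walking session for pipeline-level tests.
small_walking_session <- function(seed = 3, noise_frac = 0.3,
                                  durations = c(before = 10, active = 10,
                                                after = 10)) {
  simulate_session("walking", epoch_durations = durations,
                   noise_frac = noise_frac, seed = seed)
}
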