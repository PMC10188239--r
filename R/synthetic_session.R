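#' Photoreceptor response parameters
#'
#' Parameters of the forward ERG model: a resonant second-order low-pass
#' filter `H(f) = beta / (1 + j*2*w*tau*zeta - (w*tau)^2)` (with
#' `w = 2*pi*f`), applied causally with a pure transduction delay and sign
#' inversion, plus additive recording noise and an optional 150 Hz line
#' artefact.
#'
#' @param beta Amplitude (DC gain, ERG units per stimulus unit), > 0.
#' @param tau_ms Time constant in ms, > 0.
#' @param zeta Dimensionless damping factor, > 0 (values below 1/sqrt(2)
#'   give a resonance peak; insect-eye fits sit near 0.15).
#' @param delay_ms Pure transduction delay in ms, >= 0.
#' @param polarity +1 or -1; the ERG is sign-inverted relative to the
#'   stimulus, so -1 is the default.
#' @param noise_sd Additive Gaussian noise sd in ERG units.
#' @param artefact_150hz_amp Amplitude of a 150 Hz sinusoidal artefact.
#'
#' @return A list of class `"photoreceptor_params"`.
#' @export
photoreceptor_params <- function(beta = 1, tau_ms = 1.48, zeta = 0.150,
                                 delay_ms = 7, polarity = -1,
                                 noise_sd = 0, artefact_150hz_amp = 0) {
  if (beta <= 0 || tau_ms <= 0 || zeta <= 0 || delay_ms < 0)
    stop("photoreceptor_params: need beta, tau, zeta > 0 and delay >= 0",
         call. = FALSE)
  if (!polarity %in% c(-1, 1))
    stop("photoreceptor_params: polarity must be +1 or -1", call. = FALSE)
  structure(list(beta = beta, tau_ms = tau_ms, zeta = zeta,
                 delay_ms = delay_ms, polarity = polarity,
                 noise_sd = noise_sd,
                 artefact_150hz_amp = artefact_150hz_amp),
            class = "photoreceptor_params")
}

#' Temperature model for latency and filter time constant
#'
#' Linear latency-temperature relation (default: the fitted relation
#' latency = 22.21 ms - 0.48 ms/degC * T) plus a linear tau-temperature
#' interpolation anchored at two (temperature, tau) pairs. The default
#' anchors reproduce the heated-cohort condition medians (1.48 ms at
#' 26.9 degC before heating, 1.14 ms at 31.9 degC heated).
#'
#' @param intercept_ms Latency at 0 degC, in ms.
#' @param slope_ms_per_C Latency change per degC (negative in the
#'   physiological regime).
#' @param tau_anchors 2x2 matrix `rbind(c(T1, tau1), c(T2, tau2))` anchoring
#'   the tau-temperature line (temperatures in degC, tau in ms).
#' @param temp_range Supported temperature range in degC; values outside it
#'   trigger a warning (the linear relation only holds locally).
#'
#' @return A list of class `"temperature_model"`.
#' @export
temperature_model <- function(intercept_ms = 22.21, slope_ms_per_C = -0.48,
                              tau_anchors = rbind(c(26.9, 1.48),
                                                  c(31.9, 1.14)),
                              temp_range = c(24, 38)) {
  stopifnot(is.matrix(tau_anchors), nrow(tau_anchors) == 2,
            ncol(tau_anchors) == 2)
  structure(list(intercept_ms = intercept_ms,
                 slope_ms_per_C = slope_ms_per_C,
                 tau_anchors = tau_anchors, temp_range = temp_range),
            class = "temperature_model")
}

# tau anchors from the walking-cohort condition medians (tau at the
# reported condition temperatures of the walking experiment).
walking_tau_anchors <- function() rbind(c(27.6, 1.41), c(29.9, 1.25))

#' ERG latency predicted from eye temperature
#'
#' @param temp Eye temperature in degC (vectorized).
#' @param model A `temperature_model`.
#' @param intercept_offset,slope_offset Per-animal random-effect offsets
#'   (ms, ms/degC).
#' @return Latency in ms.
#' @export
#' @examples
#' latency_from_temperature(30) # 22.21 - 0.48 * 30
latency_from_temperature <- function(temp, model = temperature_model(),
                                     intercept_offset = 0,
                                     slope_offset = 0) {
  if (any(temp < model$temp_range[1] | temp > model$temp_range[2]))
    warning("latency_from_temperature: temperature outside the supported ",
            "range [", model$temp_range[1], ", ", model$temp_range[2],
            "] degC; the linear relation only holds locally")
  (model$intercept_ms + intercept_offset) +
    (model$slope_ms_per_C + slope_offset) * temp
}

#' Filter time constant predicted from eye temperature
#'
#' Linear interpolation through the model's two (temperature, tau) anchors,
#' extrapolated linearly outside them.
#'
#' @inheritParams latency_from_temperature
#' @return Time constant in ms.
#' @export
#' @examples
#' tau_from_temperature(c(26.9, 31.9, 29.4))
tau_from_temperature <- function(temp, model = temperature_model()) {
  a <- model$tau_anchors
  slope <- (a[2, 2] - a[1, 2]) / (a[2, 1] - a[1, 1])
  tau <- a[1, 2] + slope * (temp - a[1, 1])
  if (any(tau <= 0))
    stop("tau_from_temperature: non-positive tau at the requested ",
         "temperature", call. = FALSE)
  tau
}

# Complex second-order low-pass transfer function at frequency f (Hz);
# tau in ms. Conjugate-symmetric in f, so it can be applied on a full
# (signed-frequency) FFT grid directly.
h_complex <- function(f, beta, tau_ms, zeta) {
  w <- 2 * pi * f
  x <- w * (tau_ms / 1000)
  beta / (1 + 1i * 2 * x * zeta - x^2)
}

# Apply H(f), a pure delay (exact fractional delay as a phase ramp) and a
# polarity flip to a sample vector, via the FFT (circular convolution).
fft_filter_delay <- function(x, rate, beta, tau_ms, zeta, delay_ms = 0,
                             polarity = -1) {
  n <- length(x)
  k <- 0:(n - 1)
  f <- ifelse(k <= n / 2, k, k - n) * rate / n
  H <- h_complex(f, beta, tau_ms, zeta) *
    exp(-1i * 2 * pi * f * delay_ms / 1000)
  polarity * Re(stats::fft(stats::fft(x) * H, inverse = TRUE) / n)
}

#' Simulate the ERG response to a stimulus
#'
#' Forward model: the stimulus is passed through the second-order low-pass
#' `H(f)`, delayed by the pure transduction delay, sign-flipped according to
#' the polarity, and corrupted by Gaussian recording noise and an optional
#' 150 Hz artefact. The filter and the (possibly fractional) delay are
#' applied exactly in the frequency domain, so with zero noise the transfer
#' magnitude from stimulus to output equals `|H(f)|` to numerical precision.
#'
#' @param stimulus An `erg_ts` (photodiode-equivalent trace).
#' @param params A `photoreceptor_params`.
#' @param seed Optional integer seed for the noise and the artefact phase.
#'
#' @return An `erg_ts` in ERG units (mV-like, arbitrary).
#' @export
second_order_response <- function(stimulus, params, seed = NULL) {
  stopifnot(inherits(stimulus, "erg_ts"),
            inherits(params, "photoreceptor_params"))
  f_n <- 1 / (2 * pi * params$tau_ms / 1000)
  if (f_n >= stimulus$rate / 2)
    stop("second_order_response: tau too small for the sampling rate ",
         "(natural frequency at or above Nyquist)", call. = FALSE)
  clean <- fft_filter_delay(stimulus$samples, stimulus$rate, params$beta,
                            params$tau_ms, params$zeta, params$delay_ms,
                            params$polarity)
  out <- with_seed(seed, {
    y <- clean
    if (params$noise_sd > 0)
      y <- y + stats::rnorm(length(y), sd = params$noise_sd)
    if (params$artefact_150hz_amp > 0)
      y <- y + params$artefact_150hz_amp *
        sin(2 * pi * 150 * ts_time(stimulus) + stats::runif(1, 0, 2 * pi))
    y
  })
  time_series(out, stimulus$rate, t0 = stimulus$t0, units = "mV")
}

# Lag (ms) of the cross-correlation extremum between a stimulus block and
# its noiseless filtered response with zero pure delay, computed from the
# block's own spectrum: c(k) = IFFT(|X|^2 * H * polarity), parabolic-refined.
# Adding `offset` to the pure delay makes the measured cross-correlation
# latency equal delay + offset.
xcorr_filter_offset <- function(x, rate, beta, tau_ms, zeta,
                                polarity = -1, max_lag_ms = 30) {
  n <- length(x)
  k <- 0:(n - 1)
  f <- ifelse(k <= n / 2, k, k - n) * rate / n
  X <- stats::fft(x - mean(x))
  cc <- Re(stats::fft(Mod(X)^2 * h_complex(f, beta, tau_ms, zeta),
                      inverse = TRUE) / n) * polarity
  kmax <- min(n - 2L, as.integer(floor(max_lag_ms / 1000 * rate)))
  seg <- cc[1:(kmax + 1L)]           # lags 0 .. kmax
  i <- which.min(seg)                # polarity folded in above
  lag <- i - 1L
  if (i > 1L && i < length(seg)) {   # parabolic sub-sample refinement
    y1 <- seg[i - 1L]; y2 <- seg[i]; y3 <- seg[i + 1L]
    den <- (y1 - 2 * y2 + y3)
    if (den != 0) lag <- lag + 0.5 * (y1 - y3) / den
  }
  lag / rate * 1000
}

# Half-maximum latency (ms) of the noiseless single-pulse response with zero
# pure delay: the filter's contribution to the pulse latency measurement.
halfmax_filter_offset <- function(rate, beta, tau_ms, zeta, polarity = -1,
                                  pulse_width = 50, pulse_amp = 1,
                                  window_ms = 100) {
  onset <- 0.2
  dur <- onset + (window_ms + pulse_width) / 1000 + 0.3
  pt <- generate_pulse_train(dur, rate, pulse_width = pulse_width,
                             pulse_rate = 1 / dur, amplitude = pulse_amp)
  # shift the single pulse to `onset`
  x <- c(numeric(as.integer(round(onset * rate))), pt$ts$samples)
  x <- x[1:as.integer(round(dur * rate))]
  y <- fft_filter_delay(x, rate, beta, tau_ms, zeta, 0, polarity)
  pulse_latency_half_max(time_series(y, rate), onsets = onset,
                         window = window_ms)
}

#' Simulate a complete recording session
#'
#' Builds the four channels of one animal's recording (photodiode stimulus,
#' ERG, eye temperature, forward motion) across the three condition epochs
#' (sitting before, active = walking or infrared heating, sitting after).
#' Eye temperature ramps up during the active epoch and decays
#' exponentially afterwards; the ERG is generated block-wise (5 s blocks,
#' aligned with the evaluation segments) from the block-mean temperature:
#' the filter time constant follows [tau_from_temperature()] and the pure
#' delay is calibrated per block so that the cross-correlation latency of
#' the noiseless block equals [latency_from_temperature()] (pulse protocol:
#' so that the half-maximum pulse latency equals the epoch's target).
#'
#' @param protocol `"walking"`, `"heating"`, `"pulse"` or `"intensity"`.
#' @param animal_id Label for the animal.
#' @param stimulus A `stimulus_spec`; defaults to the standard noise stimulus
#'   (10 s token, 250 Hz / 9-pole Butterworth, 1.74e14 photons cm^-2 s^-1)
#'   or, for the pulse protocol, 50 ms pulses at 1 Hz and 2e15 photons.
#' @param params A `photoreceptor_params` carrying beta, zeta and polarity
#'   (tau and delay are driven by the temperature coupling).
#' @param temp_model A `temperature_model`; defaults to heated-cohort
#'   anchors for `"heating"` and walking-cohort anchors for `"walking"`.
#' @param baseline_temp Sitting eye temperature in degC (walking default
#'   27.6, heating default 26.9).
#' @param temp_rise Walking: plateau temperature rise in degC (default 2.3).
#' @param peak_temp Heating: plateau (lamp-on) temperature in degC
#'   (default 37).
#' @param decay_tau_s Post-active temperature decay time constant in s
#'   (default 120 for walking - metabolic cool-down - and 3 for heating -
#'   lamp-off relaxation, which places the post-active evaluation window
#'   near the heated-condition temperature).
#' @param epoch_durations Named vector `c(before=, active=, after=)` in s;
#'   the default keeps the >= 300 s recovery period.
#' @param latency_offset,latency_slope_offset Per-animal random-effect
#'   offsets passed to [latency_from_temperature()].
#' @param tau_scale Per-animal multiplicative scatter on tau.
#' @param pulse_targets Pulse protocol: named target half-maximum latencies
#'   (ms) per condition, `c(before=, active=, after=)`.
#' @param fixed_latency Intensity protocol: constant target latency in ms
#'   (overrides the temperature coupling).
#' @param noise_frac ERG noise sd as a fraction of the clean ERG sd
#'   (default 0.3 for noise stimulation, study-like coherence; 0.15 for the
#'   ~10x brighter pulse stimulus).
#' @param artefact_frac 150 Hz artefact amplitude as a fraction of the clean
#'   ERG sd (default 0.15).
#' @param rate Sampling rate in Hz (default 3000).
#' @param block_s Generation block length in s (default 5, matching the
#'   evaluation segment length).
#' @param seed Integer seed; the session is fully reproducible.
#'
#' @return A list of class `"erg_session"` with elements `animal_id`,
#'   `channels` (stimulus, erg, temperature, motion as `erg_ts`), `epochs`
#'   (data.frame label/start/end), `protocol`, `intensity`, `onsets` (pulse
#'   protocol) and `truth` (per-block generating parameters).
#' @export
simulate_session <- function(protocol = c("walking", "heating", "pulse",
                                          "intensity"),
                             animal_id = "a01", stimulus = NULL,
                             params = photoreceptor_params(),
                             temp_model = NULL, baseline_temp = NULL,
                             temp_rise = 2.3, peak_temp = 37,
                             decay_tau_s = NULL,
                             epoch_durations = c(before = 60, active = 60,
                                                 after = 310),
                             latency_offset = 0, latency_slope_offset = 0,
                             tau_scale = 1,
                             pulse_targets = c(before = 10.3, active = 8.7,
                                               after = 10.1),
                             fixed_latency = NULL,
                             noise_frac = NULL, artefact_frac = 0.15,
                             rate = 3000, block_s = 5, seed = 1L) {
  protocol <- match.arg(protocol)
  if (is.null(temp_model))
    temp_model <- if (protocol == "walking")
      temperature_model(tau_anchors = walking_tau_anchors())
    else temperature_model()
  if (is.null(baseline_temp))
    baseline_temp <- if (protocol == "walking") 27.6 else 26.9
  if (is.null(decay_tau_s))
    decay_tau_s <- if (protocol == "heating") 3 else 120
  if (is.null(stimulus))
    stimulus <- if (protocol == "pulse")
      stimulus_spec("pulse", mean_intensity = 2e15)
    else stimulus_spec("noise")
  # the pulse stimulus is ~10x brighter than the noise stimulus, so pulse
  # responses ride well above the recording noise
  if (is.null(noise_frac))
    noise_frac <- if (protocol == "pulse") 0.15 else 0.3
  if (protocol == "intensity") {
    epoch_durations <- c(before = unname(epoch_durations[1]))
  }
  stopifnot(all(epoch_durations > 0))

  dur <- sum(epoch_durations)
  n <- as.integer(round(dur * rate))
  tt <- (seq_len(n) - 1L) / rate
  ep_start <- cumsum(c(0, utils::head(epoch_durations, -1)))
  ep_end <- cumsum(epoch_durations)
  epochs <- data.frame(label = names(epoch_durations), start = ep_start,
                       end = ep_end, stringsAsFactors = FALSE)

  ## --- temperature channel ---------------------------------------------
  temp <- rep(baseline_temp, n)
  if (protocol %in% c("walking", "heating")) {
    a0 <- epochs$start[epochs$label == "active"]
    a1 <- epochs$end[epochs$label == "active"]
    plateau <- if (protocol == "walking") baseline_temp + temp_rise
               else peak_temp
    ramp_end <- a0 + (a1 - a0) / 3
    act <- tt >= a0 & tt < a1
    temp[act] <- baseline_temp + (plateau - baseline_temp) *
      pmin(1, (tt[act] - a0) / (ramp_end - a0))
    aft <- tt >= a1
    temp[aft] <- baseline_temp + (plateau - baseline_temp) *
      exp(-(tt[aft] - a1) / decay_tau_s)
  }

  ## --- stimulus channel (photodiode volts) -----------------------------
  photodiode_gain <- 2e-15  # V per photon cm^-2 s^-1
  onsets <- NULL
  if (protocol == "pulse") {
    pt <- generate_pulse_train(dur, rate, pulse_width = stimulus$pulse_width,
                               pulse_rate = stimulus$pulse_rate,
                               amplitude = stimulus$mean_intensity *
                                 photodiode_gain)
    stim <- pt$ts$samples
    onsets <- pt$onsets
  } else {
    token <- synth_noise_stimulus(stimulus, rate = rate)
    stim <- rep_len(token$samples, n) * photodiode_gain
  }

  ## --- ERG, block-wise with temperature-coupled tau and delay ----------
  blocks <- list()
  for (e in seq_len(nrow(epochs))) {
    b0 <- seq(epochs$start[e], epochs$end[e] - 1e-9, by = block_s)
    blocks <- c(blocks, lapply(b0, function(s)
      c(start = s, end = min(epochs$end[e], s + block_s),
        epoch = e)))
  }
  erg_clean <- numeric(n)
  truth <- vector("list", length(blocks))
  for (bi in seq_along(blocks)) {
    b <- blocks[[bi]]
    i0 <- as.integer(round(b[["start"]] * rate)) + 1L
    i1 <- as.integer(round(b[["end"]] * rate))
    xb <- stim[i0:i1]
    t_b <- mean(temp[i0:i1])
    tau_b <- tau_scale * tau_from_temperature(t_b, temp_model)
    label <- epochs$label[b[["epoch"]]]
    if (protocol == "pulse") {
      target <- pulse_targets[[label]] + latency_offset
      off <- halfmax_filter_offset(rate, params$beta, tau_b, params$zeta,
                                   params$polarity,
                                   pulse_width = stimulus$pulse_width,
                                   pulse_amp = 1)
    } else {
      # heating transients deliberately touch the edge of the supported
      # temperature range; the range warning is for analysis use
      target <- if (!is.null(fixed_latency)) fixed_latency + latency_offset
        else suppressWarnings(
          latency_from_temperature(t_b, temp_model, latency_offset,
                                   latency_slope_offset))
      off <- xcorr_filter_offset(xb, rate, params$beta, tau_b, params$zeta,
                                 params$polarity)
    }
    delay_b <- target - off
    if (delay_b < 0)
      stop("simulate_session: calibrated pure delay is negative; ",
           "target latency too short for this filter", call. = FALSE)
    erg_clean[i0:i1] <- fft_filter_delay(xb, rate, params$beta, tau_b,
                                         params$zeta, delay_b,
                                         params$polarity)
    truth[[bi]] <- data.frame(block_start = b[["start"]],
                              block_end = b[["end"]], condition = label,
                              temperature_C = t_b, tau_ms = tau_b,
                              zeta = params$zeta, beta = params$beta,
                              target_latency_ms = target,
                              delay_ms = delay_b)
  }
  truth <- do.call(rbind, truth)

  ## --- noise, artefact, motion -----------------------------------------
  out <- with_seed(seed, {
    s_clean <- stats::sd(erg_clean)
    erg <- erg_clean
    if (noise_frac > 0)
      erg <- erg + stats::rnorm(n, sd = noise_frac * s_clean)
    if (artefact_frac > 0)
      erg <- erg + artefact_frac * s_clean *
        sin(2 * pi * 150 * tt + stats::runif(1, 0, 2 * pi))
    motion <- numeric(n)
    if (protocol == "walking") {
      a0 <- epochs$start[epochs$label == "active"]
      a1 <- epochs$end[epochs$label == "active"]
      act <- tt >= a0 & tt < a1
      knots <- pmax(0.5, stats::rnorm(ceiling((a1 - a0) * 2) + 1, 5, 2))
      motion[act] <- stats::approx(seq(a0, a1, length.out = length(knots)),
                                   knots, xout = tt[act])$y
    }
    list(erg = erg, motion = motion)
  })

  structure(list(
    animal_id = animal_id,
    channels = list(
      stimulus = time_series(stim, rate, units = "V"),
      erg = time_series(out$erg, rate, units = "mV"),
      temperature = time_series(temp, rate, units = "degC"),
      motion = time_series(out$motion, rate, units = "mm/s")),
    epochs = epochs, protocol = protocol,
    intensity = stimulus$mean_intensity, onsets = onsets,
    truth = truth), class = "erg_session")
}

#' @export
print.erg_session <- function(x, ...) {
  cat(sprintf("<erg_session> %s, protocol %s, %.0f s @ %g Hz, epochs: %s\n",
              x$animal_id, x$protocol,
              ts_duration(x$channels$erg), x$channels$erg$rate,
              paste(x$epochs$label, collapse = "/")))
  invisible(x)
}

#' Cohort specification for synthetic sessions
#'
#' @param n_animals Number of animals (>= 1).
#' @param protocol `"walking"`, `"heating"` or `"pulse"`.
#' @param latency_intercept_sd Per-animal latency offset sd in ms.
#' @param latency_slope_sd Per-animal temperature-slope offset sd (ms/degC).
#' @param tau_scale_sd Log-sd of extra per-animal tau scatter beyond the
#'   temperature coupling (default 0: between-animal tau differences are
#'   mediated by the condition-temperature spread, keeping the generating
#'   condition median exactly at the temperature-model value).
#' @param beta_sd Log-sd of the per-animal amplitude scatter.
#' @param zeta_sd Log-sd of the per-animal damping scatter.
#' @param before_temp,before_temp_sd Sitting-condition temperature mean/sd
#'   in degC (walking default 27.6 +- 1.7, heating 26.9 +- 1.2).
#' @param active_temp,active_temp_sd Active-condition (evaluation window)
#'   temperature mean/sd (walking 29.9 +- 2.0, heating 31.9 +- 2.0).
#' @param pulse_target_medians Pulse protocol: condition target half-max
#'   latency medians in ms.
#' @param pulse_offset_sd Pulse protocol: per-animal latency offset sd (ms).
#' @param center If `TRUE` (default), per-animal draws are median-centred so
#'   the cohort's generating condition medians equal the stated values
#'   exactly - the construction required for parameter-recovery validation.
#' @param seed Integer seed.
#' @return A list of class `"cohort_spec"`.
#' @export
cohort_spec <- function(n_animals, protocol = c("walking", "heating",
                                                "pulse"),
                        latency_intercept_sd = 0.4, latency_slope_sd = 0.02,
                        tau_scale_sd = 0, beta_sd = 0.2, zeta_sd = 0.03,
                        before_temp = NULL, before_temp_sd = NULL,
                        active_temp = NULL, active_temp_sd = 2.0,
                        pulse_target_medians = c(before = 10.3,
                                                 active = 8.7,
                                                 after = 10.1),
                        pulse_offset_sd = 0.8, center = TRUE, seed = 1L) {
  protocol <- match.arg(protocol)
  if (n_animals < 1) stop("cohort_spec: n_animals >= 1", call. = FALSE)
  if (is.null(before_temp))
    before_temp <- if (protocol == "walking") 27.6 else 26.9
  if (is.null(before_temp_sd))
    before_temp_sd <- if (protocol == "walking") 1.7 else 1.2
  if (is.null(active_temp))
    active_temp <- if (protocol == "walking") 29.9 else 31.9
  structure(list(n_animals = as.integer(n_animals), protocol = protocol,
                 latency_intercept_sd = latency_intercept_sd,
                 latency_slope_sd = latency_slope_sd,
                 tau_scale_sd = tau_scale_sd, beta_sd = beta_sd,
                 zeta_sd = zeta_sd, before_temp = before_temp,
                 before_temp_sd = before_temp_sd, active_temp = active_temp,
                 active_temp_sd = active_temp_sd,
                 pulse_target_medians = pulse_target_medians,
                 pulse_offset_sd = pulse_offset_sd, center = center,
                 seed = as.integer(seed)), class = "cohort_spec")
}

# median-centre a draw vector (no-op when centring is disabled)
centre <- function(x, on) if (on) x - stats::median(x) else x

#' Simulate a cohort of sessions
#'
#' Draws per-animal random effects (condition temperatures, latency offsets,
#' tau/beta/zeta scatter) once per animal and generates one session per
#' animal with [simulate_session()]. With `center = TRUE` the cohort's
#' generating condition medians equal the specified condition values
#' exactly (median-pinned cohorts), which is what end-to-end
#' parameter-recovery checks require.
#'
#' The walking plateau rise and heating peak are back-computed from each
#' animal's drawn active-condition temperature through the post-active
#' decay, so the 5 s evaluation window immediately after the active epoch
#' sits at the drawn condition temperature (heating peaks land near 37
#' degC).
#'
#' @param spec A `cohort_spec`.
#' @param ... Further arguments passed to [simulate_session()] (e.g.
#'   `epoch_durations`, `noise_frac`).
#' @return List of `erg_session`, one per animal.
#' @export
simulate_cohort <- function(spec, ...) {
  stopifnot(inherits(spec, "cohort_spec"))
  nA <- spec$n_animals
  # per-animal active temperature = own baseline + a positive rise, so each
  # animal warms during the active epoch (as every real animal did); the
  # rise sd is chosen so the active-condition spread matches the stated sd
  rise_mean <- spec$active_temp - spec$before_temp
  rise_sd <- sqrt(max(spec$active_temp_sd^2 - spec$before_temp_sd^2, 0))
  draws <- with_seed(spec$seed, {
    before_t <- spec$before_temp +
      centre(stats::rnorm(nA, 0, spec$before_temp_sd), spec$center)
    rise <- pmax(stats::rnorm(nA, rise_mean, rise_sd), 0.3)
    active_t <- before_t + rise
    if (spec$center)
      active_t <- active_t - stats::median(active_t) + spec$active_temp
    list(
    before_t = before_t,
    active_t = active_t,
    lat_off = centre(stats::rnorm(nA, 0, spec$latency_intercept_sd),
                     spec$center),
    slope_off = centre(stats::rnorm(nA, 0, spec$latency_slope_sd),
                       spec$center),
    tau_scale = exp(centre(stats::rnorm(nA, 0, spec$tau_scale_sd),
                           spec$center)),
    beta = exp(stats::rnorm(nA, 0, spec$beta_sd)),
    zeta = 0.150 * exp(centre(stats::rnorm(nA, 0, spec$zeta_sd),
                              spec$center)),
    pulse_off = centre(stats::rnorm(nA, 0, spec$pulse_offset_sd),
                       spec$center),
    seeds = sample.int(2^30, nA))
  })

  # mean temperature of the post-active 5 s window relative to the plateau:
  # plateau rise needed = (active condition temp - baseline) / g
  decay <- if (spec$protocol == "heating") 3 else 120
  g <- (decay / 5) * (1 - exp(-5 / decay))

  lapply(seq_len(nA), function(i) {
    id <- sprintf("%s%02d", substr(spec$protocol, 1, 1), i)
    if (spec$protocol == "pulse") {
      simulate_session("pulse", animal_id = id,
        params = photoreceptor_params(beta = draws$beta[i],
                                      zeta = draws$zeta[i]),
        baseline_temp = draws$before_t[i],
        pulse_targets = spec$pulse_target_medians + draws$pulse_off[i],
        seed = draws$seeds[i], ...)
    } else {
      rise <- (draws$active_t[i] - draws$before_t[i]) / g
      # the heat lamp was regulated to ~37 degC; cap the plateau there so
      # extreme draws cannot push the eye outside the physiological range
      if (spec$protocol == "heating")
        rise <- min(rise, 38.5 - draws$before_t[i])
      simulate_session(spec$protocol, animal_id = id,
        params = photoreceptor_params(beta = draws$beta[i],
                                      zeta = draws$zeta[i]),
        baseline_temp = draws$before_t[i],
        temp_rise = if (spec$protocol == "walking") rise else 2.3,
        peak_temp = if (spec$protocol == "heating")
          draws$before_t[i] + rise else 37,
        latency_offset = draws$lat_off[i],
        latency_slope_offset = draws$slope_off[i],
        tau_scale = draws$tau_scale[i],
        seed = draws$seeds[i], ...)
    }
  })
}

#' Simulate an adaptation (intensity) series
#'
#' One sitting session per light intensity for a single animal. Latency
#' follows a log-intensity adaptation model calibrated so that the default
#' four study intensities span a 1.4 ms latency difference between lowest
#' and highest.
#'
#' @param intensities Ascending light intensities in photons cm^-2 s^-1
#'   (default: the four study values).
#' @param reference_latency Latency in ms at the lowest intensity (default:
#'   the sitting latency at the default baseline temperature).
#' @param latency_drop_ms Latency decrease from lowest to highest default
#'   intensity (calibrates the log-intensity slope; default 1.4).
#' @param animal_id Animal label.
#' @param duration Session duration in s per intensity (single sitting
#'   epoch).
#' @param seed Integer seed.
#' @param ... Passed to [simulate_session()].
#' @return List of `erg_session`, one per intensity.
#' @export
simulate_intensity_series <- function(intensities = c(1.74e14, 7.27e14,
                                                      1.31e15, 2.41e15),
                                      reference_latency = NULL,
                                      latency_drop_ms = 1.4,
                                      animal_id = "i01", duration = 20,
                                      seed = 1L, ...) {
  if (any(diff(intensities) <= 0) || any(intensities <= 0))
    stop("simulate_intensity_series: intensities must be positive and ",
         "ascending", call. = FALSE)
  if (is.null(reference_latency))
    reference_latency <- latency_from_temperature(26.9)
  span <- log10(2.41e15 / 1.74e14)      # default calibration span
  k <- latency_drop_ms / span           # ms per decade
  seeds <- with_seed(seed, sample.int(2^30, length(intensities)))
  lapply(seq_along(intensities), function(j) {
    lat <- reference_latency - k * log10(intensities[j] / intensities[1])
    simulate_session("intensity", animal_id = animal_id,
                     stimulus = stimulus_spec("noise",
                                              mean_intensity = intensities[j]),
                     fixed_latency = lat, baseline_temp = 26.9,
                     epoch_durations = c(before = duration),
                     seed = seeds[j], ...)
  })
}

#' Simulate measurement-level latency-temperature cohorts
#'
#' Generates the tidy latency/temperature table that the mixed-effects
#' analysis consumes: per-animal random intercepts and temperature slopes
#' around the population relation, a configurable treatment offset for the
#' heated group, and residual noise. Defaults mirror the reference design: 12
#' walking and 22 heated animals with 5 eye-temperature points each.
#'
#' @param n_walking,n_heated Animals per treatment group.
#' @param temps_per_animal Temperature points per animal (evenly spaced over
#'   the animal's range).
#' @param model A `temperature_model` (population intercept/slope).
#' @param re_intercept_sd,re_slope_sd Random-effect sds (ms, ms/degC).
#' @param resid_sd Residual sd in ms.
#' @param treatment_offset Additive latency offset (ms) for the heated
#'   group (default 0).
#' @param walking_range,heated_range Temperature ranges in degC.
#' @param center Mean-centre the random-effect draws (default TRUE).
#' @param seed Integer seed.
#' @return data.frame with columns `animal`, `treatment`, `temperature_C`,
#'   `latency_ms`.
#' @export
simulate_latency_cohort <- function(n_walking = 12, n_heated = 22,
                                    temps_per_animal = 5,
                                    model = temperature_model(),
                                    re_intercept_sd = 0.4,
                                    re_slope_sd = 0.02, resid_sd = 0.25,
                                    treatment_offset = 0,
                                    walking_range = c(26.5, 31.5),
                                    heated_range = c(26, 35),
                                    center = TRUE, seed = 1L) {
  nA <- n_walking + n_heated
  with_seed(seed, {
    b0 <- stats::rnorm(nA, 0, re_intercept_sd)
    b1 <- stats::rnorm(nA, 0, re_slope_sd)
    if (center) { b0 <- b0 - mean(b0); b1 <- b1 - mean(b1) }
    rows <- lapply(seq_len(nA), function(i) {
      heated <- i > n_walking
      rng <- if (heated) heated_range else walking_range
      rng <- rng + stats::runif(1, -0.5, 0.5)
      temps <- seq(rng[1], rng[2], length.out = temps_per_animal)
      lat <- latency_from_temperature(temps, model, b0[i], b1[i]) +
        (if (heated) treatment_offset else 0) +
        stats::rnorm(temps_per_animal, 0, resid_sd)
      data.frame(animal = sprintf("lm%02d", i),
                 treatment = if (heated) "heated" else "walking",
                 temperature_C = temps, latency_ms = lat,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}
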