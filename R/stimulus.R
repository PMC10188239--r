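#' Stimulus specification
#'
#' Bundles the parameters of the light stimuli used throughout the package:
#' band-limited Gaussian white noise for system identification and
#' rectangular pulse trains for half-maximum latency measurements.
#'
#' @param kind `"noise"` or `"pulse"`.
#' @param duration Stimulus duration in seconds.
#' @param mean_intensity Mean light intensity in photons cm^-2 s^-1.
#' @param pulse_width Pulse width in ms (pulse kind).
#' @param pulse_rate Pulse repetition rate in Hz (pulse kind).
#' @param corner_freq Low-pass corner frequency in Hz (noise kind).
#' @param filter_order Butterworth order in poles (noise kind).
#' @param contrast Noise modulation depth (sd / mean) after intensity scaling.
#' @param seed Integer seed for the noise token.
#'
#' @return A list of class `"stimulus_spec"`.
#' @export
stimulus_spec <- function(kind = c("noise", "pulse"), duration = 10,
                          mean_intensity = 1.74e14, pulse_width = 50,
                          pulse_rate = 1, corner_freq = 250,
                          filter_order = 9, contrast = 0.32, seed = 1L) {
  kind <- match.arg(kind)
  if (mean_intensity <= 0)
    stop("stimulus_spec: mean_intensity must be positive", call. = FALSE)
  if (kind == "noise") {
    if (corner_freq <= 0 || filter_order < 1)
      stop("stimulus_spec: noise kind needs corner_freq > 0, filter_order >= 1",
           call. = FALSE)
  } else {
    if (pulse_width * pulse_rate >= 1000)
      stop("stimulus_spec: pulse duty cycle must be < 1", call. = FALSE)
  }
  structure(list(kind = kind, duration = duration,
                 mean_intensity = mean_intensity, pulse_width = pulse_width,
                 pulse_rate = pulse_rate, corner_freq = corner_freq,
                 filter_order = filter_order, contrast = contrast,
                 seed = as.integer(seed)),
            class = "stimulus_spec")
}

#' Generate Gaussian white noise
#'
#' Zero-mean, unit-variance Gaussian noise token, the raw material for the
#' band-limited noise light stimulus (a 10 s token by convention).
#'
#' @param duration Duration in seconds (default 10).
#' @param rate Sampling rate in Hz (default 3000, the digitization rate).
#' @param seed Integer seed; fixed seed gives an identical token.
#'
#' @return An `erg_ts` with `duration * rate` samples.
#' @export
#' @examples
#' wn <- generate_white_noise(1, 3000, seed = 1)
#' c(mean(wn$samples), stats::sd(wn$samples))
generate_white_noise <- function(duration = 10, rate = 3000, seed = 1L) {
  if (!is.numeric(duration) || duration <= 0)
    stop("generate_white_noise: duration must be positive", call. = FALSE)
  if (!is.numeric(rate) || rate <= 0)
    stop("generate_white_noise: rate must be positive", call. = FALSE)
  n <- as.integer(round(duration * rate))
  samples <- with_seed(seed, stats::rnorm(n))
  time_series(samples, rate, units = "a.u.")
}

#' Digital Butterworth low-pass filter
#'
#' Maximally flat low-pass with unit DC gain, applied causally. The standard
#' noise stimulus is shaped with a nine-pole filter at a 250 Hz corner,
#' giving a power spectrum flat to roughly 220 Hz.
#'
#' @param ts An `erg_ts`.
#' @param corner_freq Corner (-3 dB) frequency in Hz; must be below Nyquist.
#' @param order Filter order in poles (default 9).
#'
#' @return Filtered `erg_ts`, same length and rate.
#' @export
butterworth_lowpass <- function(ts, corner_freq = 250, order = 9) {
  stopifnot(inherits(ts, "erg_ts"))
  nyq <- ts$rate / 2
  if (corner_freq >= nyq)
    stop("butterworth_lowpass: corner frequency must be below Nyquist (",
         nyq, " Hz)", call. = FALSE)
  if (order < 1) stop("butterworth_lowpass: order must be >= 1", call. = FALSE)
  bf <- signal::butter(order, corner_freq / nyq, type = "low")
  out <- as.numeric(signal::filter(bf, ts$samples))
  time_series(out, ts$rate, t0 = ts$t0, units = ts$units)
}

#' Generate a rectangular pulse train
#'
#' Light pulses of fixed width at a fixed repetition rate (study default:
#' 50 ms pulses at 1 Hz). Onsets are aligned to the sample grid.
#'
#' @param duration Total duration in seconds.
#' @param rate Sampling rate in Hz.
#' @param pulse_width Pulse width in ms.
#' @param pulse_rate Repetition rate in Hz.
#' @param amplitude Pulse amplitude (stimulus units; baseline is 0).
#'
#' @return List with `ts` (`erg_ts`) and `onsets` (onset times in s).
#' @export
#' @examples
#' pt <- generate_pulse_train(5, 3000, pulse_width = 50, pulse_rate = 1)
#' pt$onsets
generate_pulse_train <- function(duration, rate, pulse_width = 50,
                                 pulse_rate = 1, amplitude = 1) {
  if (pulse_width / 1000 >= 1 / pulse_rate)
    stop("generate_pulse_train: pulses overlap (width >= period)",
         call. = FALSE)
  n <- as.integer(round(duration * rate))
  samples <- numeric(n)
  onsets <- (0:floor(duration * pulse_rate)) / pulse_rate
  onsets <- onsets[onsets < duration - 1e-9]
  w <- as.integer(round(pulse_width / 1000 * rate))
  for (on in onsets) {
    i0 <- as.integer(round(on * rate)) + 1L
    i1 <- min(n, i0 + w - 1L)
    if (i0 <= n) samples[i0:i1] <- amplitude
  }
  list(ts = time_series(samples, rate, units = "a.u."), onsets = onsets)
}

#' Scale a trace to a target mean light intensity
#'
#' Affine rescaling so the output mean equals `mean_intensity` with the
#' stated modulation depth; light intensity cannot be negative, so negative
#' excursions are clipped at zero and the mean is restored multiplicatively.
#' The clipped fraction is recorded as an attribute.
#'
#' @param ts An `erg_ts` (e.g. unit-variance noise).
#' @param mean_intensity Target mean in photons cm^-2 s^-1.
#' @param contrast Modulation depth sd/mean of the output (default 0.32);
#'   ignored for constant inputs.
#'
#' @return An `erg_ts` with non-negative samples and mean `mean_intensity`,
#'   with attribute `clipped_fraction`.
#' @export
scale_intensity <- function(ts, mean_intensity, contrast = 0.32) {
  stopifnot(inherits(ts, "erg_ts"))
  if (mean_intensity <= 0)
    stop("scale_intensity: mean_intensity must be positive", call. = FALSE)
  x <- ts$samples
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) {
    out <- rep(mean_intensity, length(x))
    clipped <- 0
  } else {
    z <- (x - mean(x)) / s
    out <- mean_intensity * (1 + contrast * z)
    clipped <- mean(out < 0)
    out[out < 0] <- 0
    out <- out * (mean_intensity / mean(out))
  }
  res <- time_series(out, ts$rate, t0 = ts$t0, units = "photons cm^-2 s^-1")
  attr(res, "clipped_fraction") <- clipped
  res
}

#' Visual angle subtended by a circular aperture
#'
#' Full angle `2 * atan(diameter / (2 * distance))` in degrees. A 4 mm
#' light guide at 9 cm subtends 2.5 degrees.
#'
#' @param aperture_diameter Aperture diameter (same length unit as distance).
#' @param distance Distance from eye to aperture.
#'
#' @return Visual angle in degrees.
#' @export
#' @examples
#' round(visual_angle(4, 90), 1)
visual_angle <- function(aperture_diameter, distance) {
  if (aperture_diameter <= 0 || distance <= 0)
    stop("visual_angle: inputs must be positive", call. = FALSE)
  if (aperture_diameter > 2 * distance)
    stop("visual_angle: aperture must not exceed twice the distance",
         call. = FALSE)
  2 * atan(aperture_diameter / (2 * distance)) * 180 / pi
}

#' Synthesize a band-limited noise light stimulus
#'
#' Convenience wrapper: Gaussian white noise, Butterworth low-pass, intensity
#' scaling, per the `stimulus_spec`.
#'
#' @param spec A `stimulus_spec` of kind `"noise"`.
#' @param rate Sampling rate in Hz.
#' @return An `erg_ts` in photons cm^-2 s^-1.
#' @export
synth_noise_stimulus <- function(spec, rate = 3000) {
  stopifnot(inherits(spec, "stimulus_spec"), spec$kind == "noise")
  wn <- generate_white_noise(spec$duration, rate, seed = spec$seed)
  fl <- butterworth_lowpass(wn, spec$corner_freq, spec$filter_order)
  scale_intensity(fl, spec$mean_intensity, contrast = spec$contrast)
}

#' Write / read a stimulus as two-column delimited text
#'
#' Plain-text exchange format: `time_s` and `value` columns, tab-separated.
#'
#' @param ts An `erg_ts`.
#' @param path Output file path.
#' @return `write_stimulus_text` returns `path` invisibly;
#'   `read_stimulus_text` returns an `erg_ts` (rate inferred from the grid).
#' @export
write_stimulus_text <- function(ts, path) {
  stopifnot(inherits(ts, "erg_ts"))
  df <- data.frame(time_s = sprintf("%.9f", ts_time(ts)),
                   value = sprintf("%.17g", ts$samples))
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}

#' @rdname write_stimulus_text
#' @param units Unit label to attach on read.
#' @export
read_stimulus_text <- function(path, units = "") {
  df <- data.table::fread(path, sep = "\t", colClasses = "numeric")
  if (!all(c("time_s", "value") %in% names(df)))
    stop("read_stimulus_text: need columns time_s, value", call. = FALSE)
  dt <- diff(df$time_s)
  rate <- 1 / stats::median(dt)
  time_series(df$value, rate, t0 = df$time_s[1], units = units)
}
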