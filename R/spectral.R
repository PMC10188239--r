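#' Anti-aliased resampling to a coarser uniform grid
#'
#' Zero-phase FIR low-pass at the new Nyquist frequency (so resampling does
#' not shift latencies), followed by decimation (integer factors) or linear
#' interpolation onto the new grid. Spectra are conventionally computed after
#' resampling to 1 ms intervals (1 kHz).
#'
#' @param ts An `erg_ts`.
#' @param interval Target sampling interval in ms (default 1); must not be
#'   finer than the native interval.
#'
#' @return An `erg_ts` at the new rate.
#' @export
resample_uniform <- function(ts, interval = 1) {
  stopifnot(inherits(ts, "erg_ts"))
  new_rate <- 1000 / interval
  if (new_rate > ts$rate + 1e-9)
    stop("resample_uniform: upsampling requested (interval finer than ",
         "native)", call. = FALSE)
  if (abs(new_rate - ts$rate) < 1e-9) return(ts)
  w <- (new_rate / 2) / (ts$rate / 2)
  b <- signal::fir1(128, w, type = "low")
  xf <- signal::filtfilt(b, ts$samples)
  q <- ts$rate / new_rate
  if (abs(q - round(q)) < 1e-9) {
    out <- xf[seq(1, length(xf), by = as.integer(round(q)))]
  } else {
    t_old <- ts_time(ts)
    t_new <- seq(ts$t0, t_old[length(t_old)], by = 1 / new_rate)
    out <- stats::approx(t_old, xf, xout = t_new)$y
  }
  time_series(out, new_rate, t0 = ts$t0, units = ts$units)
}

#' Welch cross-spectral estimation
#'
#' Splits both channels into segments (default 512 samples, the standard
#' FFT segment length), applies a taper, and averages per-segment auto- and
#' cross-spectra over the ensemble. Linear coherence and the frequency
#' response (gain) are computed from the averaged spectra:
#' `coherence = |<Sxy>|^2 / (<Sxx> <Syy>)` and `G = <Sxy> / <Sxx>`.
#' Coherence is bounded in `[0, 1]` by the Cauchy-Schwarz inequality on the
#' averaged spectra.
#'
#' @param x,y `erg_ts` with equal rates (input = stimulus, output = ERG).
#' @param segment_len Segment length in samples (default 512).
#' @param window `"hann"` (default) or `"rect"`.
#' @param overlap Fractional overlap between segments (default 0.5; use 0
#'   with `"rect"` for the plainest disjoint-segment reading).
#'
#' @return A list of class `"spectral_estimate"`: `freqs` (Hz, 0..Nyquist),
#'   `Sxx`, `Syy` (one-sided densities), `Sxy` (complex), `gain` (complex),
#'   `coherence`, `n_segments`, `rate`.
#' @export
estimate_spectra <- function(x, y, segment_len = 512,
                             window = c("hann", "rect"), overlap = 0.5) {
  stopifnot(inherits(x, "erg_ts"), inherits(y, "erg_ts"))
  window <- match.arg(window)
  if (x$rate != y$rate)
    stop("estimate_spectra: equal rates required", call. = FALSE)
  n <- min(length(x$samples), length(y$samples))
  if (n < 2 * segment_len)
    stop("estimate_spectra: need at least 2 segments (",
         2 * segment_len, " samples); coherence is undefined from one",
         call. = FALSE)
  step <- max(1L, as.integer(round(segment_len * (1 - overlap))))
  starts <- seq(1L, n - segment_len + 1L, by = step)
  w <- if (window == "hann")
    0.5 - 0.5 * cos(2 * pi * seq_len(segment_len) / (segment_len + 1))
  else rep(1, segment_len)
  U <- sum(w^2)
  half <- segment_len %/% 2 + 1L
  Sxx <- numeric(half); Syy <- numeric(half)
  Sxy <- complex(real = numeric(half), imaginary = numeric(half))
  for (s in starts) {
    xs <- x$samples[s:(s + segment_len - 1L)]
    ys <- y$samples[s:(s + segment_len - 1L)]
    X <- stats::fft((xs - mean(xs)) * w)[1:half]
    Y <- stats::fft((ys - mean(ys)) * w)[1:half]
    Sxx <- Sxx + Mod(X)^2
    Syy <- Syy + Mod(Y)^2
    Sxy <- Sxy + Conj(X) * Y
  }
  m <- length(starts)
  scale <- 1 / (m * U * x$rate)
  Sxx <- Sxx * scale; Syy <- Syy * scale; Sxy <- Sxy * scale
  coh <- ifelse(Sxx > 0 & Syy > 0, Mod(Sxy)^2 / (Sxx * Syy), NA_real_)
  coh <- pmax(0, pmin(1, coh))
  gain <- ifelse(Sxx > 0, Sxy / Sxx, NA_complex_)
  structure(list(freqs = (0:(half - 1L)) * x$rate / segment_len,
                 Sxx = Sxx, Syy = Syy, Sxy = Sxy, gain = gain,
                 coherence = coh, n_segments = m, rate = x$rate),
            class = "spectral_estimate")
}

#' @export
print.spectral_estimate <- function(x, ...) {
  cat(sprintf(
    "<spectral_estimate> %d bins to %g Hz (df = %.3g Hz), %d segments\n",
    length(x$freqs), max(x$freqs), x$freqs[2], x$n_segments))
  invisible(x)
}

#' Gain magnitude from a spectral estimate
#'
#' `|G(f)| = |<Sxy>| / <Sxx>` per frequency bin. Bins with zero input power
#' are flagged missing; the DC bin is conventionally excluded from filter
#' fitting downstream.
#'
#' @param est A `spectral_estimate`.
#' @return data.frame with `freq_Hz`, `gain_mag`, `coherence`.
#' @export
gain_magnitude <- function(est) {
  stopifnot(inherits(est, "spectral_estimate"))
  data.frame(freq_Hz = est$freqs, gain_mag = Mod(est$gain),
             coherence = est$coherence)
}

#' Export a spectral estimate as a delimited table
#'
#' @param est A `spectral_estimate`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_spectra_text <- function(est, path) {
  df <- data.frame(freq_Hz = est$freqs, Sxx = est$Sxx, Syy = est$Syy,
                   Re_Sxy = Re(est$Sxy), Im_Sxy = Im(est$Sxy),
                   gain_mag = Mod(est$gain), coherence = est$coherence)
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}
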