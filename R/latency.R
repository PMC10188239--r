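#' Half-maximum latency of pulse responses
#'
#' For each pulse, the latency is the time from pulse onset to the first
#' crossing of 50% of that response's maximum (absolute) deflection from
#' the pre-onset baseline, linearly interpolated between samples. The mean
#' over the pulses in the segment is returned (the standard evaluation averages 5 s,
#' i.e. five pulses at 1 Hz). The measure is invariant to amplitude scaling
#' of the ERG.
#'
#' @param erg An `erg_ts` ERG trace.
#' @param onsets Pulse onset times in seconds (absolute, same clock as the
#'   trace).
#' @param window Response window after onset in ms (default 100).
#'
#' @return Mean latency in ms over the pulses, with attribute `per_pulse`
#'   (per-pulse latencies, `NA` where no crossing occurred). If no pulse
#'   yields a crossing, an error is signalled.
#' @export
pulse_latency_half_max <- function(erg, onsets, window = 100) {
  stopifnot(inherits(erg, "erg_ts"))
  if (length(onsets) < 1) stop("pulse_latency_half_max: need >= 1 onset",
                               call. = FALSE)
  rate <- erg$rate
  nwin <- as.integer(round(window / 1000 * rate))
  per <- vapply(onsets, function(on) {
    i_on <- as.integer(round((on - erg$t0) * rate)) + 1L
    if (i_on < 1L || i_on + nwin > length(erg$samples)) return(NA_real_)
    # baseline: mean of up to 5 ms immediately before onset
    nb <- min(i_on - 1L, as.integer(round(0.005 * rate)))
    base <- if (nb > 0) mean(erg$samples[(i_on - nb):(i_on - 1L)])
            else erg$samples[i_on]
    resp <- abs(erg$samples[i_on:(i_on + nwin)] - base)
    thr <- max(resp) / 2
    if (thr <= 0) return(NA_real_)
    above <- which(resp >= thr)
    above <- above[above > 1L]
    if (length(above) == 0) return(NA_real_)
    k <- above[1]
    # linear interpolation between samples k-1 and k
    frac <- (thr - resp[k - 1L]) / (resp[k] - resp[k - 1L])
    ((k - 2L + frac) / rate) * 1000
  }, numeric(1))
  if (all(is.na(per)))
    stop("pulse_latency_half_max: no pulse produced a half-maximum crossing",
         call. = FALSE)
  out <- mean(per, na.rm = TRUE)
  attr(out, "per_pulse") <- per
  out
}

#' Normalized cross-correlation between two channels
#'
#' Mean-removed, unit-norm cross-correlation for all lags in
#' `[-max_lag, +max_lag]`. A value of 1 at some lag means identical
#' waveforms (up to amplitude) at that shift, -1 identical waveforms with
#' inverted signs. Positive lags mean `y` is delayed relative to `x`.
#'
#' @param x,y `erg_ts` objects with equal rates and overlapping support of
#'   at least 1 s.
#' @param max_lag Maximum lag in ms (default 30).
#'
#' @return A list of class `"cross_correlogram"` with `lags` (ms, uniform,
#'   strictly increasing) and `values` (correlation coefficients in
#'   `[-1, 1]`).
#' @export
cross_correlate <- function(x, y, max_lag = 30) {
  stopifnot(inherits(x, "erg_ts"), inherits(y, "erg_ts"))
  if (x$rate != y$rate)
    stop("cross_correlate: x and y must share a sampling rate",
         call. = FALSE)
  n <- min(length(x$samples), length(y$samples))
  if (n / x$rate < 1)
    stop("cross_correlate: need >= 1 s of overlapping data", call. = FALSE)
  xs <- x$samples[1:n] - mean(x$samples[1:n])
  ys <- y$samples[1:n] - mean(y$samples[1:n])
  sx <- sqrt(sum(xs^2) / n)
  sy <- sqrt(sum(ys^2) / n)
  if (sx == 0 || sy == 0)
    stop("cross_correlate: zero-variance segment", call. = FALSE)
  L <- as.integer(floor(max_lag / 1000 * x$rate))
  L <- min(L, n - 1L)
  nfft <- 2^ceiling(log2(n + L))
  X <- stats::fft(c(xs, numeric(nfft - n)))
  Y <- stats::fft(c(ys, numeric(nfft - n)))
  cc <- Re(stats::fft(Conj(X) * Y, inverse = TRUE) / nfft)
  # cc[k+1] = sum_t x(t) y(t+k) for k >= 0; negative lags wrap at the end
  pos <- cc[1:(L + 1L)]
  neg <- cc[(nfft - L + 1L):nfft]
  vals <- c(neg, pos) / (n * sx * sy)
  vals <- pmax(-1, pmin(1, vals))
  structure(list(lags = (-L:L) / x$rate * 1000, values = vals),
            class = "cross_correlogram")
}

#' Latency from the cross-correlation extremum
#'
#' The lag at the global minimum of the correlogram (the ERG is inversely
#' correlated with the stimulus), with parabolic sub-sample refinement.
#' Searching the maximum instead is available for non-inverted channels.
#'
#' @param c A `cross_correlogram`.
#' @param search Lag range searched, in ms (default `c(0, 30)`: positive
#'   lags only, causal responses).
#' @param use `"min"` (default, inverted ERG) or `"max"`.
#'
#' @return Latency in ms, with attribute `value` (correlogram value at the
#'   extremum). A warning is raised if the extremum sits on the search
#'   boundary.
#' @export
xcorr_latency <- function(c, search = c(0, 30), use = c("min", "max")) {
  stopifnot(inherits(c, "cross_correlogram"))
  use <- match.arg(use)
  keep <- which(c$lags >= search[1] & c$lags <= search[2])
  if (length(keep) < 3)
    stop("xcorr_latency: search range covers fewer than 3 lags",
         call. = FALSE)
  v <- c$values[keep]
  if (use == "min") v <- -v
  i <- which.max(v)
  if (i == 1L || i == length(v))
    warning("xcorr_latency: extremum at the search boundary; ",
            "latency may be outside the searched range")
  lag <- c$lags[keep[i]]
  if (i > 1L && i < length(v)) {
    y1 <- v[i - 1L]; y2 <- v[i]; y3 <- v[i + 1L]
    den <- y1 - 2 * y2 + y3
    if (den != 0) {
      dlag <- c$lags[keep[2]] - c$lags[keep[1]]
      lag <- lag + 0.5 * (y1 - y3) / den * dlag
    }
  }
  out <- lag
  attr(out, "value") <- c$values[keep[i]]
  out
}

#' Sliding-window latency monitor
#'
#' Continuously estimates the cross-correlation latency between stimulus and
#' ERG in sliding windows across a session, pairing every estimate with the
#' window-mean eye temperature - the continuous latency monitor used during
#' noise stimulation.
#'
#' @param session An `erg_session`.
#' @param window Window length in s (default 5, the evaluation segment
#'   length).
#' @param step Step between windows in s (default 1).
#' @param max_lag,search Passed to [cross_correlate()] / [xcorr_latency()].
#'
#' @return data.frame with one row per window: `animal`, `time_mid` (s),
#'   `condition` (epoch label at the window midpoint), `latency_ms`,
#'   `temperature_C`, `xcorr_value`. Windows where estimation fails yield
#'   `NA` latency.
#' @export
sliding_latency <- function(session, window = 5, step = 1, max_lag = 30,
                            search = c(0, 30)) {
  stopifnot(inherits(session, "erg_session"))
  stim <- session$channels$stimulus
  erg <- session$channels$erg
  temp <- session$channels$temperature
  dur <- ts_duration(erg)
  starts <- seq(0, dur - window, by = step)
  rows <- lapply(starts, function(s) {
    lat <- NA_real_; val <- NA_real_
    res <- try(suppressWarnings({
      cg <- cross_correlate(ts_window(stim, s, s + window),
                            ts_window(erg, s, s + window), max_lag)
      xcorr_latency(cg, search = search)
    }), silent = TRUE)
    if (!inherits(res, "try-error")) {
      lat <- as.numeric(res); val <- attr(res, "value")
    }
    mid <- s + window / 2
    cond <- session$epochs$label[session$epochs$start <= mid &
                                   session$epochs$end > mid][1]
    data.frame(animal = session$animal_id, time_mid = mid,
               condition = if (is.na(cond)) NA_character_ else cond,
               latency_ms = lat,
               temperature_C = mean(ts_window(temp, s, s + window)$samples),
               xcorr_value = val, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
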