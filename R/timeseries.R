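#' Uniformly sampled time series
#'
#' Lightweight carrier for every channel handled by the package: a numeric
#' sample vector together with its sampling rate, start time and unit label.
#'
#' @param samples Numeric vector of samples (finite values only).
#' @param rate Sampling rate in Hz (samples per second), must be positive.
#' @param t0 Time of the first sample in seconds.
#' @param units Unit label for the samples (informational).
#'
#' @return An object of class `"erg_ts"`: a list with elements `samples`,
#'   `rate`, `t0` and `units`.
#' @export
#' @examples
#' ts <- time_series(sin(2 * pi * 5 * seq(0, 1, by = 1e-3)), rate = 1000)
#' ts_duration(ts)
time_series <- function(samples, rate, t0 = 0, units = "") {
  samples <- as.numeric(samples)
  if (length(samples) < 1L)
    stop("time_series: need at least one sample", call. = FALSE)
  if (!all(is.finite(samples)))
    stop("time_series: samples must all be finite", call. = FALSE)
  if (!is.numeric(rate) || length(rate) != 1L || !is.finite(rate) || rate <= 0)
    stop("time_series: rate must be a positive number", call. = FALSE)
  structure(list(samples = samples, rate = rate, t0 = as.numeric(t0),
                 units = as.character(units)),
            class = "erg_ts")
}

#' @export
print.erg_ts <- function(x, ...) {
  cat(sprintf("<erg_ts> %d samples @ %g Hz, t0 = %g s, units = '%s'\n",
              length(x$samples), x$rate, x$t0, x$units))
  invisible(x)
}

#' Time axis of a time series
#'
#' @param ts An `erg_ts` object.
#' @return Numeric vector of sample times in seconds.
#' @export
ts_time <- function(ts) {
  ts$t0 + (seq_along(ts$samples) - 1L) / ts$rate
}

#' Duration of a time series in seconds
#'
#' @param ts An `erg_ts` object.
#' @return Duration (number of samples / rate) in seconds.
#' @export
ts_duration <- function(ts) length(ts$samples) / ts$rate

#' Extract a time window from a time series
#'
#' @param ts An `erg_ts` object.
#' @param start,end Absolute start/end times in seconds (`[start, end)`).
#' @return An `erg_ts` covering the requested window.
#' @export
ts_window <- function(ts, start, end) {
  if (end <= start) stop("ts_window: end must exceed start", call. = FALSE)
  i0 <- max(1L, 1L + as.integer(round((start - ts$t0) * ts$rate)))
  i1 <- min(length(ts$samples), as.integer(round((end - ts$t0) * ts$rate)))
  if (i1 < i0) stop("ts_window: window outside the recording", call. = FALSE)
  time_series(ts$samples[i0:i1], ts$rate,
              t0 = ts$t0 + (i0 - 1L) / ts$rate, units = ts$units)
}

# Run a block of code under a local, restorable RNG state. Used so that
# every randomized operation takes an explicit seed without clobbering the
# caller's stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  force(code)
}
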