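#' Gain magnitude of the second-order low-pass model
#'
#' `|H(f)| = beta / sqrt((1 - (w*tau)^2)^2 + (2*w*tau*zeta)^2)` with
#' `w = 2*pi*f`. At DC this is `beta`; at `w*tau = 1` it is `beta/(2*zeta)`
#' (the real part cancels); damping below 1/sqrt(2) yields a resonance peak
#' at `f = sqrt(1 - 2*zeta^2) / (2*pi*tau)`.
#'
#' @param f Frequency in Hz (vectorized).
#' @param beta Amplitude (DC gain).
#' @param tau Time constant in ms.
#' @param zeta Damping factor.
#' @return Gain magnitude at each frequency.
#' @export
#' @examples
#' model_gain(0, 2, 1.41, 0.15)        # DC gain = beta
#' f1 <- 1 / (2 * pi * 1.41e-3)        # w * tau = 1
#' model_gain(f1, 1, 1.41, 0.15)       # beta / (2 zeta)
model_gain <- function(f, beta, tau, zeta) {
  x <- 2 * pi * f * (tau / 1000)
  beta / sqrt((1 - x^2)^2 + (2 * x * zeta)^2)
}

#' Coherence-weighted fit of the second-order low-pass filter
#'
#' Weighted least squares of [model_gain()] against a measured gain
#' magnitude curve, with weights given by the linear coherence at each
#' frequency (bins the stimulus does not drive, or that noise dominates,
#' carry little weight). Parameters are optimized on the log scale
#' (enforcing positivity) by Levenberg-Marquardt with a peak-frequency
#' initialization plus jittered restarts under a fixed seed; the returned
#' fit is the restart with the lowest weighted residual sum of squares.
#'
#' @param freqs Frequency grid in Hz.
#' @param gain_mag Measured gain magnitudes (same length).
#' @param coherence_weights Weights in `[0, 1]` (typically the coherence).
#' @param freq_range Fitted band in Hz (default `c(2, 220)`: drop the DC
#'   region, honour the stimulus flatness limit).
#' @param exclude_bands Matrix of `(lo, hi)` rows removed from the fit;
#'   default excludes 146-154 Hz around the 150 Hz line artefact.
#' @param n_restarts Number of jittered restarts (default 5).
#' @param seed Seed for the restart jitter.
#' @param log_domain Fit log-magnitudes instead of magnitudes (default
#'   FALSE: weight the magnitude residuals directly).
#'
#' @return A list of class `"filter_fit_result"`: `beta`, `tau_ms`, `zeta`,
#'   `weighted_rss`, `n_freqs`, `converged`, `freq_range`, `init_rss`
#'   (weighted RSS at each initialization point).
#' @export
fit_gain <- function(freqs, gain_mag, coherence_weights,
                     freq_range = c(2, 220),
                     exclude_bands = matrix(c(146, 154), ncol = 2),
                     n_restarts = 5, seed = 1L, log_domain = FALSE) {
  stopifnot(length(freqs) == length(gain_mag),
            length(freqs) == length(coherence_weights))
  if (any(coherence_weights < 0 | coherence_weights > 1, na.rm = TRUE))
    stop("fit_gain: weights must lie in [0, 1]", call. = FALSE)
  keep <- freqs >= freq_range[1] & freqs <= freq_range[2] &
    is.finite(gain_mag) & is.finite(coherence_weights) & gain_mag > 0
  if (!is.null(exclude_bands))
    for (r in seq_len(nrow(exclude_bands)))
      keep <- keep & !(freqs >= exclude_bands[r, 1] &
                         freqs <= exclude_bands[r, 2])
  f <- freqs[keep]; g <- gain_mag[keep]; wts <- coherence_weights[keep]
  if (length(f) < 10)
    stop("fit_gain: fewer than 10 usable frequency bins in range",
         call. = FALSE)

  resid_fun <- function(p) {
    m <- model_gain(f, exp(p[1]), exp(p[2]), exp(p[3]))
    if (log_domain) sqrt(wts) * (log(m) - log(g))
    else sqrt(wts) * (m - g)
  }
  rss <- function(p) sum(resid_fun(p)^2)

  # peak-frequency heuristic initialization
  f_peak <- f[which.max(g)]
  tau0 <- 1000 / (2 * pi * max(f_peak, f[1]))
  beta0 <- g[1]
  starts <- list(log(c(beta0, tau0, 0.2)))
  jit <- with_seed(seed,
                   matrix(stats::rnorm(3 * n_restarts, 0, 0.3),
                          ncol = 3))
  for (i in seq_len(n_restarts))
    starts[[i + 1L]] <- starts[[1L]] + jit[i, ]

  best <- NULL; init_rss <- numeric(length(starts))
  for (i in seq_along(starts)) {
    init_rss[i] <- rss(starts[[i]])
    fit <- try(minpack.lm::nls.lm(par = starts[[i]], fn = resid_fun,
                                  control = minpack.lm::nls.lm.control(
                                    maxiter = 200)),
               silent = TRUE)
    if (inherits(fit, "try-error")) next
    r <- sum(fit$fvec^2)
    if (is.null(best) || r < best$rss)
      best <- list(par = fit$par, rss = r, info = fit$info)
  }
  if (is.null(best))
    stop("fit_gain: no restart converged; gain curve may be degenerate",
         call. = FALSE)
  p <- exp(best$par)
  structure(list(beta = p[1], tau_ms = p[2], zeta = p[3],
                 weighted_rss = best$rss, n_freqs = length(f),
                 converged = best$info %in% 1:4,
                 freq_range = freq_range, init_rss = init_rss),
            class = "filter_fit_result")
}

#' @export
print.filter_fit_result <- function(x, ...) {
  cat(sprintf(paste0("<filter_fit_result> beta = %.4g, tau = %.4g ms, ",
                     "zeta = %.4g (wRSS %.3g over %d bins, %s)\n"),
              x$beta, x$tau_ms, x$zeta, x$weighted_rss, x$n_freqs,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Normalize fitted amplitudes within animals
#'
#' Divides each animal's fitted amplitude `beta` by that animal's maximum
#' `beta` across its conditions, so every animal's largest amplitude is 1 -
#' the normalization used when comparing amplitudes across conditions.
#'
#' @param fits data.frame with columns `animal`, `condition`, `beta`
#'   (>= 2 conditions per animal).
#' @return The input with an added `beta_norm` column.
#' @export
normalize_beta <- function(fits) {
  stopifnot(is.data.frame(fits),
            all(c("animal", "condition", "beta") %in% names(fits)))
  tab <- table(fits$animal)
  if (any(tab < 2))
    stop("normalize_beta: need >= 2 conditions per animal", call. = FALSE)
  mx <- tapply(fits$beta, fits$animal, max)
  if (any(mx <= 0))
    stop("normalize_beta: non-positive maximum amplitude", call. = FALSE)
  fits$beta_norm <- fits$beta / as.numeric(mx[as.character(fits$animal)])
  fits
}
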