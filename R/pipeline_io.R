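#' Analysis configuration
#'
#' Bundles every tunable of the pipeline with the protocol defaults: 5 s
#' evaluation segments with a >= 300 s recovery, 1 ms spectral resampling,
#' 512-point Welch segments (Hann, 50% overlap), a 2-220 Hz fit band
#' excluding 146-154 Hz around the 150 Hz artefact, 5 fit restarts, and the
#' three Bonferroni-corrected condition contrasts at alpha = 0.05.
#'
#' @param window_s Evaluation segment length in s.
#' @param recovery_min_s Minimum recovery delay for the `after` segment, s.
#' @param active_segment `"post"` (5 s immediately after the active epoch;
#'   noise protocols, avoiding movement artefacts) or `"within"` (last 5 s
#'   of the active epoch; pulse protocol).
#' @param resample_interval_ms Spectral resampling interval in ms.
#' @param segment_len Welch segment length in samples.
#' @param spec_window,spec_overlap Welch taper and overlap.
#' @param fit_freq_range Fitted band in Hz.
#' @param artefact_band Excluded band in Hz (`c(lo, hi)` or NULL).
#' @param n_restarts Fit restarts.
#' @param max_lag_ms,search_ms Cross-correlation lag bounds in ms.
#' @param pulse_window_ms Pulse response window in ms.
#' @param alpha Family-wise alpha for condition contrasts.
#' @param seed Seed governing every stochastic step of an analysis run.
#' @return A list of class `"analysis_config"`.
#' @export
analysis_config <- function(window_s = 5, recovery_min_s = 300,
                            active_segment = c("post", "within"),
                            resample_interval_ms = 1, segment_len = 512,
                            spec_window = "hann", spec_overlap = 0.5,
                            fit_freq_range = c(2, 220),
                            artefact_band = c(146, 154), n_restarts = 5,
                            max_lag_ms = 30, search_ms = c(0, 30),
                            pulse_window_ms = 100, alpha = 0.05,
                            seed = 1L) {
  active_segment <- match.arg(active_segment)
  stopifnot(window_s >= 1, recovery_min_s >= 0, segment_len >= 64,
            alpha > 0, alpha < 1)
  structure(as.list(environment()), class = "analysis_config")
}

#' Write / read a session container
#'
#' Plain-text directory container: one two-column delimited file per
#' channel (`time_s`, `value`, serialized at full precision so the
#' round-trip is bit-exact), an `epochs.tsv` table and a `meta.json` with
#' animal id, protocol, intensity, rates and units.
#'
#' @param session An `erg_session`.
#' @param path Directory to create/overwrite.
#' @return `write_session` returns `path` invisibly; `read_session` an
#'   `erg_session`.
#' @export
write_session <- function(session, path) {
  stopifnot(inherits(session, "erg_session"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(session$channels))
    write_stimulus_text(session$channels[[nm]],
                        file.path(path, paste0(nm, ".tsv")))
  data.table::fwrite(session$epochs, file.path(path, "epochs.tsv"),
                     sep = "\t")
  meta <- list(animal_id = session$animal_id, protocol = session$protocol,
               intensity = session$intensity, onsets = session$onsets,
               channels = lapply(session$channels, function(ch)
                 list(rate = ch$rate, t0 = ch$t0, units = ch$units)))
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_session
#' @export
read_session <- function(path) {
  required <- c("stimulus", "erg", "temperature", "motion")
  files <- file.path(path, paste0(required, ".tsv"))
  missing <- required[!file.exists(files)]
  if (length(missing))
    stop("read_session: container is missing channel(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  meta <- jsonlite::read_json(file.path(path, "meta.json"),
                              simplifyVector = TRUE)
  channels <- lapply(required, function(nm) {
    ts <- read_stimulus_text(file.path(path, paste0(nm, ".tsv")))
    cm <- meta$channels[[nm]]
    time_series(ts$samples, cm$rate, t0 = cm$t0, units = cm$units)
  })
  names(channels) <- required
  epochs <- as.data.frame(data.table::fread(file.path(path, "epochs.tsv")))
  structure(list(animal_id = meta$animal_id, channels = channels,
                 epochs = epochs, protocol = meta$protocol,
                 intensity = meta$intensity,
                 onsets = if (is.null(meta$onsets)) NULL
                   else as.numeric(meta$onsets),
                 truth = NULL), class = "erg_session")
}

#' Evaluation segments for the three conditions
#'
#' Places the 5 s evaluation segments: `before` immediately preceding the
#' active epoch, `active` immediately after it (noise protocols; movement
#' artefacts preclude using the walking period itself) or within its last
#' 5 s (pulse protocol), and `after` at least the recovery delay (default
#' 300 s) past the end of activity. Epoch boundaries come from the labelled
#' epochs, or are derived from the motion channel (forward speed above a
#' threshold for at least 2 s).
#'
#' @param session An `erg_session`.
#' @param config An `analysis_config`.
#' @param from_motion If TRUE, derive the active epoch from the motion
#'   channel instead of the labels.
#' @param motion_threshold Speed threshold (channel units) for
#'   `from_motion`.
#' @return data.frame with columns `condition`, `start`, `end`,
#'   `available`.
#' @export
segment_conditions <- function(session, config = analysis_config(),
                               from_motion = FALSE, motion_threshold = 1) {
  stopifnot(inherits(session, "erg_session"))
  w <- config$window_s
  if (from_motion) {
    mo <- session$channels$motion
    on <- mo$samples > motion_threshold
    r <- rle(on)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values & (r$lengths / mo$rate >= 2)
    if (!any(keep))
      stop("segment_conditions: no motion bout >= 2 s found", call. = FALSE)
    a0 <- (starts[keep][1] - 1L) / mo$rate
    a1 <- ends[keep][sum(keep)] / mo$rate
  } else {
    act <- session$epochs[session$epochs$label == "active", ]
    if (nrow(act) == 0)
      stop("segment_conditions: session has no active epoch", call. = FALSE)
    a0 <- act$start[1]; a1 <- act$end[1]
  }
  dur <- ts_duration(session$channels$erg)
  active_seg <- if (config$active_segment == "within")
    c(max(a0, a1 - w), a1) else c(a1, a1 + w)
  segs <- data.frame(
    condition = c("before", "active", "after"),
    start = c(a0 - w, active_seg[1], a1 + config$recovery_min_s),
    end = c(a0, active_seg[2], a1 + config$recovery_min_s + w),
    stringsAsFactors = FALSE)
  segs$available <- segs$start >= 0 & segs$end <= dur + 1e-9
  segs
}

# latency + spectral fit for one evaluation segment of one session
analyze_segment <- function(session, seg, config) {
  stim <- ts_window(session$channels$stimulus, seg$start, seg$end)
  erg <- ts_window(session$channels$erg, seg$start, seg$end)
  temp <- mean(ts_window(session$channels$temperature, seg$start,
                         seg$end)$samples)
  out <- list(temperature_C = temp, latency_ms = NA_real_,
              fit = NULL)
  if (identical(session$protocol, "pulse")) {
    ons <- session$onsets[session$onsets >= seg$start &
                            session$onsets + config$pulse_window_ms / 1000 <=
                            seg$end]
    res <- try(pulse_latency_half_max(erg, ons,
                                      window = config$pulse_window_ms),
               silent = TRUE)
    if (!inherits(res, "try-error")) out$latency_ms <- as.numeric(res)
    return(out)
  }
  res <- try(suppressWarnings(xcorr_latency(
    cross_correlate(stim, erg, max_lag = config$max_lag_ms),
    search = config$search_ms)), silent = TRUE)
  if (!inherits(res, "try-error")) out$latency_ms <- as.numeric(res)
  ft <- try({
    xs <- resample_uniform(stim, config$resample_interval_ms)
    ys <- resample_uniform(erg, config$resample_interval_ms)
    est <- estimate_spectra(xs, ys, segment_len = config$segment_len,
                            window = config$spec_window,
                            overlap = config$spec_overlap)
    gm <- gain_magnitude(est)
    fit_gain(gm$freq_Hz, gm$gain_mag, gm$coherence,
             freq_range = config$fit_freq_range,
             exclude_bands = if (is.null(config$artefact_band)) NULL
               else matrix(config$artefact_band, ncol = 2),
             n_restarts = config$n_restarts, seed = config$seed)
  }, silent = TRUE)
  if (!inherits(ft, "try-error")) out$fit <- ft
  out
}

#' Analyse one session
#'
#' Runs the evaluation-segment analysis (cross-correlation or pulse
#' latency, plus spectral estimation and coherence-weighted filter fitting
#' for noise protocols) on each available condition segment.
#'
#' @param session An `erg_session`.
#' @param config An `analysis_config`; for pulse sessions the active
#'   segment is taken within the walking epoch.
#' @return data.frame with one row per condition: `animal`, `condition`,
#'   `method`, `latency_ms`, `temperature_C`, `intensity`, `seg_start`,
#'   `seg_end`, `beta`, `tau_ms`, `zeta`, `weighted_rss`, `converged`.
#' @export
analyze_session <- function(session, config = analysis_config()) {
  stopifnot(inherits(session, "erg_session"))
  if (identical(session$protocol, "pulse") &&
      config$active_segment != "within")
    config$active_segment <- "within"
  segs <- segment_conditions(session, config)
  rows <- lapply(seq_len(nrow(segs)), function(i) {
    seg <- segs[i, ]
    base <- data.frame(animal = session$animal_id,
                       condition = seg$condition,
                       method = if (identical(session$protocol, "pulse"))
                         "pulse_halfmax" else "xcorr",
                       latency_ms = NA_real_, temperature_C = NA_real_,
                       intensity = session$intensity,
                       seg_start = seg$start, seg_end = seg$end,
                       beta = NA_real_, tau_ms = NA_real_, zeta = NA_real_,
                       weighted_rss = NA_real_, converged = NA,
                       stringsAsFactors = FALSE)
    if (!seg$available) return(base)
    res <- analyze_segment(session, seg, config)
    base$latency_ms <- res$latency_ms
    base$temperature_C <- res$temperature_C
    if (!is.null(res$fit)) {
      base$beta <- res$fit$beta
      base$tau_ms <- res$fit$tau_ms
      base$zeta <- res$fit$zeta
      base$weighted_rss <- res$fit$weighted_rss
      base$converged <- res$fit$converged
    }
    base
  })
  do.call(rbind, rows)
}

#' Run the full analysis pipeline on a cohort
#'
#' Per-animal condition tables (latency, temperature and filter fits),
#' within-animal amplitude normalization, paired Wilcoxon condition
#' comparisons with Bonferroni correction, and - when the sessions span
#' several temperatures - the latency-temperature mixed model on
#' temperature-stratified sliding-latency points. Failures in individual
#' sessions are logged and the pipeline continues.
#'
#' @param sessions List of `erg_session` (>= 1).
#' @param config An `analysis_config`.
#' @param mixed_model Fit the latency-temperature mixed model from
#'   sliding-latency measurements (default FALSE; needs >= 2 animals).
#' @param temps_per_animal Temperature points per animal for the mixed
#'   model (default 5).
#' @return A list of class `"erg_run"`: `measurements` (per condition),
#'   `comparisons` (Wilcoxon tables for latency and tau), `regression`
#'   (or NULL), `config`, `log`.
#' @export
run_pipeline <- function(sessions, config = analysis_config(),
                         mixed_model = FALSE, temps_per_animal = 5) {
  if (inherits(sessions, "erg_session")) sessions <- list(sessions)
  stopifnot(length(sessions) >= 1)
  log <- character()
  tabs <- list()
  for (s in sessions) {
    r <- try(analyze_session(s, config), silent = TRUE)
    if (inherits(r, "try-error")) {
      log <- c(log, sprintf("session %s: FAILED (%s)", s$animal_id,
                            conditionMessage(attr(r, "condition"))))
    } else {
      tabs[[length(tabs) + 1L]] <- r
      log <- c(log, sprintf("session %s: analysed %d segments",
                            s$animal_id, sum(!is.na(r$latency_ms))))
    }
  }
  if (!length(tabs))
    stop("run_pipeline: every session failed", call. = FALSE)
  meas <- do.call(rbind, tabs)

  fits_ok <- meas[!is.na(meas$beta), c("animal", "condition", "beta")]
  if (nrow(fits_ok) && all(table(fits_ok$animal) >= 2)) {
    nb <- normalize_beta(fits_ok)
    meas$beta_norm <- nb$beta_norm[match(
      paste(meas$animal, meas$condition),
      paste(nb$animal, nb$condition))]
  } else meas$beta_norm <- NA_real_

  comparisons <- list()
  for (var in c("latency_ms", "tau_ms")) {
    v <- meas[!is.na(meas[[var]]), c("animal", "condition", var)]
    names(v)[3] <- "value"
    complete <- length(unique(v$condition)) == 3 &&
      all(table(v$animal) == 3) && length(unique(v$animal)) >= 3
    if (complete)
      comparisons[[var]] <- paired_wilcoxon_bonferroni(v,
                                                       alpha = config$alpha)
  }

  regression <- NULL
  if (mixed_model && length(sessions) >= 2) {
    pts <- lapply(sessions, function(s) {
      sl <- sliding_latency(s, window = config$window_s,
                            max_lag = config$max_lag_ms,
                            search = config$search_ms)
      sl <- sl[!is.na(sl$latency_ms), ]
      if (!nrow(sl)) return(NULL)
      qs <- seq(min(sl$temperature_C), max(sl$temperature_C),
                length.out = temps_per_animal)
      picked <- unique(vapply(qs, function(q)
        which.min(abs(sl$temperature_C - q)), integer(1)))
      sl[picked, c("animal", "temperature_C", "latency_ms")]
    })
    pts <- do.call(rbind, pts)
    regression <- try(fit_latency_temperature_model(pts, boot_ci = FALSE),
                      silent = TRUE)
    if (inherits(regression, "try-error")) {
      log <- c(log, "mixed model: FAILED")
      regression <- NULL
    }
  }
  structure(list(measurements = meas, comparisons = comparisons,
                 regression = regression, config = config, log = log),
            class = "erg_run")
}

#' Write the tables of a pipeline run
#'
#' Delimited measurement/comparison tables plus a small markdown report.
#'
#' @param run An `erg_run`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(run, dir) {
  stopifnot(inherits(run, "erg_run"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  data.table::fwrite(run$measurements,
                     file.path(dir, "measurements.tsv"), sep = "\t")
  for (nm in names(run$comparisons))
    data.table::fwrite(run$comparisons[[nm]],
                       file.path(dir, paste0("wilcoxon_", nm, ".tsv")),
                       sep = "\t")
  md <- c("# ERG pipeline report", "",
          sprintf("Sessions analysed: %d",
                  length(unique(run$measurements$animal))), "",
          "## Condition medians", "")
  for (var in c("latency_ms", "tau_ms", "zeta", "beta_norm")) {
    ok <- !is.na(run$measurements[[var]])
    if (!any(ok)) next
    med <- tapply(run$measurements[[var]][ok],
                  run$measurements$condition[ok], stats::median)
    md <- c(md, sprintf("- %s: %s", var,
                        paste(sprintf("%s = %.3g", names(med), med),
                              collapse = ", ")))
  }
  if (!is.null(run$regression))
    md <- c(md, "", "## Latency-temperature model", "",
            sprintf("Selected model: %s; latency = %.2f %+.3f * T ms",
                    run$regression$selected, run$regression$intercept_ms,
                    run$regression$slope_ms_per_C))
  md <- c(md, "", "## Log", "", paste0("- ", run$log))
  writeLines(md, file.path(dir, "report.md"))
  invisible(dir)
}
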