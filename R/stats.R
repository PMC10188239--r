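#' Paired Wilcoxon signed-rank tests with Bonferroni correction
#'
#' Pairwise condition comparisons within animals. Exact signed-rank
#' p-values are used for small samples without ties (the default behaviour
#' of [stats::wilcox.test()] up to n = 49), the normal approximation
#' otherwise. The significance threshold is `alpha / m` for `m` contrasts
#' (0.05 / 3 = 0.0167 for the default three-condition design).
#'
#' @param values data.frame with columns `animal`, `condition`, `value`
#'   (one value per animal and condition).
#' @param contrasts List of 2-vectors of condition labels; default the three
#'   pairwise contrasts of before/active/after.
#' @param alpha Family-wise significance level (default 0.05).
#'
#' @return data.frame with one row per contrast: `contrast`, `n`,
#'   `statistic` (signed-rank V), `p_value`, `alpha_corrected`,
#'   `significant`.
#' @export
paired_wilcoxon_bonferroni <- function(values,
                                       contrasts = list(
                                         c("before", "active"),
                                         c("after", "active"),
                                         c("before", "after")),
                                       alpha = 0.05) {
  stopifnot(is.data.frame(values),
            all(c("animal", "condition", "value") %in% names(values)))
  m <- length(contrasts)
  alpha_c <- alpha / m
  rows <- lapply(contrasts, function(ct) {
    a <- values[values$condition == ct[1], c("animal", "value")]
    b <- values[values$condition == ct[2], c("animal", "value")]
    mg <- merge(a, b, by = "animal")
    if (nrow(mg) < nrow(a) || nrow(mg) < nrow(b) || nrow(mg) == 0)
      stop("paired_wilcoxon_bonferroni: conditions '", ct[1], "' and '",
           ct[2], "' are not fully paired across animals", call. = FALSE)
    if (all(mg$value.x == mg$value.y)) {
      # all differences zero: no evidence against the null
      wt <- list(statistic = c(V = 0), p.value = 1)
    } else {
      wt <- suppressWarnings(stats::wilcox.test(mg$value.x, mg$value.y,
                                                paired = TRUE))
    }
    data.frame(contrast = paste(ct, collapse = " vs "), n = nrow(mg),
               statistic = unname(wt$statistic), p_value = wt$p.value,
               alpha_corrected = alpha_c,
               significant = wt$p.value < alpha_c,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Mixed-effects model of the latency-temperature relationship
#'
#' Fits linear mixed-effects models of latency on eye temperature with
#' per-animal random intercepts and temperature slopes, compares candidate
#' fixed-effect structures (null, + temperature, + treatment,
#' + interaction) by likelihood-ratio tests and AIC (models fitted by ML
#' for the comparison), and refits the selected model by REML for the
#' reported coefficients. Confidence intervals for the fixed effects come
#' from a parametric bootstrap (falling back to Wald intervals if the
#' bootstrap fails).
#'
#' @param measurements data.frame with columns `animal`, `latency_ms`,
#'   `temperature_C` and optionally `treatment` (>= 2 animals, >= 2
#'   temperatures per animal).
#' @param boot_ci Logical: bootstrap the fixed-effect CIs (default TRUE).
#' @param n_boot Bootstrap replicates (default 200).
#' @param seed Seed for the bootstrap.
#' @param force Optional candidate name (`"null"`, `"temperature"`,
#'   `"treatment"`, `"interaction"`) to report instead of the AIC-selected
#'   structure (the comparison table is still computed).
#'
#' @return A list of class `"latency_temperature_fit"`: `intercept_ms`,
#'   `slope_ms_per_C`, `treatment_offset_ms` (NA if treatment is not in the
#'   selected model), `ci` (matrix of 95% intervals), `selected`,
#'   `model_table` (AIC / logLik / LRT p per candidate), `fit` (the REML
#'   `merMod`), `singular` flag.
#' @export
fit_latency_temperature_model <- function(measurements, boot_ci = TRUE,
                                          n_boot = 200, seed = 1L,
                                          force = NULL) {
  stopifnot(is.data.frame(measurements),
            all(c("animal", "latency_ms", "temperature_C") %in%
                  names(measurements)))
  d <- measurements
  d$animal <- factor(d$animal)
  if (nlevels(d$animal) < 2)
    stop("fit_latency_temperature_model: need >= 2 animals", call. = FALSE)
  if (min(tapply(d$temperature_C, d$animal,
                 function(x) length(unique(x)))) < 2)
    stop("fit_latency_temperature_model: need >= 2 temperatures per animal",
         call. = FALSE)
  has_tr <- "treatment" %in% names(d) &&
    length(unique(d$treatment)) > 1
  if (has_tr) {
    lv <- unique(d$treatment)
    # walking as the reference level: the reported offset is the extra
    # latency of the heated group
    if (all(c("walking", "heated") %in% lv))
      lv <- c("walking", setdiff(lv, "walking"))
    d$treatment <- factor(d$treatment, levels = lv)
  }

  re <- "(1 + temperature_C || animal)"
  forms <- list(null = paste("latency_ms ~ 1 +", re),
                temperature = paste("latency_ms ~ temperature_C +", re))
  if (has_tr) {
    forms$treatment <- paste("latency_ms ~ temperature_C + treatment +", re)
    forms$interaction <-
      paste("latency_ms ~ temperature_C * treatment +", re)
  }

  fit_ml <- function(f)
    suppressWarnings(suppressMessages(
      lme4::lmer(stats::as.formula(f), data = d, REML = FALSE)))
  fits <- lapply(forms, function(f) try(fit_ml(f), silent = TRUE))
  ok <- !vapply(fits, inherits, logical(1), "try-error")
  fits <- fits[ok]
  if (!length(fits))
    stop("fit_latency_temperature_model: no candidate model fitted",
         call. = FALSE)
  aics <- vapply(fits, stats::AIC, numeric(1))
  lls <- vapply(fits, function(m) as.numeric(stats::logLik(m)), numeric(1))
  lrt_p <- rep(NA_real_, length(fits))
  for (i in seq_along(fits)[-1]) {
    an <- suppressMessages(stats::anova(fits[[i - 1]], fits[[i]]))
    lrt_p[i] <- an$`Pr(>Chisq)`[2]
  }
  model_table <- data.frame(model = names(fits), AIC = aics, logLik = lls,
                            lrt_p_vs_previous = lrt_p,
                            stringsAsFactors = FALSE)
  # forward selection along the nested chain: accept a richer model only if
  # the likelihood-ratio test supports it and the AIC improves
  sel_i <- 1L
  for (i in seq_along(fits)[-1]) {
    if (!is.na(lrt_p[i]) && lrt_p[i] < 0.05 && aics[i] < aics[sel_i])
      sel_i <- i
    else break
  }
  selected <- names(fits)[sel_i]
  if (!is.null(force)) {
    if (!force %in% names(forms))
      stop("fit_latency_temperature_model: unknown model '", force, "'",
           call. = FALSE)
    selected <- force
  }

  # reported coefficients: REML refit of the selected structure
  refit <- function(f)
    suppressWarnings(suppressMessages(
      lmerTest::lmer(stats::as.formula(f), data = d, REML = TRUE)))
  fit <- try(refit(forms[[selected]]), silent = TRUE)
  singular <- FALSE
  if (inherits(fit, "try-error") || lme4::isSingular(fit)) {
    singular <- TRUE
    warning("fit_latency_temperature_model: singular random-effect fit; ",
            "falling back to random intercepts only")
    f2 <- gsub("1 \\+ temperature_C \\|\\| ", "1 | ", forms[[selected]])
    fit <- refit(f2)
  }
  fe <- lme4::fixef(fit)
  tr_coef <- grep("^treatment", names(fe), value = TRUE)

  ci <- NULL
  if (boot_ci) {
    ci <- try(with_seed(seed, suppressWarnings(suppressMessages(
      stats::confint(fit, parm = "beta_", method = "boot",
                     nsim = n_boot, quiet = TRUE)))), silent = TRUE)
    if (inherits(ci, "try-error")) ci <- NULL
  }
  if (is.null(ci))
    ci <- suppressWarnings(stats::confint(fit, parm = "beta_",
                                          method = "Wald"))

  structure(list(
    intercept_ms = unname(fe["(Intercept)"]),
    slope_ms_per_C = if ("temperature_C" %in% names(fe))
      unname(fe["temperature_C"]) else NA_real_,
    treatment_offset_ms = if (length(tr_coef))
      unname(fe[tr_coef[1]]) else NA_real_,
    ci = ci, selected = selected, model_table = model_table,
    fit = fit, singular = singular),
    class = "latency_temperature_fit")
}

#' @export
print.latency_temperature_fit <- function(x, ...) {
  cat(sprintf(paste0("<latency_temperature_fit> model '%s': latency = ",
                     "%.2f %+.3f * T (ms, T in degC)"),
              x$selected, x$intercept_ms,
              ifelse(is.na(x$slope_ms_per_C), 0, x$slope_ms_per_C)))
  if (!is.na(x$treatment_offset_ms))
    cat(sprintf(", treatment offset %+.3f ms", x$treatment_offset_ms))
  cat("\n")
  invisible(x)
}

#' Latency summary across light intensities
#'
#' Per-intensity median latencies, a monotonicity check and the
#' highest-versus-lowest intensity latency difference; optionally also
#' reports the walking-versus-sitting latency effect from supplied
#' condition medians for comparison.
#'
#' @param measurements data.frame with columns `intensity`, `latency_ms`
#'   (optionally `animal`).
#' @param walking_reference Optional numeric `c(sitting, walking)` median
#'   latencies in ms; their difference is reported as `walking_effect_ms`.
#'
#' @return A list: `per_intensity` (data.frame intensity/median/n),
#'   `monotone_decreasing`, `range_difference_ms` (lowest minus highest
#'   intensity median), `walking_effect_ms` (or NA).
#' @export
#' @examples
#' d <- data.frame(intensity = rep(c(1e14, 1e15), each = 3),
#'                 latency_ms = c(9, 9.1, 8.9, 8.0, 8.1, 7.9))
#' intensity_latency_summary(d, walking_reference = c(9.0, 7.4))
intensity_latency_summary <- function(measurements,
                                      walking_reference = NULL) {
  stopifnot(is.data.frame(measurements),
            all(c("intensity", "latency_ms") %in% names(measurements)))
  ints <- sort(unique(measurements$intensity))
  if (length(ints) < 2)
    stop("intensity_latency_summary: need >= 2 intensities", call. = FALSE)
  med <- vapply(ints, function(i)
    stats::median(measurements$latency_ms[measurements$intensity == i]),
    numeric(1))
  n <- vapply(ints, function(i)
    sum(measurements$intensity == i), integer(1))
  per <- data.frame(intensity = ints, median_latency_ms = med, n = n)
  list(per_intensity = per,
       monotone_decreasing = all(diff(med) <= 0),
       range_difference_ms = med[1] - med[length(med)],
       walking_effect_ms = if (is.null(walking_reference)) NA_real_
         else walking_reference[1] - walking_reference[2])
}
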