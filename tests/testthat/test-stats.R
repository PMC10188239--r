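test_that("Bonferroni threshold and degenerate cases behave", {
  d <- data.frame(animal = rep(sprintf("a%02d", 1:8), 3),
                  condition = rep(c("before", "active", "after"), each = 8),
                  value = rep(1:8, 3))
  res <- paired_wilcoxon_bonferroni(d, alpha = 0.05)
  expect_equal(nrow(res), 3)
  expect_equal(round(res$alpha_corrected[1], 4), 0.0167)
  # identical paired values: p = 1, never significant
  expect_true(all(res$p_value == 1))
  expect_false(any(res$significant))

  d_miss <- d[-1, ]
  expect_error(paired_wilcoxon_bonferroni(d_miss), "paired")
})

test_that("exact signed-rank p-values match brute-force enumeration", {
  set.seed(19)
  for (rep in 1:4) {
    n <- 12
    before <- rnorm(n, 10, 1)
    active <- before - rnorm(n, 0.6, 0.7)   # mostly decreased
    oracle <- brute_force_signed_rank(before, active)
    wt <- stats::wilcox.test(before, active, paired = TRUE)
    expect_equal(unname(wt$statistic), oracle$V)
    expect_equal(wt$p.value, oracle$p, tolerance = 1e-12)
  }
  # all 12 pairs decreased: the one-table case, p = 2 / 2^12
  before <- 1:12 + 10
  active <- before - runif(12, 0.1, 1)
  d <- data.frame(animal = rep(sprintf("a%02d", 1:12), 2),
                  condition = rep(c("before", "active"), each = 12),
                  value = c(before, active))
  res <- paired_wilcoxon_bonferroni(d, contrasts = list(c("before",
                                                          "active")))
  expect_equal(res$p_value, 2 / 2^12, tolerance = 1e-12)
  expect_equal(res$p_value, brute_force_signed_rank(before, active)$p)
  expect_true(res$significant)
})

test_that("noise-free linear data is recovered exactly by the mixed model", {
  d <- simulate_latency_cohort(n_walking = 4, n_heated = 4,
                               re_intercept_sd = 0, re_slope_sd = 0,
                               resid_sd = 0, seed = 1)
  fit <- suppressWarnings(
    fit_latency_temperature_model(d, boot_ci = FALSE))
  expect_equal(fit$intercept_ms, 22.21, tolerance = 1e-6)
  expect_equal(fit$slope_ms_per_C, -0.48, tolerance = 1e-6)
})

test_that("the latency-temperature slope and intercept are recovered", {
  d <- simulate_latency_cohort(seed = 23)
  expect_equal(nrow(d), (12 + 22) * 5)
  fit <- fit_latency_temperature_model(d, boot_ci = TRUE, n_boot = 100,
                                       seed = 2)
  expect_equal(fit$slope_ms_per_C, -0.48, tolerance = 0.05)
  expect_equal(fit$intercept_ms, 22.21, tolerance = 0.05)
  ci <- fit$ci
  expect_lt(ci["temperature_C", 1], -0.48)
  expect_gt(ci["temperature_C", 2], -0.48)
  expect_lt(ci["(Intercept)", 1], 22.21)
  expect_gt(ci["(Intercept)", 2], 22.21)
})

test_that("an injected treatment offset is detected within 2 s.e.", {
  d <- simulate_latency_cohort(re_intercept_sd = 0.1, resid_sd = 0.15,
                               treatment_offset = 0.177, seed = 31)
  fit <- suppressWarnings(
    fit_latency_temperature_model(d, boot_ci = FALSE, force = "treatment"))
  cf <- stats::coef(summary(fit$fit))
  trow <- grep("^treatment", rownames(cf))
  expect_lt(abs(cf[trow, "Estimate"] - 0.177), 2 * cf[trow, "Std. Error"])
})

test_that("model selection mostly identifies the generating structure", {
  hits <- 0
  for (s in 1:10) {
    d <- simulate_latency_cohort(treatment_offset = 0, seed = 400 + s,
                                 center = FALSE)
    fit <- fit_latency_temperature_model(d, boot_ci = FALSE)
    hits <- hits + (fit$selected == "temperature")
  }
  expect_gte(hits, 8)
})

test_that("intensity summaries report medians, monotonicity and effects", {
  # the printed condition medians as direct input: walking effect 1.6 ms
  d <- data.frame(intensity = rep(c(1.74e14, 7.27e14, 1.31e15, 2.41e15),
                                  each = 4),
                  latency_ms = c(9.0, 9.1, 8.9, 9.0,
                                 8.6, 8.5, 8.7, 8.6,
                                 8.1, 8.2, 8.0, 8.1,
                                 7.6, 7.7, 7.5, 7.6))
  s <- intensity_latency_summary(d, walking_reference = c(9.0, 7.4))
  expect_equal(s$walking_effect_ms, 1.6)
  expect_true(s$monotone_decreasing)
  expect_equal(s$range_difference_ms, 9.0 - 7.6, tolerance = 1e-9)

  # duplicated series: zero difference
  d2 <- data.frame(intensity = rep(c(1e14, 1e14 * 1.0001), each = 3),
                   latency_ms = rep(c(9, 9.2, 8.8), 2))
  s2 <- intensity_latency_summary(d2)
  expect_equal(s2$range_difference_ms, 0)
  expect_error(intensity_latency_summary(d[d$intensity == 1.74e14, ]),
               ">= 2 intensities")
})
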