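# ergid — system identification and latency analysis for insect ERGs

`ergid` is an R package for quantifying how fast an insect eye responds to
light, from electroretinogram (ERG) recordings made during stimulation
with band-limited Gaussian white noise or with light pulses. It is aimed
at sensory physiologists who record multi-channel sessions — photodiode
stimulus trace, ERG voltage, eye temperature, locomotion — and want a
reproducible pipeline from raw channels to condition-level statistics.

The pipeline implements:

* **Stimulus synthesis** — Gaussian white-noise tokens shaped by a 9-pole
  Butterworth low-pass (250 Hz corner, flat spectrum to ≈220 Hz),
  rectangular pulse trains (50 ms at 1 Hz), intensity scaling to photon
  flux, and the aperture geometry (a 4 mm light guide at 9 cm subtends
  2.5°).
* **Latency estimation** — the half-maximum crossing time of pulse
  responses, and the lag of the *minimum* of the stimulus–ERG
  cross-correlation under noise stimulation (the ERG is sign-inverted
  relative to the light), with sub-sample refinement and a sliding-window
  monitor paired with eye temperature.
* **Spectral estimation** — Welch-averaged auto- and cross-spectra on
  1 ms-resampled data (512-point segments), giving the frequency response
  G(f) = ⟨Sxy⟩/⟨Sxx⟩ and the linear coherence
  γ²(f) = |⟨Sxy⟩|² / (⟨Sxx⟩⟨Syy⟩) ∈ [0, 1].
* **Filter fitting** — coherence-weighted least squares of the gain
  magnitude with a resonant second-order low-pass
  H(f) = β / (1 + j·2ωτζ − (ωτ)²), yielding amplitude β, time constant τ
  (ms) and damping ζ per animal and condition.
* **Statistics** — paired Wilcoxon signed-rank condition contrasts with
  Bonferroni correction (α/3 = 0.0167), and an `lme4` mixed-effects model
  of latency on eye temperature with per-animal random intercepts and
  slopes, likelihood-ratio/AIC model selection and bootstrap CIs.
* **Synthetic sessions** — a first-class generator that produces complete
  recordings (stimulus, ERG, temperature, motion, epochs) from the fitted
  second-order model with temperature-coupled delay and time constant, so
  the entire pipeline is validated by parameter recovery against known
  ground truth.

See `vignettes/erg-system-identification.Rmd` for the model, the
estimator choices and the generator's assumptions.

## Worked example

Simulate one walking session (60 s sitting, 60 s walking, 310 s
recovery; eye temperature rises 2.3 °C during walking) and analyse its
three 5 s evaluation segments:

```r
library(ergid)
s   <- simulate_session("walking", seed = 42)
res <- analyze_session(s)
res[, c("condition", "latency_ms", "temperature_C", "beta", "tau_ms", "zeta")]
#>   condition latency_ms temperature_C  beta tau_ms   zeta
#> 1    before      8.967         27.60 1.002  1.408 0.1525
#> 2    active      7.878         29.85 1.002  1.251 0.1514
#> 3     after      8.864         27.78 1.000  1.397 0.1499
```

Latency drops by ~1.1 ms and the filter time constant shortens from
1.41 ms to 1.25 ms while the eye is warm — the session was generated with
exactly those condition parameters, and the pipeline recovers them from
the noisy channels. At cohort level:

```r
sessions <- simulate_cohort(cohort_spec(12, "walking", seed = 11))
run      <- run_pipeline(sessions)
round(tapply(run$measurements$tau_ms, run$measurements$condition, median), 3)
#> active  after before
#>  1.250  1.399  1.408
run$comparisons$latency_ms
#>           contrast  n statistic  p_value alpha_corrected significant
#> 1 before vs active 12        78 0.000488          0.0167        TRUE
#> 2  after vs active 12        78 0.000488          0.0167        TRUE
#> 3  before vs after 12        78 0.000488          0.0167        TRUE
```

`p = 0.000488` is the exact one-table signed-rank value for 12 animals
that all sped up while warm. The latency–temperature relation is
recovered from measurement-level cohorts with
`fit_latency_temperature_model()`:

```r
d   <- simulate_latency_cohort(seed = 9)   # 12 walking + 22 heated animals
fit <- fit_latency_temperature_model(d)
fit
#> <latency_temperature_fit> model 'temperature': latency = 22.45 -0.487 * T (ms, T in degC)
```

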