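---
title: "Methods: ERG system identification and latency analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ERG system identification and latency analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ergid)
```

## The measurement problem

The electroretinogram (ERG) is an extracellular field potential recorded
from the compound eye, dominated by the summed response of the
photoreceptors. When an insect is stimulated with light whose intensity
fluctuates as band-limited Gaussian white noise, the ERG can be treated as
the (noisy, sign-inverted, delayed) output of an approximately linear
system driven by the photodiode-measured stimulus. Two quantities
summarize the speed of that system:

* **latency** — the time offset between stimulus and response, measured
  either as the time at which a pulse response crosses half of its maximum
  amplitude, or as the lag of the minimum of the stimulus–ERG
  cross-correlation (the minimum, not the maximum, because the ERG is
  inversely correlated with the light trace);
* **the frequency-response roll-off** — captured by fitting the gain
  magnitude $|G(f)|$ with a resonant second-order low-pass filter
  $$H(f) = \frac{\beta}{1 + j\,2\omega\tau\zeta - (\omega\tau)^2},
  \qquad \omega = 2\pi f,$$
  with amplitude $\beta$ (DC gain), time constant $\tau$ (ms) and damping
  $\zeta$ (dimensionless; $\zeta < 1/\sqrt2$ gives a resonance peak near
  $f = \sqrt{1-2\zeta^2}/(2\pi\tau)$).

Both measures shrink when the eye warms — during locomotion or under an
infrared lamp — and the package's statistics layer quantifies that
temperature dependence with paired nonparametric condition contrasts and a
linear mixed-effects model of latency on eye temperature.

## Spectral estimation

Gain and linear coherence are estimated by Welch averaging: both channels
are resampled to 1 ms intervals (zero-phase FIR anti-aliasing, so
resampling cannot shift latencies), cut into 512-point segments, tapered,
Fourier transformed, and averaged:

$$G(f) = \frac{\langle S_{xy}(f)\rangle}{\langle S_{xx}(f)\rangle},
\qquad
\gamma^2(f) = \frac{|\langle S_{xy}(f)\rangle|^2}
                   {\langle S_{xx}(f)\rangle\,\langle S_{yy}(f)\rangle}.$$

The coherence numerator is the squared magnitude of the *averaged*
cross-spectrum (magnitude-squared coherence). Squaring per segment before
averaging would make $\gamma^2 \equiv 1$ regardless of the data, so the
ensemble average must be taken first; this is the standard estimator and
the package implements it that way deliberately. By Cauchy–Schwarz the
estimate lies in $[0,1]$ by construction, and for an additive-noise channel
it approaches $\mathrm{SNR}/(1+\mathrm{SNR})$ per frequency — a property
the test-suite verifies by simulation.

Defaults: Hann taper with 50% overlap (variance reduction at the stated
~1.95 Hz resolution without biasing the gain); a rectangular/no-overlap
mode is available for the plainest disjoint-segment reading. The ensemble
is formed within each 5 s evaluation segment; averaging across a whole
condition epoch is possible by passing longer windows.

## Coherence-weighted filter fitting

`fit_gain()` minimizes
$\sum_f \gamma^2(f)\,\bigl(|H(f;\beta,\tau,\zeta)| - |G(f)|\bigr)^2$
over the default band 2–220 Hz: the DC bin is excluded, the upper limit
honours the flatness limit of the noise stimulus (the nine-pole 250 Hz
Butterworth leaves the stimulus spectrum flat to roughly 220 Hz), and a
146–154 Hz band is excluded because mains-related artefacts at 150 Hz
contaminate that bin in real recordings (the synthetic generator injects
the same artefact). Weighting by $\gamma^2$ applies to squared magnitude
residuals — the most direct reading of "weighted by the coherence" — with
a log-domain option.

Numerics: parameters are optimized as logarithms (positivity without
clipping) by Levenberg–Marquardt. Strongly resonant gain curves
($\zeta \approx 0.15$) create local minima, so the fit starts from a
peak-frequency heuristic ($\tau_0 = 1/(2\pi f_{\mathrm{peak}})$,
$\zeta_0 = 0.2$, $\beta_0 = |G|$ at the lowest bin) plus five jittered
restarts under a fixed seed, and returns the restart with the lowest
weighted residual. On gain curves generated from the model itself all
three parameters are recovered to better than 0.1% across
$\beta \in [0.1, 10]$, $\tau \in [0.5, 5]$ ms, $\zeta \in [0.05, 1]$.

Amplitudes are compared across conditions after within-animal
normalization (`normalize_beta()`: each animal's $\beta$ divided by that
animal's maximum), since absolute ERG amplitude depends on electrode
placement.

## Latency estimators

`pulse_latency_half_max()` measures, per pulse, the first crossing of 50%
of that response's maximum absolute deflection from the pre-onset
baseline, linearly interpolated between samples, and averages the pulses
of the segment (five pulses in 5 s at the 1 Hz default). The per-pulse
(not session-global) maximum makes the measure robust to slow amplitude
drift and invariant to amplitude scaling.

`xcorr_latency()` reads the lag of the global minimum of the normalized
cross-correlation on positive lags (0–30 ms by default), with parabolic
sub-sample refinement. Sub-sample interpolation matters because the native
3 kHz sampling grid (0.33 ms) is coarse relative to the ~0.1 ms latency
differences of interest. A maximum-based reading is available for
non-inverted channels. `sliding_latency()` applies the estimator in
sliding windows (5 s window, 1 s step by default) and pairs every estimate
with the window-mean eye temperature.

## Segment policy

For noise protocols the three evaluation segments are: 5 s immediately
before the active epoch, 5 s immediately *after* it (movement artefacts
preclude evaluating during walking itself; recovery is slow enough that
this is a good proxy for the active state), and 5 s starting at least
300 s after activity ends. For pulse protocols the active-condition
segment lies within the last 5 s of the walking epoch. Epoch boundaries
come from labels or are derived from the motion channel (forward speed
above threshold for at least 2 s).

## The synthetic-session generator

The analysis stages need ground truth to be validated against, so the
package generates complete sessions (stimulus, ERG, temperature, motion,
epoch labels). The fitted second-order low-pass is promoted to the forward
model: the ERG is the stimulus passed through $H(f)$, delayed, sign
inverted, plus white recording noise and a 150 Hz artefact. This makes
parameter recovery well-posed: the pipeline is correct if it returns the
generating $(\beta, \tau, \zeta)$ and latencies.

Key generator choices:

* **Frequency-domain synthesis.** $H(f)$ and the (fractional) pure delay
  are applied exactly in the frequency domain on 5 s blocks aligned with
  the evaluation segments. A time-domain discretization (bilinear
  transform) would warp the magnitude response by ~1.8% at 220 Hz at
  3 kHz — most of the 2% transfer-match budget — whereas the
  frequency-domain route is exact, and its circular boundary assumption
  matches the looped 10 s noise token.
* **Latency decomposition.** Total measured latency = pure transduction
  delay + the filter's own contribution. The filter contribution is
  computed per block from the block's own stimulus spectrum (lag of the
  extremum of $\mathrm{IFFT}(|X|^2 H)$, the noiseless cross-correlation),
  and the pure delay absorbs the temperature dependence, so the
  cross-correlation latency of a noiseless block equals
  `latency_from_temperature()` exactly. Pulse sessions are calibrated the
  same way through the half-maximum offset of the noiseless pulse
  response.
* **Temperature coupling.** Latency follows the linear relation
  `22.21 ms − 0.48 ms/°C · T` (per-animal random intercepts and slopes on
  top); $\tau$ interpolates linearly between two reported
  condition-median anchors (heating: 1.48 ms at 26.9 °C and 1.14 ms at
  31.9 °C; walking: 1.41 ms at 27.6 °C and 1.25 ms at 29.9 °C); $\beta$
  and $\zeta$ are temperature-independent by default (condition-specific
  shifts are available as options, not defaults).
* **Temperature trajectories.** Sitting baseline; a ramp over the first
  third of the active epoch to a plateau (walking: +2.3 °C by default;
  heating: ~37 °C, the lamp-on peak); exponential decay afterwards. The
  decay constant is 120 s for walking (metabolic cool-down) and 3 s for
  heating: an infrared lamp heats the eye surface with little thermal
  mass, and the fast lamp-off relaxation places the post-active 5 s
  evaluation window at ≈31.9 °C — exactly the reported heated-condition
  temperature — reconciling the ~37 °C peak with the ~32 °C heated
  condition without extra mechanism.
* **Median-pinned cohorts.** `simulate_cohort()` draws per-animal
  condition temperatures, latency offsets and amplitude/damping scatter,
  then removes the cohort median of each draw, so the cohort's
  *generating* condition medians equal the specified values exactly.
  Parameter-recovery checks compare recovered medians against generating
  medians; without pinning, cohort sampling error alone (~4% on a
  12-animal median) would be conflated with estimator error. Between-animal
  $\tau$ variability is mediated by the condition-temperature spread
  (±1.2–2.0 °C), which keeps the generating $\tau$ median exactly on the
  temperature model because the median commutes with the monotone
  temperature–$\tau$ map; extra multiplicative $\tau$ scatter is available
  via `tau_scale_sd` but breaks exact pinning.
* **Noise levels.** Recording noise defaults to 30% of the clean-ERG sd
  under noise stimulation, which yields coherence ≈0.9 at low frequencies
  falling towards ~0.7 near 220 Hz — the shape seen in real recordings —
  and 15% for pulse stimulation, whose stimulus is roughly tenfold
  brighter. The 150 Hz artefact defaults to 15% of the clean sd with a
  random phase per session.

What the generator does **not** emulate: phototransduction nonlinearity
and light adaptation dynamics (the intensity series imposes a
log-intensity latency rule rather than modelling adaptation), movement
artefacts in the ERG during walking (the real reason the active segment is
taken post-hoc), slow electrode drift, and any deviation of the true ERG
from the second-order model. Passing recovery tests therefore demonstrates
that the estimation pipeline is consistent and unbiased for a system of
the assumed class at realistic noise levels — not that the biological ERG
is exactly second order.

## Statistics

Condition contrasts use exact paired Wilcoxon signed-rank tests (normal
approximation only beyond n = 49 or with ties) at a Bonferroni-corrected
threshold $\alpha/3 = 0.0167$. The test-suite cross-checks the exact
p-values against full $2^n$ sign-flip enumeration.

The latency–temperature relationship is modelled with `lme4`:
`latency ~ temperature + treatment + (1 + temperature || animal)` and its
nested simplifications, fitted by maximum likelihood for model comparison
and REML for reported coefficients. Selection walks the nested chain
(null → temperature → treatment → interaction) and accepts a richer model
only when the likelihood-ratio test supports it *and* the AIC improves;
gating on the LRT keeps the spurious-term acceptance rate near the test
level, where bare minimum-AIC selection would add a superfluous term in
roughly a quarter of null simulations. Random effects are uncorrelated
intercepts and slopes, matching the generator; singular fits fall back to
random intercepts with a warning. Fixed-effect CIs come from a parametric
bootstrap (200 replicates by default), with Wald intervals as fallback.
Small-sample post-hoc degrees of freedom use the Satterthwaite
approximation via `lmerTest` (Kenward–Roger is available through
`pbkrtest`; at these cohort sizes the two are practically
indistinguishable).

The measurement-level cohort generator (`simulate_latency_cohort()`)
defaults to 12 walking + 22 heated animals with five eye-temperature
points per animal (170 measurements), per-animal random intercept sd
0.4 ms and slope sd 0.02 ms/°C, residual sd 0.25 ms, and no treatment
offset; an offset (e.g. +0.177 ms for heated animals) can be injected to
probe detectability. The five temperatures are evenly spaced over each
animal's observed range — the simplest defensible rule, since no selection
rule for such points is prescribed.

## Problem sizes and runtime

Validation uses the reference group sizes throughout: 12 walking, 22 heated
and 16 pulse animals, with 60 s sitting / 60 s active / 310 s recovery
sessions at 3 kHz for the noise protocols (10/10/310 s for pulse
sessions, whose evaluation needs only five pulses per condition). These
sizes keep the complete recovery experiment at around a minute of compute
while leaving the cohort medians' estimation error an order of magnitude
inside the acceptance tolerances.

## Known limitations

* The self-consistent forward model means recovery tests cannot detect
  model misspecification of the real ERG.
* The text session container is verbose (one sample per line); it trades
  size for transparency and lossless round-trips.
* The walking-condition evaluation uses the post-walking window by
  design; if recovery were much faster than the ~2 s it takes to settle a
  window, active-state speed would be underestimated.
* The latency–temperature relation is linear only locally; the model
  warns outside 24–38 °C.
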