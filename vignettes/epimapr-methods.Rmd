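---
title: "Methods: epicardial activation mapping and perfusion trend analytics"
author: "epimapr authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: epicardial activation mapping and perfusion trend analytics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epimapr)
```

# Scope and data model

`epimapr` analyses two data streams from ex vivo normothermic working-heart
perfusion experiments: multichannel unipolar epicardial electrograms (UEG)
recorded on rectangular electrode grids during pacing, and the hourly
biomarker / continuous hemodynamic series that track the preparation's
physiological state.

The two acquisition geometries the electrogram side is built around are an
11 × 11 grid with 5 mm inter-electrode spacing sampled at 2048 Hz and a
6 × 8 grid sampled at 500 Hz. Electrodes are labelled `(row, col)` from 1;
electrode `(r, c)` sits at `((c-1)·s, (r-1)·s)` mm, channels are stored
row-major, and all of this is defined once in `ElectrodeGrid` and reused
everywhere. Speeds are exposed in cm/s while internal arithmetic is mm/ms;
the conversion factor 100 is a named constant. The spacing of the 6 × 8
array is not authoritatively documented; we default it to 5 mm and leave it
configurable rather than guessing a value as fact.

# The synthetic wavefront generator

`simulateRecording()` produces paced UEG recordings with known ground
truth. It is deliberately *kinematic*: a wavefront specification (planar
direction + speed, or focal source + speed) determines the analytic
activation time of every electrode, and each channel's waveform is built
around that instant. There is no tissue model — no monodomain/bidomain
equations, no action-potential dynamics, no conduction block or re-entry.
That is exactly what makes it usable as an oracle: the quantity every
downstream stage estimates (the activation time, and through it the
propagation velocity) is known in closed form.

Component choices, and why:

* **QRS template.** A derivative-of-Gaussian biphasic deflection (R-then-S
  wave). Its analytic derivative is minimal exactly at the template centre,
  so the detector's target is unambiguous. Width default 40 ms
  (`qrsWidth`), i.e. Gaussian σ of 6.7 ms, typical of a ventricular
  deflection. Peak amplitude 1 signal unit by default; all noise amplitudes
  are naturally read relative to it.
* **T wave.** A broad positive Gaussian (σ = 40 ms) 180 ms after local
  activation, amplitude 0.15 by default. It exists so the search window
  contains a realistic slow wave that a naive "largest deflection" detector
  would confuse; its slopes are an order of magnitude below the QRS slope.
* **Baseline wander.** A single sinusoid, default 0.3 Hz — inside the
  high-pass stopband by construction, so the filter contract can be checked
  against it. Per-channel random phase.
* **Noise.** Additive white Gaussian (`noiseSd`). Real electrode noise is
  coloured and includes motion artifacts; white noise is the conservative
  choice for exercising the derivative operator, which amplifies high
  frequencies.
* **Pacing artifact.** A 2-sample rectangular spike on all channels at each
  stimulus, so blanking logic is actually exercised.
* **Bad channels.** Channels listed in the grid receive nuisance components
  only — emulating a malfunctioning electrode such as the documented
  `(2,6)` case.
* **Determinism.** The `seed` in `beatTrainSpec` makes recordings
  bit-identical; the generator saves and restores the caller's RNG state.

For a planar wave, `onsetDelay` is the activation time at the coordinate
origin, so directions with negative components need a larger onset to keep
all activation times after the stimulus; the simulator refuses
configurations where activation precedes the stimulus or overruns the
pacing interval, rather than silently wrapping.

What passing tests on this generator do *not* show: robustness to
real-tissue phenomena (fractionated electrograms, repolarisation overlap,
wavefront curvature and anisotropy, electrode contact loss mid-recording).
The pipeline's accuracy statements are about the kinematic model class.

# Preprocessing

The band-pass is a digital Butterworth with cutoffs 0.5 and 40 Hz. Two
decisions are ours, since only the cutoffs are externally fixed:

* **Order 4** (a 2nd-order low-pass prototype transformed to band-pass) —
  the conventional compromise for electrogram work; steeper filters ring,
  shallower ones leave wander.
* **Zero-phase application** (forward–backward, `zeroPhase = TRUE`). A
  causal pass would delay each deflection by a frequency-dependent group
  delay and bias every activation time — the one quantity the pipeline
  exists to measure. The effective magnitude response is the squared
  single-pass response; tests assert the 10 Hz passband (≥ 0.99), the 50 Hz
  attenuation (closed-form Butterworth gain) and DC rejection at both
  sampling rates.

The forward–backward pass is implemented in the package rather than taken
from `signal::filtfilt` because edge handling matters here: each pass is
initialised at the steady state of a constant input equal to the boundary
sample (so a DC offset is removed *exactly*, with no start-up transient),
and the signal is extended by odd reflection over a pad scaled to the
slowest pole's time constant (≈ 6/(1−r) samples for maximal pole radius r)
before filtering. With a 0.5 Hz high-pass at 2048 Hz the slow pole's
transient lasts seconds; a fixed short pad would leak O(signal) transients
into the first beats. The recursions themselves run through the C code
behind `stats::filter`.

Beat segmentation is stimulus-driven: one window per pacing stimulus
followed by a full `window` (default 400 ms — generous, because arrival
delays beyond 150 ms occur in deteriorating preparations), starting after a
`blanking` interval (default 10 ms) that excludes the stimulus artifact,
and capped at the next stimulus so windows are disjoint. Without pacing
metadata a convenience detector thresholds the mean-channel derivative at
5 robust SDs with a 250 ms refractory period; it is a fallback for sinus
recordings, not a validated R-peak detector.

# Activation detection

AT = argmin of the discrete time-derivative within the search window,
relative to the stimulus. Numerical choices:

* **Derivative estimator:** central difference at the native rate. The
  signal is already band-limited to 40 Hz, so further smoothing would only
  widen the minimum.
* **Tie-break:** earliest sample wins (deterministic).
* **Sub-sample refinement (default `refine = "parabolic"`):** a parabola
  through the three derivative samples around the discrete minimum. At
  500 Hz a sample is 2 ms; a wave at 150 cm/s crosses the 6 × 8 grid's
  35 mm span in ~23 ms, so sample-resolution ATs alone would leave the
  two-point velocity with a quantisation error of several percent —
  incompatible with the 1 % agreement the estimator cross-validation
  demands. The refinement brings AT errors to ~10⁻³ ms on clean signals
  while never moving the estimate by more than half a sample;
  `refine = "none"` gives the literal argmin.
* **Validity floor:** a channel is invalid for a beat when its deflection
  amplitude (half peak-to-peak within the window) is ≤ 5 × a robust
  per-channel noise estimate (whole-record MAD — deflections are sparse in
  time, so the MAD tracks the noise floor). A pure-noise channel peaks
  around 3–4 SDs and fails the floor; manual bad-channel lists are
  honoured regardless, so both detection modes (manual and automatic)
  coexist.

Isochrone construction is a deterministic binning of the valid ATs into
bands of `interval` ms (default 10 ms — a round value giving 3–6 bands for
typical 30–60 ms grid-crossing times; the choice is presentational and
configurable). The wave's arrival time is the earliest valid AT.

# Velocity estimation and restitution

Two estimators are shipped and labelled in their output:

* `estimateWpvTwoPoint()` — the literal distance-over-delay quotient
  between two electrodes in the propagation direction. When no pair is
  given, the direction comes from the plane fit and the most-aligned pair
  at maximal separation is chosen deterministically (maximal separation
  because the AT-difference error is fixed by the sampling grid, so the
  relative error shrinks with transit time).
* `fitPlaneVelocity()` — least squares on AT(x, y) = a·x + b·y + c over
  valid electrodes (via `stats::lm.fit`); speed = 1/‖(a, b)‖, direction =
  (a, b)/‖(a, b)‖, with the RMS residual reported. Robust default, since it
  pools all electrodes. Gradient norms below 10⁻⁶ ms/mm (a speed of
  10⁸ cm/s, far beyond physiology) are reported as degenerate simultaneous
  activation; collinear electrode sets are rejected.

Restitution: per-beat estimates pooled by pacing rate, mean ± sample SD
(n − 1). Pooling beats across experiments (rather than averaging
per-experiment means) is a choice; with the beat counts per rate
unrecorded in typical summaries, pooled aggregation is the only
reproducible convention, and it is what `restitutionSummary()` implements.

# Perfusion trend analytics

* **Hourly slopes:** per-experiment OLS of concentration vs time (per
  hour), then mean ± sample SD across experiments. Published per-hour
  increments could also be read as mean successive differences; OLS is
  chosen because it uses all samples and coincides with the successive
  difference for the evenly-spaced, two-point case.
* **Percent change** is always relative to the pre-connection baseline
  sample (the first sample of each series).
* **Excursion flags** partition every referenced sample into
  low / in-range / high; samples without limits are unflagged.
* **Deterioration rate:** OLS slope of percent-of-baseline cardiac output,
  sign-flipped to a positive %/hour.
* **Homeostasis duration:** the criterion is not externally defined, so the
  package reuses the platform's own inclusion thresholds (CO ≥ 3 L/min,
  aortic ≥ 60 mmHg, atrial 10–20 mmHg) as the failure criterion — an
  informed default, fully configurable, not an authoritative rule. Failure
  must persist for 2 consecutive samples so a single noisy reading cannot
  end a run.
* **Weight change:** paired t-test (`stats::t.test`), with the
  zero-variance-of-differences case reported as a degenerate p → 0 (or 1
  for identical lists) instead of an error.
* **ANOVA across hours:** `stats::aov` on time-as-factor, raw p-values, no
  multiplicity adjustment (deliberately, matching common reporting of such
  panels).

The perfusion generator (`simulatePerfusionRun()`) draws per-experiment
linear drifts around the scenario's hourly rates (sodium +3.9 ± 1.2,
chloride +4.7 ± 2.4, calcium +0.3 ± 0.2, phosphate +0.2 ± 0.08, magnesium
+0.2 ± 0.1 mmol/L/h; ammonia +132.5 ± 34.2 µmol/L/h from 305 ± 76 µmol/L;
potassium flat at 7 ± 0.3 mmol/L; glucose and lactate −1 mmol/L/h), hourly
samples over 240 min. Baseline levels and reference ranges are plausible
porcine values chosen once for the simulator — they are synthetic, not
measured. Hemodynamics: baseline CO 5.1 ± 1.7 L/min declining linearly in
percent of baseline at 12.5 ± 2.7 %/h, aortic 75 ± 8 and atrial 13 ± 2 mmHg
held at their working-mode targets; baseline draws are rejection-sampled
against the platform's inclusion criteria (CO ≥ 3 L/min, AP ≥ 60 mmHg, ATP
10–20 mmHg at working-mode start), because a cohort is by construction
composed of hearts that met them. Heart weights: pre 513 ± 104 g, gain
144 ± 41 g. Linear drift is a first-order emulation: real panels show
wash-out transients in the first hour, manual glucose/pH corrections and
late lactate inflections that the generator does not model.

# Problem sizes and numerical tolerances in the test suite

The suite cross-validates the estimators on noiseless planar waves at
30–150 cm/s along 8 compass directions on both acquisition geometries
(64 full pipeline runs; agreement within 1 %), checks activation detection
at sample resolution against analytic ATs, and uses brute-force oracles
elsewhere: 1000-replicate Monte-Carlo bands for plane-fit speed under 1 ms
AT noise and for cohort slope recovery, exact sign-flip permutation (2¹⁶
flips) against the paired t-test, label permutation against the ANOVA F,
and closed-form crossing times for homeostasis. Recordings in tests use
2–5 beats and the two standard grids; perfusion cohorts use 7 experiments
with hourly samples over 240 min — the scale of the experiments the
package models, which also keeps the whole suite under a minute.

# Known limitations

* Wavefronts are kinematic; no curvature-aware or anisotropic CV methods
  (no polynomial surface CV, no conduction tensor estimation).
* No repolarisation analysis (ARI), no body-surface mapping, no 3D
  geometry.
* The sinus-rhythm segmentation path is a convenience, not a validated
  QRS detector.
* The homeostasis criterion is a package default, not an authoritative
  definition; report it alongside any duration you publish.
* Restitution pooling weights experiments by their beat counts; if you
  need per-experiment weighting, aggregate `fitPlaneVelocity()` outputs
  yourself before calling `restitutionSummary()`.
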