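# epimapr

Epicardial electrogram mapping and perfusion trend analytics for ex vivo
working-heart experiments.

Isolated hearts perfused with warm oxygenated blood on a working-heart
platform are a standard test bed for cardiac devices and surgical training.
Two streams of data characterise how well such a preparation holds up over
the hours of an experiment:

* **Unipolar epicardial electrograms (UEG)** recorded simultaneously from a
  rectangular multielectrode grid on the left ventricle while the heart is
  paced at fixed rates (typically 100, 120 and 150 beats/min). From these
  one derives per-beat *activation maps* and the *wave propagation velocity*
  (WPV) of the depolarising wavefront, whose dependence on pacing rate is
  the electrical restitution of the tissue.
* **Hourly blood panels and continuous hemodynamics** (electrolytes,
  metabolites, damage markers; cardiac output and pressures), which drift as
  the isolated organ lacks hepatic and renal clearance.

`epimapr` implements the full analysis chain for both streams, plus a
synthetic generator with known ground truth so that every stage is testable
without access to recorded hearts.

## The methods in brief

**Preprocessing.** UEG channels are band-pass filtered with a digital
Butterworth filter, cutoffs f<sub>c1</sub> = 0.5 Hz and f<sub>c2</sub> =
40 Hz (order 4, applied forward–backward so the filter is zero-phase and
does not displace activation times).

**Activation times.** Within the QRS search window of each paced beat,
the local activation time under electrode *p* is

> AT(p) = argmin<sub>t</sub> dV/dt,

the instant of steepest negative deflection of the unipolar electrogram.
Beats are segmented around each pacing stimulus with a post-stimulus
blanking interval that excludes the stimulus artifact.

**Activation maps and isochrones.** Per beat, the AT(p) field on the grid
is discretised into isochrone bands (default 10 ms) joining the areas that
activate simultaneously.

**Wave propagation velocity.** Two estimators are provided:

> WPV = d(p₂, p₁) / (AT(p₂) − AT(p₁)),

the two-point quotient for electrodes p₁, p₂ along the direction of
propagation (d is Euclidean distance), and a least-squares plane fit
AT(x, y) = a·x + b·y + c whose inverse gradient magnitude is the speed —
more robust, since it pools all valid electrodes. Per-beat estimates are
pooled by pacing rate into a restitution table (mean ± sample SD).

**Perfusion trends.** Per-analyte hourly OLS slopes (per experiment, then
mean ± SD across experiments), percent change from the pre-connection
baseline, reference-range excursion flags, the cardiac-output deterioration
rate (OLS slope of percent-of-baseline CO, %/hour), homeostasis duration
(time until CO ≥ 3 L/min, aortic ≥ 60 mmHg, atrial 10–20 mmHg first fails
persistently), paired t-tests for heart-weight gain and one-way ANOVA
across sampling hours.

## Worked example

Simulate a noisy planar wavefront (100 cm/s) on an 11 × 11 grid with 5 mm
pitch, paced at 100 bpm and sampled at 2048 Hz, with electrode (2,6)
malfunctioning, then run the full pipeline:

```r
library(epimapr)

grid  <- ElectrodeGrid(11, 11, spacing = 5, badChannels = c(2, 6))
wave  <- planarWave(speed = 100, direction = c(1, 0), onsetDelay = 130)
beats <- beatTrainSpec(pacingRate = 100, nBeats = 3, noiseSd = 0.05,
                       seed = 42)
rec   <- simulateRecording(grid, wave, beats, fs = 2048)

filt <- bandpassFilter(rec)              # zero-phase Butterworth 0.5-40 Hz
maps <- detectActivationTimes(filt, segmentBeats(filt))
maps[[1]]
#> ActivationMap: beat 1 (stimulus at 0 ms), 120/121 valid electrodes
#>   AT range: 129.94 - 180.08 ms after stimulus

estimateWpvTwoPoint(maps[[1]])           # deterministic electrode pair
#> VelocityEstimate: beat 1, 99.88 cm/s (two_point)
fitPlaneVelocity(maps[[1]])
#> VelocityEstimate: beat 1, 99.98 cm/s (plane_fit)
#>   direction (1.000, 0.000), RMS residual 0.043 ms
```

The wave reaches the grid ~130 ms after the stimulus and crosses it in
50 ms; the malfunctioning channel is excluded from every map; both
estimators recover the generator's 100 cm/s to within noise.
`plotActivationMap(maps[[1]])` draws the isochrone map.

On the perfusion side, a synthetic seven-heart cohort under the default
scenario (electrolyte drifts, ammonia accumulation, CO decline):

```r
run <- simulatePerfusionRun(seed = 7)
head(trendSlopeSummary(trendSummary(run$biomarkers)), 3)
#>         analyte   unit   meanSlope     sdSlope n
#> 1       ammonia umol/L 137.0214493 35.71424239 7
#> 2 calcium_total mmol/L   0.2392408  0.06941188 7
#> 3      chloride mmol/L   5.1250607  2.83439277 7

mean(vapply(run$hemodynamics, deteriorationRate, numeric(1)))   # 13.22 %/h
mean(vapply(run$hemodynamics, homeostasisDuration, numeric(1))) # 177.1 min
```

Slopes are unit/hour; the recovered cohort means sit around the scenario's
configured rates (ammonia +132.5 µmol/L/h, CO −12.5 %/h), and homeostasis
lasts about three hours before the cardiac-output criterion fails.

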