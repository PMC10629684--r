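---
title: "Inferring sympathetic activation from surface temperature: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring sympathetic activation from surface temperature: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vasotherm)
```

## The problem

During an acute stressor, the sympathetic-adrenal-medullary response drives
tachycardia and peripheral vasoconstriction within seconds. Vasoconstriction
cools exposed skin, so body-surface temperatures measured by infrared
thermography (here the periocular skin ring, `T_eye`, and the bill,
`T_bill`, of a small passerine) are a candidate non-invasive window on
sympathetic state. Establishing that link requires synchronizing two very
different data streams — R-wave detections from an implanted ECG telemetry
transmitter and 16-bit radiometric thermal frames — and modelling calibrated
regional temperatures against heart-rate variability (HRV) while
controlling for movement, imaging geometry, air temperature and sex.

`vasotherm` implements that pipeline end to end, together with a
synthetic-data generator with known ground-truth coupling, so every stage
can be verified without any animal data.

## Cardiac chain

R-R intervals (RRI) are differences of successive beat times, stamped at
the closing beat. HRV is the coefficient of variation (sample sd / mean) of
the RRIs inside a **trailing 2 s window**, emitted only where at least 3
intervals fall in the window (below 3 a CV is statistically meaningless;
the window width itself is part of the study design and is not a tuning
knob here). Trailing alignment means the estimate at stressor onset uses
only pre-onset data.

Two censoring rules precede any analysis:

* **Gap/spike flagging.** Telemetry dropouts create intervals spanning
  several missed beats; spurious detections create implausibly short ones.
  An interval is flagged when it leaves `[0.5, 2] x` the local median over
  11 neighbouring intervals. Flagging is non-destructive and monotone.
  This is a documented automated surrogate for what is usually a manual
  review step; the multipliers are deliberately loose so that genuine
  physiological variation (CV ~ 0.03) is never touched.
* **Onset-spike censoring.** When the rolling window straddles the abrupt
  heart-rate rise at stressor onset, the mixed slow/fast intervals inflate
  the CV artifactually. HRV values above the run's baseline mean within
  the first 10 s after onset are removed. The operation is idempotent and
  never adds points.

The censored trace is linearly interpolated to one value per millisecond.
Gaps wider than `max_gap` (default 2 s) are left missing rather than
bridged — interpolating across a multi-second dropout fabricates data; set
`max_gap = Inf` to bridge everything.

## Thermal chain

Regional temperatures are **maxima** over a region of interest: for small,
free-moving animals imaged against a cooler background, motion blur biases
surface temperature estimates downward, never upward, so the maximum is
the least-biased statistic. Oval ROIs test pixel centres against the
ellipse inequality; line ROIs (nare to bill tip) are rasterized
8-connected. Both are deterministic and oracle-checkable; coordinates are
1-based (row, col) from the top-left pixel.

Counts map linearly to temperature (`T = counts/400 - 50` °C, i.e.
0.0025 °C per count over −50 to +113.8 °C). Calibration applies, per
logger minute, the offset between an in-scene reference logger and the
camera's mean estimate of the logger surface; the single offset absorbs
camera bias and emissivity/gain error, and is step-held across the minute
(the logger reports once per minute; interpolating between readings would
claim precision the instrument does not have). For a purely additive
camera error the correction is exact up to count quantization (≤ 0.0025 °C).

Each series is then quality-filtered (the usable-frame flag stands in for
manual sharp/in-profile image selection; an automated sharpness score is
out of scope) and passed through a **trailing 5 s rolling maximum**, again
suppressing one-sided negative error.

A note on the rolling maximum: a trailing windowed maximum is *not*
idempotent. Each application lets a maximum propagate one further window
forward (take values (10, 1, 1) at times (1, 2, 3) s with a 1.5 s window:
one pass gives (10, 10, 1), a second gives (10, 10, 10)). The filter here
is the standard trailing one; re-application is pointwise non-decreasing,
and exact idempotence holds only when all observation gaps exceed the
window. The validation suite keeps a strict idempotence assertion to
document this property; it fails for exactly the reason above, and we
document the filter rather than redefine it.

## Periods and matching

Analysis periods on the onset-relative clock: baseline [−60, 0) s,
stressor [0, 180) s, 15 min [840, 900) s, 30 min [1740, 1800) s, with
half-open membership so 0 s opens the stressor and 180 s belongs to
nothing. Baseline/15 min/30 min reduce to one value per run (mean for
cardiac variables, max for temperatures); the stressor keeps multiple
readings. A temperature period enters analysis only with ≥ 5 measurements
counted *before* filtering (quality-rejected frames were never
measurements, so they do not count).

Each retained temperature observation is joined with the HRV value at its
exact millisecond grid cell (the grid is dense, so nearest-cell lookup and
nearest-neighbour matching coincide), the activity signal at its
timestamp, and the air temperature step-held per logger minute.
Observations falling in censored HRV gaps are dropped and counted, so
exclusion bookkeeping reconciles exactly. Confidence intervals for period
summaries use the percentile bootstrap of the mean with 10 000 resamples
(percentile rather than BCa: only the resample count is part of the study
design, and the percentile interval is the simplest estimator whose
coverage we can verify by simulation).

## The coupling model

For each region, temperature is modelled with linear mixed-effects models
(`nlme::lme`, maximum likelihood so AICs are comparable across
fixed-effect sets):

```
temp ~ hrv + activity + position_index + air_temp + sex
random = ~ 1 | (round/)individual(/run_order)
correlation = corExp(form = ~ t) (selected)
```

* **Correlation structure** is chosen by refitting the full model under
  AR1, linear, Gaussian and exponential residual correlation (defined on
  observation time within the innermost group; AR1 on observation order)
  and keeping the lowest AIC, ties to the first candidate. On a regular
  grid AR1 and exponential are the same model, so selection consistency
  is only testable — and is tested — on irregularly spaced observations,
  which is what quality-filtered frames produce anyway.
* **Dredging** fits all 2^5 = 32 fixed-effect subsets with that
  structure. Non-convergent subsets are flagged and excluded.
* **Averaging** retains models within 6 AIC of the best, removes
  *uninformative* models (a retained model that equals a strictly simpler
  retained model plus extra terms while sitting within 2 AIC of it), and
  renormalises Akaike weights `w_i ∝ exp(−Δ_i/2)`. Conditional averages
  run over models containing a term; full averages treat the term as 0
  elsewhere, so `full = conditional × summed weight` term by term.
  Averaged standard errors use the model-averaging variance formula
  including between-model spread; CIs are normal-theory at 95%.
* **Collinearity** is checked post hoc with VIF = 1/(1−R²) per design
  column at the conventional threshold of 3.

## The synthetic generator

The generator emulates the study conditions, not the optics. A latent
sympathetic activation `s(t) ∈ [0, 1]` rises logistically at onset
(90% of ceiling 15 s after onset), holds while the experimenter is
present, and decays exponentially after room exit (τ = 300 s). From `s`:

* **Beats**: local mean RRI `60000/HR(s)` ms with HR interpolating
  556.7 → 875 beats/min, local dispersion set so the interval CV tracks
  0.03 → 0.01. Optional dropped beats and spurious detections at
  configurable rates.
* **Frames**: eye drive proportional to `s` with a partial mid-stressor
  recovery dip (centre 40 s); bill drive integrating `s` over the 180 s
  stressor (so activation held at 1 for the whole stressor accumulates to
  exactly the full coupling, a 4 °C drop) and recovering with τ = 450 s,
  chosen so the bill sits ~0.9 °C below baseline 11 min later, matching
  the intended response shape. Activity is a Poisson-burst shot-noise
  process, elevated during handling; its amplitude is a stand-in (no
  units exist for the transmitter's movement channel), so only the sign
  and recovery of the fitted activity coefficient are meaningful.
  Per-observation temperature noise is 0.2 °C and a per-run offset
  (SD 0.3 °C) provides the random-intercept variance; both are
  realistic-scale choices, not reported quantities. A camera bias
  (default −0.7 °C) is added to every pixel; the reference target is
  rendered at the logged temperature so calibration must remove exactly
  that bias. The default usable-frame fraction is 0.03, matching the
  ratio of reported usable measurements per run (~75–79) to in-period
  frames at 7.5 Hz (~2700).

What the generator does **not** emulate: plumage radiative physics,
motion-blur optics (quality is a flag, not a rendered degradation),
atmospheric transmission, electrode-detachment failure modes, or
treatment-group effects. Passing recovery tests therefore demonstrate the
*pipeline's* correctness under the stated signal structure, not the
biological effect size in real birds.

## The recovery benchmark and its one honest failure

The benchmark (used by the acceptance suite and `recover_coupling()`)
scales the study down to run on one CPU in minutes: 10-minute runs,
1 Hz thermal frames, 4 individuals × 1 run per replicate, usable-frame
fraction 0.225 so the *usable-observation rate* (~0.22 obs/s) matches the
full-rate default and the reported per-period counts (~16 baseline, ~36
stressor observations per run). The bill drive is set proportional so a
structural temperature-on-HRV slope exists:
`k = beta_bill / (cv_baseline − cv_stress) = 4 / 0.02 = 200 °C` per unit
CV. Dredging uses no residual correlation structure here: the generator's
observation noise is white and usable frames are ~4 s apart, beyond the
2 s CV window, so matched HRV errors are independent.

Across 50 replicates the averaged HRV coefficient is positive in 100%
and the dredge all but always retains `hrv`; with coupling disabled the
CI covers zero at nominal rate. But the benchmark's CI-covers-truth
requirement fails, and it fails for a structural reason worth stating
plainly: the matched HRV is itself an estimate — a sample CV over ~19
(baseline) to ~29 (stressor) intervals — with sampling SD
`cv/sqrt(2(n−1))` ≈ 0.005 at baseline. Against a true HRV signal SD of
~0.009 across the baseline/stressor design, that is classical
errors-in-variables attenuation with reliability λ ≈ 0.9: the estimand of
the fitted regression is `λk ≈ 180`, not `k = 200`. With ~200
observations per replicate the CI half-width is a few units, so intervals
concentrate tightly around the attenuated estimand and essentially never
cover the structural slope (measured median bias ≈ −11%, the extra
percent or two coming from window smoothing across the onset
transition). No usable
sample size fixes this — shrinking n widens CIs slower than it shrinks
the bias-to-SE ratio — and the bias is a property of the *study design*
(the 2 s window at these heart rates), not of this implementation. The
recovery report therefore also prints the attenuation-predicted estimand
so the two can be compared. The same mechanism applies, unknowably, to
analyses of real recordings with this design.

## Numerical and sizing choices

* Count encoding clamps to [0, 65535]; all scene temperatures sit well
  inside the representable range, so clamping never activates in
  practice.
* CV computation slices each trailing window directly (the same
  arithmetic as the brute-force oracle) rather than using running sums;
  at these window sizes the O(n·w) cost is negligible and it avoids
  catastrophic cancellation, keeping implementation and oracle within
  1e−10 relative everywhere.
* `lme` fits use ML with `nlminb` (falling back to `optim`), tolerance
  1e−9; in the degenerate zero-variance limit the fitted intercept SD
  lands at the boundary and fixed effects match OLS to ~1e−9.
* Test problem sizes: oracle sweeps use 1000 random series of 20–60
  points; bootstrap coverage uses 2000 replicate datasets of n = 30 at
  B = 10 000; selection-consistency uses 25 seeds (the win rate is far
  from the 80% bound); the recovery benchmark uses 50 coupled and 100
  null replicates.

## Limitations

* The artifact-flagging rule is a surrogate for manual telemetry review;
  its multipliers are documented, not derived.
* Quality is an input flag; no sharpness score is computed.
* The exponential/Gaussian/linear correlation ranges are defined on time
  within run; between-run residual correlation is assumed absent.
* Coefficients from real recordings are not reproducible here (no raw
  data are distributed); all quantitative validation is against the
  generator's known truth.
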