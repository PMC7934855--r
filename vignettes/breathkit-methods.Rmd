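---
title: "breathkit: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{breathkit: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(breathkit)
```

## The measurement problem

Whole-body plethysmography records breathing in an unrestrained rodent as
a flow (or flow-proportional) signal from a sealed chamber with a constant
bias flow. In mouse models of spinocerebellar ataxia type 1 (SCA1),
neuromuscular breathing dysfunction is a late, survival-limiting
phenotype: affected mice first show a reduced tidal volume with a
compensatory rise in breathing frequency, and near end of life a deeper
tidal-volume deficit without further frequency compensation, so minute
ventilation finally falls. Quantifying that progression requires
per-breath segmentation of a noisy signal, aggressive artifact rejection
(mice sniff, move, and groom in the chamber), and summary metrics that are
robust to what was rejected. breathkit implements that analysis chain,
plus a waveform simulator so every stage can be validated against a known
ground truth — no raw plethysmography recordings of this kind are publicly
deposited.

## Breath segmentation

The flow trace is baseline-corrected and breaths are delimited at upward
zero-crossings validated by hysteresis: a crossing only counts as an onset
if the signal afterwards exceeds `+h` and beforehand dropped below `-h`.
The default `h` is 5% of the interquartile range of the corrected flow, a
unitless choice that survives calibration changes. Onset and
inspiration-end times are refined by linear interpolation between the
bracketing samples; purely grid-quantized durations can shift by exactly
one sample period when the sampling rate changes, which interpolation
avoids.

Two deliberate conventions:

* **Baseline is the rolling (or global) mean, not the median.** A breath
  that conserves volume integrates to zero regardless of how asymmetric
  its waveform is, so the mean estimates zero flow without bias. The
  median does not: with inspiration occupying less than half the cycle
  (the package default is 40%), the sample median sits well below zero,
  and using it inflated inspired volumes by ~30% and shifted every onset
  in early testing. A positive `baseline_window` gives a running mean that
  tracks slow drift from bias-flow imbalance; `0` (default) subtracts the
  global mean.
* **Breath length is onset-to-onset**, so lengths tile the recording
  exactly and the irregularity statistic below has a single unambiguous
  "breath length" series. Expiratory time is the remainder of the breath
  after inspiration, which folds any end-expiratory pause into `te`; a
  pathologically long pause therefore counts toward the expiratory-time
  artifact rule, which is the intended, conservative reading.

Inspired (`vti`) and expired (`vte`) tidal volumes are trapezoidal
integrals of the positive and negative phases. At 1 kHz and typical mouse
breath durations the integration error is far below 0.1%.

## The artifact-rejection cascade

Quality control applies, in order:

1. **Per-breath rules** (each a pure function of one breath): inspiratory
   time under 0.025 s, expiratory time over 10 s, or expired volume more
   than twice the inspired volume. All comparisons are strict — a breath
   sitting exactly on a threshold is retained — mirroring the wording
   "under / over / more than" of the original criteria.
2. **A sliding window of 200 breaths** (step 1) over the breaths that
   survived step 1: a window is rejected when strictly more than 10% of
   its breaths are faster than 600 breaths/min (instantaneous rate,
   60/length), and every breath of a rejected window is excluded. With
   fewer than 200 surviving breaths the whole sequence is one window, so
   short recordings are not silently exempt.
3. **Animal exclusion**: fewer than 100 reliable breaths excludes the
   animal (a report field, never an exception).

The original analysis code is not recoverable, so two ambiguities are
exposed as switches with documented defaults: `window_scope` ("survivors",
the default, or "all" — whether the window runs over rule survivors or all
breaths) and `window_action` ("interval", the default, excluding whole
rejected windows, or "fast_only"). Filtering survivors avoids counting a
movement spike twice (once as a tiny-`ti` fragment, once as "fast
breathing").

One consequence worth knowing: under the default survivors scope,
loosening `ti_min` or `te_max` can *decrease* the reliable count, because
newly admitted fast breaths can push windows over the 10% fraction and
take their neighbours with them. The intuitive monotonicity (looser
thresholds, no fewer reliable breaths) is guaranteed only with
`window_scope = "all"`, and that is where the package tests it.

## Respiratory metrics

For the reliable breaths of one animal:

* `frequency` — mean instantaneous rate, `mean(60 / length)`. The mean
  rate rather than breaths-per-total-time is used because exclusions
  fragment the recording and the window rule is breath-indexed, not
  time-indexed.
* `tidal_volume` — mean inspired volume `vti` (minute ventilation is "the
  volume inhaled per minute", so the inspired side is the relevant one).
* `minute_ventilation` — `frequency * tidal_volume`, exact by
  construction.
* `ibii_mean` — mean interbreath-interval irregularity, where
  `IBII(n) = |L(n+1) - L(n)| / L(n)` for breaths consecutive *in the
  original recording*. Pairs spanning an excluded breath are skipped, not
  bridged: the definition's `n`, `n+1` are chronological recording
  indices, and bridging would manufacture spurious irregularity at every
  exclusion boundary. IBII is dimensionless, zero for metronomic
  breathing, and invariant to rescaling all lengths.

Group comparison is a one-way fixed-effects ANOVA across genotypes at a
single age (the published two-way designs concern longitudinal behavioral
assays outside this scope). The 0.05 threshold is reported, not acted on,
and no multiple-testing correction is applied across the three metrics,
matching the original reporting.

## The simulator: a stated world

`simulate_trace()` renders a breath schedule into a flow signal: each
breath is a positive half-sine (inspiration) then a negative half-sine
(expiration), with amplitudes set analytically so the half-wave integrals
equal the scheduled volumes — smooth, integrable, and checkable in closed
form; the real waveform shape is unknown and nothing downstream depends on
it. Breath lengths are `L = T0 * exp(sigma * Z + sigma^2 / 2)` with i.i.d.
standard-normal `Z`; the offset centres the jitter so `E[60/L]` equals the
configured rate, and `sigma` is solved from the closed form
`E[IBII] = exp(sigma^2) * (2 * pnorm(sigma * sqrt(2)) - 1)` so the
`irregularity` knob *is* the target mean IBII. Artifacts are injected at
configured per-minute Poisson rates: sniffing runs (default 30 breaths at
700 breaths/min — deliberately beyond the 600 cutoff so the window filter
has true positives), prolonged expirations (12 s > the 10 s rule),
volume-asymmetric breaths (Vte = 2.5 Vti), and biphasic movement spikes.
Chamber bias flow appears only as an optional constant offset (plus
optional white noise); pressure-to-volume calibration physics is out of
scope and traces are treated as calibrated flow.

Phenotype presets encode only the published *qualitative* orderings — no
absolute breathing baselines are printed for these genotypes, so the
numbers are package choices at typical awake-mouse magnitudes, fixed once:

| preset | rate (bpm) | VT (mL) | irregularity | VE (mL/min) |
|---|---|---|---|---|
| WT | 250 | 0.20 | 0.10 | 50.0 |
| SCA1_6mo | 330 | 0.17 | 0.15 | 56.1 |
| SCA1_late | 330 | 0.13 | 0.20 | 42.9 |
| SCA1_rescued_late | 370 | 0.14 | 0.15 | 51.8 |

This reproduces: lower VT in SCA1 with compensatory frequency (mildly
*raised* VE at 6 months), no further frequency rise late (VE falls), and a
frequency-driven VE recovery in the rescued genotype. The default
recording is 30 minutes at 1 kHz; cohorts default to 10 animals per
genotype. Per-animal seeds derive from the master seed by a fixed
linear-congruential counter, so enlarging a cohort never perturbs existing
animals.

What the simulator does **not** emulate — and hence what a green test does
not establish: between-animal variability within a genotype (every animal
of a preset shares the same true rate and VT, so simulated group
comparisons have unrealistically small within-group variance for volume
metrics), temperature/humidity corrections, chamber pressure dynamics,
apneas or sighs as distinct event classes, and real movement artifacts,
which are messier than a clean biphasic spike. Ground-truth recovery on
simulated traces validates the *code*, not the commercial detector it
replaces; the original onset criterion is unknown and only internal
consistency can be tested.

## Numerical and degenerate-input choices

* Hysteresis falls back to machine epsilon if the IQR is zero; a trace
  with no excursions returns an empty table with a warning, not an error.
* A breath whose inspiration never returns to zero before the next onset
  gets `te = 0` and is discarded by the detector floor.
* `vti = 0` with `vte > 0` is ratio-flagged; `vti = vte = 0` is not (both
  fall out of the strict `vte > 2 * vti` comparison).
* Near-zero within-group variance in the ANOVA would normally raise R's
  "essentially perfect fit" warning; it is muffled because the F and p
  limits are exactly what should be reported for such data.
* File ingestion resamples mild timing jitter (>1% step deviation) onto
  the median step with a warning, but treats a step more than 5x the
  median as a dropout and refuses, naming the line.

## Known limitations

Movement spikes split a breath into fragments; the tiny-`ti` fragments are
rejected, but the leading fragment (normal `ti`, near-zero `vte`) can pass
all rules, since the ratio rule only catches `vte >> vti`, not the
reverse. The published cascade has the same blind spot; affected breaths
slightly deflate expired-volume summaries but leave inspired-volume
metrics intact. Apnea subclassification, sigh detection, enhanced pause
(Penh), and gas-exchange corrections are deliberately absent.
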