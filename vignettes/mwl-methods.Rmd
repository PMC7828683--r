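---
title: "Quantifying mental workload from cardiac and oculomotor signals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying mental workload from cardiac and oculomotor signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mwlmetrics)
```

# The measurement problem

Mental workload (MWL) is the ratio between the demands a task places on an
operator and the mental resources available to meet them. In manual
mixed-model assembly, workload rises with *operator choice complexity*: the
number and variety of part, tool and orientation choices per unit time.
`mwlmetrics` implements a multimodal quantification of MWL for simulated
assembly sessions in which participants build four models (`M1`–`M4`) of
increasing complexity while instructions are delivered by one of three
informational assistance systems (AR glasses, tablet, paper). Complexity is
the within-subject factor, the assistance system the between-subject factor.

Three indicator families are computed per participant and model:

* **Cardiac** — heart rate (HR) as an arousal index, and two time-domain
  heart-rate-variability (HRV) indices that fall with rising workload:
  RMSSD and rrHRV. Frequency-domain HRV is deliberately out of scope: it is
  too sensitive to missing or corrected beats in ambulatory recordings.
* **Oculomotor** — pupillary response (PR, diameter in mm), mean fixation
  duration (FD) and saccadic peak velocity (SPV), plus an area-of-interest
  (AOI) analysis of how gaze distributes over the workspace.
* **Performance** — assembly time, failure counts split into wrong parts
  and wrong orientation, and perceived-complexity ratings (1–100).

# Cardiac indicators

All cardiac indicators are functions of the RR series, the times between
consecutive R peaks in ms.

**R-peak detection.** `detect_r_peaks()` uses a dynamic threshold over a
moving window: the rolling upper-quantile envelope of the rectified signal
over 2 s defines the local signal ceiling, a peak candidate must exceed
`threshold_coef` (default 0.5) times that envelope, and a 250 ms refractory
period keeps only the largest candidate in any conflict. The envelope
quantile defaults to 1 (a rolling maximum): because at any plausible heart
rate a 2 s window contains at least one R wave, the rolling maximum tracks
the QRS amplitude, and half of it cleanly separates R waves from baseline
noise, which lower quantiles of the rectified signal do not — they sit in
the noise floor, since QRS complexes occupy only a few percent of samples.
All four parameters are exposed.

**Artifact handling.** `clean_rr()` is an automated surrogate for manual
beat correction, with two declared rules: RR outside 300–2000 ms, or RR
deviating more than 30% from the running median of the last 11 clean
intervals. Flagged intervals are *marked*, never deleted, so time
accounting over segments stays intact; every indicator simply skips them,
and successive-difference pairs that span a flagged interval are dropped,
not bridged.

**Sliding heart rate.** HR is computed continuously over windows of 20
clean RR intervals advancing by 5 intervals; a 5-beat stride is the unique
reading of a 20-beat window with 75% overlap. `HR = 60000 / mean(RR)`.
Each window is stamped with its last beat time (a centred stamp would not
be time-causal for continuous monitoring) and carries the duration of its
stride — the sum of its newest five intervals — as a time weight, so that
overlapping windows can be aggregated into time percentages without double
counting. Windows are restarted at model boundaries and never straddle
them.

**RMSSD** is `sqrt(mean((RR[i+1] - RR[i])^2))` over adjacent clean pairs —
the standard parasympathetic time-domain index. It scales linearly with RR:
slowing all beats by a factor k multiplies RMSSD by k.

**Relative RR and rrHRV.** The relative RR series
`rr[i] = 2 (RR[i] - RR[i-1]) / (RR[i] + RR[i-1]) * 100` is dimensionless
and exactly invariant to rescaling all RR intervals, which makes summaries
built on it robust to overall HR shifts and therefore better suited to
tasks where arousal and variability change together. Values with
`|rr| >= 20%` are treated as artifacts of the return map and excluded.
Because the literature leaves the final aggregation under-specified, this
package fixes one definition and pins it with a regression fixture:
successive retained values form return-map points `P[i] = (rr[i],
rr[i+1])`, and **rrHRV is the median Euclidean distance of these points
from their component-wise median point**. A robust centre and a robust
spread keep single ectopic-like excursions from dominating the summary.

# Oculomotor indicators

**Pupil preprocessing** (`preprocess_pupil()`) mirrors standard
pupillometry practice: per eye, discard samples outside 1–9 mm or flagged
invalid by the tracker; remove outliers deviating more than 0.5 mm from the
rolling 1 s median; linearly interpolate interior gaps up to 1 s (blinks
are 100–400 ms, so this bridges blinks but not tracking dropouts); never
extrapolate leading or trailing gaps; finally average the two eyes
sample-wise. The three thresholds are exposed as parameters; the defaults
are conventional values, not estimates. When exactly one eye is usable at
a timestamp the cleaned trace falls back to that eye — a documented
deviation from strict binocular averaging that keeps coverage high. PR per
model is the sample mean over the segment (not a fixation-weighted mean).

**Event summaries.** Fixation/saccade streams arrive already detected
(event detection from raw gaze coordinates is vendor-software territory).
`segment_event_stats()` assigns each event to the segment containing its
start — the simplest total rule; at 60 Hz event granularity boundary events
are rare. Mean FD and mean SPV per model feed the statistics layer.

**AOI metrics.** Five labelled regions (assistance system, assembly
object, assembly parts, tools, assembly tablet) plus an implicit
background. Per AOI and model, `aoi_metrics()` reports dwell time (summed
fixation time), dwell percentage *of the full segment duration* (so rows
sum below 100 — saccade and background time are not dwell), fixation count
and share (background counts in the denominator), average fixation
duration, and revisits. A *visit* is a maximal run of consecutive
fixations in one AOI; saccades never interrupt a visit, only a fixation
elsewhere does; `revisits = visits - 1`. `aoi_shift()` contrasts M4
against M1 to quantify the redistribution of gaze toward the assembly
object as complexity grows.

# Over/underload states

Workload limits are individual, so the package anchors them to each
participant's own session: `reference_stats()` computes the weighted mean
and *population* (divide-by-N) SD of a signal over the concatenation of all
four model segments — excluding the seated baseline, artifacts and missing
samples. A value strictly above `mean + sd` is overload, strictly below
`mean - sd` underload; ties go to normal (a measure-zero convention for
continuous signals, fixed for determinism). `state_time_percentages()`
converts states to percentage of time per model: HR windows are weighted
by their stride span, pupil samples equally. The three percentages
partition 100 exactly, and all percentages are invariant under affine
rescaling of the signal. For a self-referenced Gaussian signal each
extreme state captures `100 * pnorm(-1) = 15.87%` of time in the limit —
the calibration check used in the tests.

Whether overlapping HR windows should be weighted by time or simply
counted is genuinely open; stride weighting is declared here because it
converts window counts to seconds without double-counting the 75% overlap.

# Mixed-design ANOVA

`mixed_anova()` implements the classical split-plot decomposition for one
within factor crossed with one between factor: the between-group effect is
tested against subjects-within-groups, the within effect and interaction
against the within-subjects residual; effect sizes are partial eta squared
`SS_effect / (SS_effect + SS_error_of_effect)`. With unequal group sizes
the sequential (weighted-means) decomposition is used; it coincides with
R's `aov()` error-strata output, against which the implementation is
verified to 1e-8 on randomized designs. No sphericity correction is
applied: the headline complexity factor has two levels, for which
sphericity holds trivially, and four-level analyses report uncorrected F
with this caveat. "Overall" rows of report tables are sample-size-weighted
means (`weighted_overall()`), and report tables round half away from zero
to two decimals; internal computation stays at full precision. P values
are reported but never gate any pipeline step.

# The synthetic cohort generator

No public participant data exist for this paradigm, so the generator is a
first-class, tested module that emulates the statistical structure the
analysis assumes. Its defaults *are* the study conditions:

* **Schedules** — four segments in fixed order M1–M4 (low complexity
  first), mean durations 128/165/564/682 s, coefficient of variation 0.2
  (matching the reported dispersion of assembly times), optional 300 s
  seated baseline afterwards. Segments are back-to-back; an optional gap
  carries no samples and is ignored by all statistics, which makes the
  "whole assembly time" reference window unambiguous.
* **RR series** — per-cell mean HR from the calibrated system × model grid
  (`default_hr_grid()`, range 91.2–97.5 bpm), a stable per-participant
  offset (SD 3 bpm) for between-subject variance, and lag-1 autoregressive
  RR fluctuations (`phi = 0.6`, innovation SD 22.4 ms — the simplest model
  giving realistic HRV, calibrated so RMSSD ≈ 25 ms, inside the 20–34 ms
  range typical of the task). Beat artifacts (ectopic shifts, missed
  beats) are injected at 0.5% per beat and logged as ground truth.
* **ECG traces** — Gaussian R-wave templates (amplitude 1, width 20 ms) at
  the beat times plus white noise, 1000 Hz. Deliberately not a PQRST
  morphology: just enough structure to exercise the detector against known
  truth.
* **Pupil traces** — 60 Hz binocular; both eyes share the cell mean
  (`default_pupil_grid()`, 3.29–3.66 mm) plus a slow AR(1) fluctuation,
  with independent per-eye noise, blink gaps (invalid runs, 0.2 Hz,
  100–300 ms) and isolated outliers.
* **Gaze streams** — alternating fixations and saccades; AOI labels follow
  a first-order chain; fixation durations are log-normal per AOI (e.g.
  assembly object 380 ms, tools 180 ms), saccades ~50 ms, peak velocities
  normal around 185 deg/s.
* **Performance** — assembly time equals segment length; Poisson failures
  per system × complexity (orientation failures differ between systems at
  high complexity, part failures do not); perceived complexity rated once
  per block, means 26.59 (low) and 53.52 (high), SD 12 — consistent in
  magnitude with the reported manipulation-check effect size.

**AOI chain calibration.** Rather than scripting an assembly plan, the
chain is solved so the *long-run dwell shares* match per-model targets
(`default_aoi_dwell_targets()`; M1: most dwell on assistance system,
object and parts; M4: strong shift to the object at 48.63%; M2/M3
interpolated). Writing `pi` for the fixation-count occupancy, `mu_a` for
mean fixation duration of AOI `a`, `s` for mean saccade duration, and
`d_a` for the dwell-share target (percent), the expected event-cycle time
`T` satisfies `pi_a = d_a T / (100 mu_a)` for labelled AOIs with
background absorbing the remainder, giving the closed form

```
T = (mu_bg + s) / (1 - sum(d)/100 + mu_bg * sum(d_a / mu_a) / 100)
```

The transition matrix is `(1 - rho) * 1 pi' + rho * I` with stickiness
`rho = 0.3`: `pi` is stationary for every `rho`, so dwell shares are
preserved while same-AOI runs (and hence realistic revisit counts) emerge.
A full matrix can be supplied directly via `aoi_transition_override`.

**Determinism.** One global seed; every participant × signal stream draws
its seed from a stable arithmetic hash of (seed, participant index,
stream), so enlarging a cohort never reshuffles existing participants, and
identical configs serialize byte-identically. Gender is generated as
metadata only, with no physiological effect — matching the observed null
result for assembly times.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: pupil light and near reflexes (both eyes are
driven by a single workload signal), realistic ECG morphology or
electrode-motion noise, learning effects within a session, scripted
task-phase structure in gaze (the chain has no plan), or correlations
between the cardiac and oculomotor channels beyond their shared segment
structure. Parameter-recovery results demonstrate that the *pipeline* is
unbiased and correctly plumbed, not that the indicators are valid measures
of workload in the field.

# Numerical choices and degenerate inputs

* RR units are ms everywhere, HR in bpm, conversions centralized.
* Indicators needing too few inputs return `NA` with a warning rather
  than erroring, so one bad segment cannot abort a cohort run.
* An all-zero or flat ECG trace yields an empty beat list, not an error.
* Population SD (divide-by-N) is used for workload references; the choice
  is arbitrary but fixed and documented.
* `mixed_anova()` returns `NA` F when the error SS is zero (constant
  data) and errors, naming the participant, on incomplete within data.
* Redrawing non-positive duration draws is capped at 10 attempts.

# Problem sizes

The test-suite and acceptance-script simulations use cohorts of 30
participants and 10 seeds for parameter recovery (≈ 2,400 beats and 92,000
pupil samples per participant at the default durations), 100,000 samples
for the Gaussian state check, 120 s traces for detector validation, and
1,000 random label sequences for the AOI brute-force comparison; a
200-participant performance-only cohort stabilizes the recovered
perceived-complexity means. These sizes were chosen so every Monte-Carlo
tolerance sits at 3 or more standard errors.

# Limitations

The automated RR-cleaning rules are a surrogate for manual correction, not
a reproduction of it; threshold choices (30% median deviation, 20%
relative-RR cut, 0.5 mm pupil outlier rule) are conventional defaults.
The rrHRV aggregation is one of several in circulation — comparisons
across software should rely on the pinned definition above. Overlap
weighting of HR windows, the one-eye pupil fallback, and the
start-time rule for event-segment assignment are declared conventions.
Four-level within-factor F tests are uncorrected for sphericity.
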