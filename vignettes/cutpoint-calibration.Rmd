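---
title: "Calibrating accelerometer cut-points against indirect calorimetry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrating accelerometer cut-points against indirect calorimetry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Population studies monitor sedentary time (ST) and moderate-to-vigorous
physical activity (MVPA) with body-worn accelerometers, classifying each
short epoch of the acceleration record by comparing a summary metric with an
intensity *cut-point*. Cut-points are population- and placement-specific:
the acceleration a 75-year-old's hip produces at 3 METs differs from a young
adult's wrist. This package implements the laboratory calibration workflow
for adults over 70: participants wear accelerometers on the hip and both
wrists while performing everyday activities and breathing into a portable
calorimeter; oxygen uptake anchors each activity to a MET value; ROC
analysis then finds the metric thresholds that best separate ST
(&le; 1.5 METs) from light activity, and light from MVPA (&ge; 3 METs);
finally the thresholds are cross-validated on an independent sample
performing a different activity protocol. Because raw recordings of this
kind are rarely shareable, the package pairs the analysis pipeline with a
synthetic-data generator whose ground truth is known, so every stage is
testable end to end.

## Acceleration metrics

Two epoch metrics are computed from the raw tri-axial signal
(`enmo_per_second()`, `counts_per_second()`, `aggregate_epochs()`):

* **ENMO** (Euclidean Norm Minus One *g*): per sample
  $e = \max(\sqrt{x^2+y^2+z^2} - 1,\, 0)$, averaged per second and expressed
  in milli-g. Truncation happens per sample, *before* averaging, matching
  the raw-data convention of the open-source toolchain this metric comes
  from; the per-second values are averaged over 5 s epochs.
* **Activity counts**: an open reconstruction of the proprietary
  counts metric — resample each axis to 30 Hz (linear interpolation),
  band-pass 0.25–2.5 Hz (3rd-order Butterworth, applied forward and
  backward), clip to ±2.13 g, quantize at 1/256 g, rectify, zero values
  below the 0.068 g dead-band, decimate to 10 Hz by running maxima, sum per
  second; the per-second vector magnitude across axes is aggregated by
  summing over the epoch. Bit-identity with vendor software is *not*
  claimed — the counts scale here is internally consistent but not
  comparable with vendor output, which is why all count thresholds in this
  package are meaningful only relative to its own counts implementation.

Analysis windows (`trim_activity_window()`) drop the first and last 15 s of
each bout for signal stability and keep at most 3 min, centered, floored to
whole epochs; bouts too short to yield one epoch after trimming are
excluded. The exact trim length and centering are this package's documented
choice — source descriptions of such protocols state only that edge seconds
are excluded and "around 3 min" used.

## From breath-by-breath gas exchange to MET labels

`match_breaths_to_seconds()` assigns each breath to its floor second,
averages within-second duplicates, and carries the last value forward for at
most 10 s (beyond that, missing). `remove_vo2_peaks()` screens artifacts: a
single pass drops values deviating more than 2 SD from the whole-window
mean. Three choices here are deliberate and configurable:

* the pass is **single** (an iterate-to-convergence flag exists) — the
  screening rule is stated in the field as one filtering step;
* the test is **two-sided** — dropouts are as unphysiological as spikes,
  though a one-sided option (`two_sided = FALSE`) restricts it to upward
  peaks;
* statistics are **whole-window**, not running.

`steady_state_met()` averages the cleaned per-second VO2 over the last 2 min
of the bout and divides by body mass and the 1-MET constant. The default
constant is **2.8 mL O2/kg/min**, the value appropriate for older adults;
the usual adult 3.5 is available via `met_constant`. Bouts with fewer than
30 usable seconds are flagged unusable and excluded. `resting_rate()`
averages the last 5 min of a lying-still bout. `classify_intensity()` maps
METs to classes with inclusive boundaries: ST at &le; 1.5, MVPA at &ge; 3.
Classes attach to *activities*, and epochs inherit their parent activity's
class — the calibration criterion is activity-level energy expenditure, not
epoch-level.

## ROC calibration

For each wear site × metric × boundary, epochs are pooled across
participants (no clustering adjustment — matching the original analysis;
between-participant correlation therefore makes the DeLong intervals
anti-conservative, a known property of pooled designs) and dichotomized:
for the ST boundary the positives are ST epochs, for the MVPA boundary MVPA
epochs. Candidate thresholds are midpoints between consecutive sorted unique
values. Directionality is chosen so thresholds read the way published
cut-point tables do — an upper bound for ST (positive when value *below*
threshold) and a lower bound for MVPA (positive at or *above*); an epoch
exactly at a threshold is consequently not ST but is MVPA.

The AUC is the trapezoidal area under the sensitivity versus
1 − specificity curve, identical to the Mann–Whitney concordance with ties
counted one half. Confidence intervals use the DeLong structural-components
variance with a normal approximation, clipped to [0, 1]; `compare_auc()`
implements the paired (default) and unpaired DeLong tests. Accuracy grades:
AUC &ge; 0.90 excellent, 0.80–0.89 good, 0.70–0.79 fair, below 0.70 poor.

`select_cutpoint()` minimises the squared distance to the perfect corner,

$$d = (1 - \mathrm{Se})^2 + (1 - \mathrm{Sp})^2,$$

breaking ties toward higher specificity and then the smaller threshold
(specificity protects against counting light activity as the behaviour of
interest, which is the costlier error in this field). Reported thresholds
are rounded half-up to integers, as cut-point tables print them; the raw
midpoint is retained and is what `apply_cutpoints()` uses by default, so
reapplying a bundle to its own calibration sample reproduces the recorded
sensitivity and specificity exactly. `select_cutpoint_spec_priority()`
implements the alternative rule — maximise specificity subject to a
sensitivity floor (default 0.6).

## Cross-validation and epoch-scale conversion

`apply_cutpoints()` classifies an independent labelled epoch table with the
fixed thresholds, under the same direction convention, and reports the
confusion matrix, sensitivity, and specificity per combination. Wear sites
absent from the new sample (the dominant wrist, in the default
cross-validation arm) are skipped. `scale_cutpoint()` converts counts
thresholds across epoch lengths linearly (counts accumulate with time);
ENMO is an epoch *average* and is invariant, so rescaling it is refused
with an explanatory error.

## The synthetic-data generator

The generator emulates two study arms: a calibration protocol (14
activities, 80 Hz, hip + both wrists; lying 11 min, a 1.3-min usual-speed
walk, other bouts about 3–6 min) and a cross-validation protocol (9
activities, 60 Hz, hip + non-dominant wrist, 5-min bouts plus a 6-min brisk
walk).

**What comes from published values and what is configuration.** Per-site
ENMO means and SDs of the calibration activities follow the published
per-activity descriptive table for such a protocol. Per-activity MET means
are *configuration*: sources show MET distributions only graphically, so
defaults were chosen to span the published intensity range — lying 1.0,
sitting tasks 1.1–1.4, standing chores 1.8–2.8, walks 3.0–4.0. Quiet
standing is assigned a sedentary-range MET (1.3–1.4): an energy-expenditure
criterion classes low-energy standing as ST, a property discussed openly in
this literature. The cross-validation arm's acceleration targets are not
published at all and are configuration throughout, chosen by analogy
(reading ≈ writing, sweeping ≈ vacuuming) and on physical grounds (quiet
sitting barely moves the hip; bed-making moves hip and wrist). Participant
mass, height and resting VO2 are drawn from the two arms' published
descriptive statistics (resting VO2 3.0 ± 0.7 and 2.7 ± 0.7 mL/kg/min).

**Waveform model** (`simulate_raw_signal()`, `calibrate_amplitude()`). Each
bout has a fixed random orientation of the 1 g gravity vector. On top of
it:

* a **static norm bias** per recording (SD 2.5 mg, truncated at ±3.5 mg),
  emulating device calibration and posture error — it inflates ENMO but is
  invisible to the band-pass counts filter, which is exactly how quiet
  sedentary records show a few mg of ENMO yet zero counts;
* an along-gravity **sinusoid** at the activity's dominant movement
  frequency plus Gaussian jitter with SD twice the sinusoid amplitude,
  modulated by a slowly varying (~1 s) mean-one lognormal **envelope**
  (log-SD 0.75) that gives movement its burst structure;
* a **perpendicular** jitter component whose SD grows with amplitude and
  saturates at 0.15 g — body sway that generates counts while contributing
  to ENMO only at second order. This is what lets household activities
  cross the counts dead-band while their ENMO stays low;
* a white 1.5 mg sensor-noise floor, and clipping at the ±8 g dynamic
  range.

The sinusoid amplitude is found by monotone bisection on a closed-form
expectation of mean ENMO under this model (Gauss–Hermite integration over
the envelope), so calibration is deterministic and accurate to well within
the bout-to-bout realisation noise. A zero ENMO target produces a pure
rotated gravity signal. Between-participant variation enters as a normal
draw of each bout's ENMO target around the activity template (the published
SDs), truncated below at 0.3 mg.

**Breath model** (`simulate_breath_series()`). Breaths arrive with
exponential gaps clipped to 1.5–6 s, faster at higher intensity. Each
bout's steady-state VO2 is `mass × (resting_vo2 + (MET − 1) × 2.8)` mL/min
— the participant's own resting rate plus the activity's net cost — reached
through a first-order on-transient (τ = 25 s) from the previous bout's
level, with 5 % multiplicative noise. A configurable fraction of breaths
(default 2 %) becomes upward spikes 35–70 % above the local level, well
beyond the 2 SD screening threshold. Because analysis divides by the fixed
2.8 constant while participants' true resting rates vary around 3.0, the
generator reproduces the mild, realistic scale mismatch between measured
and nominal METs.

Ground-truth bout METs and intensity classes are stored in the annotation,
enabling parameter-recovery tests. All randomness flows through sub-seeds
derived from one master seed per run (participant × site × bout), so a
fixed seed gives byte-identical outputs; the packaged demo configuration
uses seed 1.

**What the generator does not emulate** — and hence what passing tests do
not establish about real data: posture (ST here is purely an
energy-expenditure criterion), non-wear and compliance, autocalibration
drift within a session, VO2 kinetics beyond a single exponential,
respiratory exchange ratio physiology (VCO2 is a fixed 0.85 ratio plus
noise), and the vendor counts scale. Cross-validation happens at 60 Hz
versus 80 Hz in calibration with no rate correction; rate effects on counts
matter mainly at intensities older adults rarely reach.

## Numerical choices

* Amplitude bisection: 60 halvings on [0, 6] g; targets below the noise
  floor return amplitude 0; targets unreachable within the dynamic range
  raise an error.
* The counts band-pass is applied zero-phase (`filtfilt`); each axis is
  demeaned and reflection-padded (8 s) first so the filter's slow step
  response cannot leak counts into a static signal's edges.
* Degenerate ROC inputs (all values identical) return AUC 0.5, flagged,
  with no threshold; zero DeLong variance collapses the interval to a
  point; comparing a curve with itself reports a difference of 0 with
  p = 1.
* Thresholds are reported rounded half *up* (plain `round()` would take a
  0.5-count midpoint to 0, which cannot act as an upper bound for a
  zero-inflated counts distribution).
* Second boundaries follow the signal's own grid from its first sample;
  epochs start at each bout's analysis-window start. No wall-clock
  alignment is imposed.

## Problem sizes

The default configuration runs the full study: 59 calibration and 19
cross-validation participants, every default activity and site, roughly
75 000 labelled epochs, completing in a few minutes on one core while
holding only one participant's raw signal in memory at a time. The unit
test suite exercises the same code paths on reduced protocols (six 90 s
bouts, a handful of participants); the DeLong calibration checks use 1000
simulated datasets of 100 positives and 100 negatives.

## Known limitations

Pooling epochs ignores within-participant correlation, so AUC confidence
intervals are narrower than a cluster-aware analysis would give (a
per-participant bootstrap is a natural extension). The counts
reconstruction is a published open surrogate, not the vendor algorithm.
Cut-points calibrated on synthetic data characterise the *pipeline*, not
older adults: the package's scientific claims are about correctness and
recoverability of the workflow, and real cut-points require real
recordings.
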