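---
title: "Quantifying respiratory modulation of sympathetic nerve activity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying respiratory modulation of sympathetic nerve activity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(respmsna)
library(dplyr)
```

## The measurement problem

Muscle sympathetic nerve activity (MSNA), recorded by microneurography
from a peripheral nerve and integrated into a neurogram of discrete
bursts, is not constant across the breath: burst probability is highest
in mid-to-late expiration and suppressed during inspiration and early
expiration. This respiratory gating couples to two haemodynamic rhythms
at the breathing frequency — respiratory sinus arrhythmia (RSA) in heart
rate and Traube–Hering (TH) waves in arterial pressure — and interacts
with beat-to-beat baroreflex control, in which a high diastolic pressure
suppresses the burst of the following cardiac cycle.

`respmsna` implements the full analysis chain for synchronized
ECG / arterial pressure / respiration / integrated-MSNA recordings, and a
synthetic-signal generator with known ground truth so that every stage of
the chain can be validated by parameter recovery rather than by eye.

## Pipeline overview

For one subject, `analyze_subject()` composes:

1. **Landmarks** — R waves (threshold + refractory detector, or
   pass-through annotations); respiratory troughs and peaks on a
   zero-phase low-pass-filtered trace (default cutoff 1 Hz), refined on
   the raw trace; inspiration is trough→peak, expiration peak→trough.
2. **Beat haemodynamics** — per cardiac cycle, the diastolic point is the
   pressure minimum in a window anchored at the R wave
   (`[r − 0.1 s, r + 0.4·RR]`; the waveform boundary is a convention, so
   both constants are configuration-exposed), SBP the maximum and MAP the
   waveform mean ("modulus") between adjacent diastolic points; HR is
   60/RR stamped at the first R wave of the pair.
3. **Neurogram** — baseline (channel median) subtracted, noise SD
   estimated robustly from the lower half of the sample distribution
   (bursts only contaminate the upper tail), the channel scaled so the
   tallest burst is 100%. Bursts are local maxima at least `snr_min`
   (default 3) noise SDs above baseline, assigned to the most recent R
   wave whose lag falls in the latency window (default 0.8–1.8 s,
   bracketing the peroneal conduction delay), at most one per cardiac
   cycle (tallest wins). The neurogram and burst times are then shifted
   backward by the subject's mean burst latency so bursts align with the
   cardiac cycle that generated them; R-wave times are never shifted.
4. **Respiratory phases** — each inspiratory and expiratory period is cut
   into five equal intervals. Two composite phases are assembled:
   *inspiration/postinspiration* (intervals 60–100% of inspiration +
   0–60% of expiration) and *mid-late expiration* (60–100% of expiration
   + 0–60% of the **following** breath's inspiration). Phase instances
   aligned with neurogram artifacts (samples above 150% of the tallest
   burst, or a user mask) are excluded whole. Burst incidence
   (bursts/100 HB), frequency (bursts/min) and area rates are computed
   per phase, plus signed absolute and percent change (negative percent
   change = inspiratory inhibition).
5. **Baroreflex** — each diastolic pressure is paired with burst
   occurrence, and with the mean shifted neurogram ±0.4 s around the R
   wave, of the *following* cycle; rows are pooled into 1-mmHg DBP bins
   and the spontaneous sympathetic baroreflex sensitivity (sBRS) is the
   slope of the count-weighted linear regression of occurrence
   probability (or mean area) on bin centre.
6. **Cyclic coupling** — per breath, RSA is the max−min of beat HR
   between adjacent end-expiration points (respiratory troughs), TH the
   max−min of beat MAP over the same window extended 1 s, and
   respiratory-modulated MSNA the integral of the raw unshifted neurogram
   over 1.5 inspiratory durations from breath start (V·s). The MSNA
   measure is correlated with TH amplitude at lags −1/0/+1 breaths.

`analyze_cohort()` maps this over a cohort and the statistics layer
provides the group-level tests: a Type-III split-plot mixed ANOVA
(phase within, group between, partial η² per effect), one-way
ANOVA / Welch / Kruskal–Wallis comparisons with Bonferroni-adjusted
pairwise follow-ups (mean-rank comparisons after Kruskal–Wallis),
χ²/Fisher proportion tests, and Spearman/Pearson correlations between
percent modulation and resting haemodynamics.

## The synthetic-data generator

`generate_subject()` emulates a 5–10 min semisupine resting recording.
Its design choices:

* **Respiration**: raised-cosine rise over `insp_fraction` of each breath
  and raised-cosine fall over the remainder, so troughs and peaks are
  smooth and unambiguous for landmark-recovery tests. Breath periods and
  amplitudes are drawn with configurable CVs.
* **Cardiac rhythm**: instantaneous heart rate is
  `hr_base + (rsa_amp/2)·m(t)` with `m(t) = −cos(2π·phase-in-breath)`,
  so heart rate and MAP peak mid-breath and bottom out at end-expiration;
  R times integrate this rate.
* **Pressure**: each beat rises diastole→systole as a raised cosine over
  0.3·RR, then decays linearly to the next diastole. Per-beat diastolic
  pressure carries the TH offset `(th_amp/2)·m(t − th_lag_s)` and
  systolic pressure is solved in closed form so the beat's waveform mean
  equals baseline MAP plus exactly that offset — the generated TH
  modulation of MAP is `th_amp` peak-to-peak by construction without a
  haemodynamic model.
* **MSNA**: per cardiac cycle, a burst occurs with probability
  `clip(p_phase + (baro_slope/100)·(DBP_prev − mean DBP), 0, 1)`, where
  `p_phase` depends on which composite phase window the R wave occupies
  (the same windows the analysis uses) and `DBP_prev` is the *previous*
  cycle's diastolic pressure. The one-cycle delay matches both the
  physiological conduction delay and how the sBRS analysis pairs each
  DBP with occurrence in the following cycle; gating on the same cycle's
  DBP would make the analysed slope collapse toward zero through the
  lag-1 autocorrelation of DBP (≈ cos(2π·RR/T), near zero at four beats
  per breath). Occurring bursts are raised-cosine pulses of width
  `burst_width_s` centred `burst_latency_s` after the R wave, plus
  Gaussian channel noise.
* One top-level seed spawns independent per-channel substreams, so
  records are bit-reproducible while channels stay independent.

Defaults emulate a healthy resting adult consistent with published
resting values: 60 bpm, 4.4-s breaths (≈13.6/min), 125/72 mmHg, RSA
6 bpm, TH 10 mmHg, burst probabilities 0.65 (expiratory window) / 0.35
(inspiratory window), baroreflex gain −5 %/mmHg, burst latency 1.3 s,
amplitude CV 0.25, noise 0.05 V (SNR 20). No published breath-to-breath
variability statistics were available, so period CV 0.1 and amplitude CV
0.15 are exposed defaults rather than calibrated values.

### What the generator does and does not emulate

The generator reproduces the *statistical* structure the analysis
assumes: pulse-synchronous bursts with fixed latency, phase-gated and
baroreflex-gated occurrence, RSA/TH modulation, breath variability,
additive noise. It does **not** emulate realistic ECG morphology (an
impulse train suffices for R detection), ectopic beats or arrhythmia,
movement artifacts, electrode drift, burst-amplitude respiratory
modulation, or closed-loop causality (in vivo, bursts *cause* part of
the TH wave; here TH is imposed and occurrence reacts to it). Passing
recovery tests therefore demonstrates correctness of the implementation
under the stated model, not robustness to every pathology of real
microneurography data.

An instructive consequence of the open-loop design: with the default
baroreflex gain, the TH-driven DBP oscillation is itself respiratory
phase-locked, and the DBP term partially counteracts the phase gating —
the *net* modulation observed in a default subject (≈ −30% change in
incidence) is smaller than `100·(p_insp − p_exp)/p_exp` (−46%). For this
reason the parameter-recovery tests isolate one pathway at a time:
percent-modulation recovery runs with `baro_slope = 0`, and baroreflex
gain recovery with equal phase probabilities. Both configurations are
otherwise at study conditions.

## Numerical choices and estimator bias

* **Max–min estimators and beat sampling.** RSA and TH are defined as
  max−min of *beat-sampled* series within a breath. A sinusoid of depth
  A sampled at ~4 beats/breath yields an expected max−min of only
  ≈ 0.84·A (for HR there is an additional RR-averaging attenuation of
  sinc(π·RR/T)). This is a property of the estimator, shared by any
  implementation of the same definition. The recovery tests therefore
  use 72 bpm with 5.5-s breaths — both well inside normal resting
  physiology — giving ≥6 beats per breath, where the combined bias is
  ≈ 7% (RSA) and ≈ 3% (TH), inside the 10% recovery tolerance. At the
  default 60 bpm / 4.4 s the same code recovers ≈ 84% of `rsa_amp`; users
  comparing RSA across groups with different heart or breathing rates
  should be aware of this differential attenuation (it affects the
  original measurement definition equally).
* **Half-open intervals.** Grid intervals and phase windows are
  `[start, end)`; an event exactly on a boundary belongs to the later
  interval. Detection-to-truth comparisons use a ±0.2 s matching window.
* **Shift handling.** Shifting is rounded to whole samples; the trailing
  region beyond the record is `NA` and excluded from integrals. Burst
  times are shifted by subtracting the neurogram's `shift_applied`, so
  bursts and neurogram always carry the same shift.
* **sBRS validity.** A fit requires ≥3 bins spanning ≥3 mmHg (the cited
  threshold-diagram method needs a pressure range; the exact bound is
  unstated and configuration-exposed). Bins with n = 1 are retained —
  the weighting already down-weights them — and an invalid fit is a
  flagged missing value, not an error, mirroring per-subject
  missingness in cohort tables.
* **Degenerate inputs.** Flat pressure, missing channels, all-noise
  neurograms, monotone respiration and empty burst sets raise stage
  errors that `analyze_subject()` converts to per-subject flags so a
  cohort run continues.

## Open design points and how they were resolved

* **Cross-breath phase composition.** Whether "0–60% of inspiration" in
  the mid-late-expiration phase belongs to the preceding or following
  breath is ambiguous in prose; the *following*-breath reading makes the
  two phases alternate contiguously through the record and preserves the
  continuity of the expiratory MSNA peak into early inspiration, so it is
  the default; `expiration_pairing = "same"` selects the other reading.
* **Burst area units.** "Total area/s" is implemented as the integral of
  the normalized neurogram over grid intervals divided by window
  duration (units: % of tallest burst), the convention consistent with
  reported "total area/s, %" tables; a constant 10% neurogram yields a
  total area/s of exactly 10%.
* **Respiratory-modulated MSNA units.** The per-breath MSNA measure used
  for TH coupling integrates the *raw* (volt-scale) unshifted neurogram,
  matching published V·s values; a normalized variant is available by
  passing a `neurogram` object.
* **End-expiration points** are identified with respiratory troughs
  (trough = end of expiration under the trough→peak inspiration
  convention).
* **Normality pre-checks** (test selection, Pearson vs Spearman) use
  Shapiro–Wilk at α = 0.05 per group; pairwise follow-ups are
  Bonferroni-adjusted; Kruskal–Wallis follow-ups compare mean ranks
  (Dunn-type z with tie correction).

## Problem sizes used in validation

The test suite validates: grid tiling and phase partition on >1,000
randomized breaths; the weighted regression against closed-form normal
equations on 1,000 random bin tables (tolerance 1e-10); percent
modulation −75% ± 5 over 20 seeds of 300-breath records (burst
probabilities 0.8/0.2) with the equal-probability null centred within
±2 points over 50 seeds of 200-breath records; RSA/TH within 10% and
latency within 20 ms noise-free; baroreflex gain −5 ± 1.5 %/mmHg over 20
seeds of 600-cycle records; burst detection sensitivity ≥0.95 / FDR
≤0.05 over 20 seeds at amplitude SNR 8; rejection rate 0.05 ± 0.02 under
500 label-permutation nulls; and a phase×group interaction detected in
≥80% of 100 three-group cohorts (n = 12/12/13, 120-s records) in which
one group's probability contrast is a quarter of the others'. Records in
the simulation studies are sampled at 100–125 Hz, which leaves all
timing tolerances at least two samples wide.

## A worked subject

```{r}
p <- subject_params(duration_s = 300, fs = 125, seed = 42)
sub <- generate_subject(p)
a <- analyze_subject(sub$record)
a$phase_metrics
a$change
tidy(a$sbrs)
```

```{r, fig.width = 7, fig.height = 5, eval = FALSE}
plot_record(sub$record, 60, 80)
plot_sbrs(a$sbrs)
```

## Limitations

Within-subject normalization to the tallest burst makes burst areas
within-subject quantities; they are not comparable across subjects or
electrodes. The pipeline does not handle ectopic beats, does not
calibrate pressure against cuff values, and offers no frequency-domain
variability analysis. Cohort statistics assume one row per subject;
repeated sessions are out of scope.
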