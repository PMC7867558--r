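---
title: "EEG-informed tailoring of tACS: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{EEG-informed tailoring of tACS: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tacstailor)
```

## The problem

Chronic-pain conditions such as fibromyalgia show a characteristic
*thalamo-cortical dysrhythmia*: resting-state EEG oscillations shifted
toward slow frequencies (theta excess over fronto-central and sensorimotor
cortex). Transcranial alternating current stimulation (tACS) can entrain
cortical oscillations at its stimulation frequency, which motivates
*tailored* stimulation: locate each patient's largest spectral deviation
from healthy controls and stimulate that scalp site at a frequency chosen
to pull activity back toward the physiological range.

`tacstailor` implements this workflow end to end: spectral analysis of
resting EEG, normative z-maps, stimulation-parameter selection, the
crossover outcome statistics used to evaluate such trials, and the
signed-rank power simulation — plus a synthetic-data module so the whole
pipeline is testable without clinical recordings.

## Spectral analysis

A recording is a channel-by-sample matrix (µV) on a 10/10 montage.
Processing follows the standard resting-state relative-power pipeline:

1. **Band-limiting and down-sampling** (`preprocess()`). The working rate
   is 500 Hz and the analysis band 1–30 Hz. All filters are zero-phase
   (forward–backward) Butterworth, so epochs keep their alignment. For
   native rates above 500 Hz a 4th-order 200 Hz anti-alias low-pass runs at
   the native rate before decimation; the band-limiting itself — an
   8th-order 30 Hz low-pass plus a 4th-order 1 Hz high-pass — runs at
   500 Hz. Two numerical facts drove this cascade: a single 8th-order
   1–30 Hz band-pass at 5 kHz has normalized cutoffs so small that its
   transfer-function coefficients are numerically unstable (filtering
   returns NaN), and a 4th-order low-pass alone leaves ~5% of 35 Hz power,
   too shallow to call the output band-limited. The cascade achieves a
   35 Hz/15 Hz PSD ratio of ~0.006, >48 dB rejection one octave outside
   each edge, ≥99% retention at 10 Hz and <10% droop up to 25 Hz. In-band
   droop between 25–30 Hz is shared by every realization of "band-pass
   filtered at 1–30 Hz" and cancels in patient-vs-control comparisons,
   since both groups pass through the identical pipeline.
2. **Common average reference** (`rereference_car()`): each sample's
   channel mean is subtracted; idempotent by construction.
3. **Epoching** (`segment_epochs()`): non-overlapping 2-s epochs of 1000
   samples; a trailing remainder is discarded.
4. **PSD** (`epoch_psd()`): the mean over epochs of the one-sided
   Hamming-windowed periodogram (Welch with zero overlap), normalized by
   the window's sum of squares so the PSD integral equals the
   window-corrected signal power. The grid spacing is 0.5 Hz.
5. **Relative power** (`relative_band_power()`): per channel, the PSD is
   summed over each band's closed interval and divided by the 1–30 Hz
   total, in percent. The bands delta 1–4, theta 4.5–7.5, alpha1 8–10,
   alpha2 10.5–12.5 and beta 13–30 Hz are closed at both ends; at 0.5 Hz
   resolution they partition the 59 analysis bins exactly (7/7/5/5/35), so
   an analytically flat spectrum splits as 11.86/11.86/8.47/8.47/59.32%.

The PSD is averaged across epochs *before* the relative-power division
(one division per channel), not the other way around; for stationary
signals the two orders agree to well within the tolerances used anywhere
in the package, and averaging first keeps the estimator a plain ratio of
mean powers.

## Normative z-maps and stimulation planning

`fit_normative()` computes the cell-wise (channel × band) mean and n−1 SD
of relative power across controls; `compute_zmap()` standardizes a subject
against it. The SD is the *between-subject* control SD — the comparison is
each participant versus the control population, not versus their own epoch
scatter. Significance is flagged at |z| ≥ 1.959964 (two-sided normal 5%).

`prevailing_rhythm()` selects the maximum positive significant z over all
cells — the "largest excess" reading of the targeting rule. Ties break
deterministically by band order (delta→beta) then montage order. If no
cell is significantly elevated, the result is an explicit "no target"
outcome and the plan degenerates to `mode = "none"` rather than an error.

`plan_stimulation()` applies the frequency rule: slow-band excess (delta,
theta, alpha1) → 30 Hz beta-tACS; fast-band excess (alpha2, beta) → 4 Hz
theta-tACS. The anode goes over the peak electrode and the cathode over
the ipsilateral mastoid (M1 left for odd-numbered labels, M2 right for
even). Midline anodes have no ipsilateral mastoid; the cathode is the
adjacent midline electrode (anterior neighbour in the Fpz–Fz–Cz–Pz–Oz
chain when available, else posterior), matching the midline electrode
pairs used in practice. Published tailoring tables occasionally list
two-site peaks; the automatic rule emits the single peak electrode and
accepts a manual cathode override instead of guessing a two-site
criterion. Amplitude is 1–2 mA. `synthesize_waveform()` renders either the
tACS sinusoid or the random-noise sham (50 ms phase-continuous segments
with amplitude ~ U(1, 2) mA and frequency ~ U(0, 100) Hz, bounded by
2 mA).

## Crossover statistics

Outcomes live in a long table (subject, sequence, timepoint T0/T1/T2/
T1′/T2′, condition, measure, value). The analysis pools arms by condition
— T1′ is the T1 of the condition delivered second — and runs, per
measure: T0 vs T1, T0 vs T2, T1 vs T2 within each condition, plus
tACS-vs-RNS at T1 and T2. All comparisons are complete-case paired
Wilcoxon signed-rank tests (`paired_wilcoxon()`):

* zero differences are dropped before ranking (Wilcoxon's original rule,
  which keeps the exact-enumeration oracle clean);
* p-values are exact (via the signed-rank null distribution) for up to 25
  tie-free differences, otherwise normal-approximate with average ranks,
  tie-corrected variance and continuity correction — integer-valued
  clinical scores guarantee ties, so the corrected path is the one the
  power simulation exercises;
* the location estimate is the Hodges–Lehmann median of Walsh averages
  with its signed-rank confidence interval, the standard interval coherent
  with the test.

No multiplicity correction is applied anywhere: these trials are
exploratory and report raw p-values, and the package mirrors that.
Period/sequence effects are deliberately not modelled (no mixed-effects
machinery); contrasts between conditions pool both sequence groups.

## Power simulation

`simulate_power()` draws n differences per replicate from a discrete
distribution and counts two-sided rejections at level α using *the same*
signed-rank implementation as the crossover analysis, so the estimate
reflects the tie-corrected test actually used. `exact_power()` enumerates
outcome multisets (multinomial weights) and sums the probability of the
rejection region — an independent oracle feasible up to |support|^n ≈ 1e7.

The motivating trial's empirical difference distribution was never
published; only its support (−1…6), its median (1.5) and the resulting
power (85% at the observed sample size, 10,000 simulations) are. The
shipped `example_vas_difference_distribution()` is therefore
*illustrative*: probabilities chosen once to satisfy those three published
constraints — P(X ≤ 1) = 0.5 exactly, so the midpoint convention gives
median 1.5 — and clearly documented as not being the study's data.
`distribution_median()` implements that midpoint convention, which is how
an integer-valued difference scale can have a half-integer median.

## The synthetic-data generator

`generate_recording()` synthesizes EEG in the frequency domain: an
amplitude spectrum proportional to 1/f^(γ/2) (γ = 1 by default) plus a
flat-top amplitude boost over each band's interval, each component with
independent uniform phases, inverse-transformed to a real signal. This
gives exact control of the expected PSD, which is what makes the spectral
module testable against analytic values. Band oscillations are
band-limited noise rather than pure sinusoids so that control cohorts
never produce the degenerate zero-SD normative cell.

Defaults emulate the acquisition conditions of the motivating study: a
32-channel 10/10 cap and 300 s of open-eyes rest (5 kHz native recordings
are supported by `preprocess()`; the generator's default is the 500 Hz
working rate, since everything downstream of preprocessing is identical).
The default band gains (delta 2, theta 2, alpha1 3, alpha2 2.5, beta 1 on
background amplitude 5) were fixed once to give a realistic adult
eyes-open relative-power profile — roughly 30/18/17/13/22% across the five
bands. Between-subject variability is log-normal on band amplitude with
CV 0.3 (positivity; no distribution is published), applied per band per
subject. An anomaly multiplies one band's amplitude at chosen electrodes;
planted-excess recovery is monotone in this gain. No volume conduction or
spatial mixing is modelled — the maps under study are per-electrode — and
no artifacts (blinks, ECG, EMG) are synthesized; the preprocessing hook is
where externally cleaned real data would enter.

`generate_patient()` additionally draws subject-level band gains from the
control distribution before applying the anomaly. At moderate anomaly
gains this realistic inter-individual variability can legitimately mask a
planted excess; the recovery guarantees quoted below therefore refer to
`generate_recording()` (population-mean gains plus anomaly), where the
anomaly is the only systematic deviation.

Outcome tables add Gaussian noise (SD 1 by default) to a measure baseline
before clamping to the score range — a pragmatic choice (no noise model is
published) that keeps the null calibration of the downstream tests exact
to within the discreteness of the signed-rank distribution.

## Problem sizes and numerical tolerances

The test-suite and acceptance computations run at deliberately scaled
sizes, chosen as the smallest at which each property is stable rather than
estimation-noise-dominated: 20 s recordings for qualitative spectral
checks, 40 s (20 epochs) for z-map recovery experiments — at 20–30 s the
epoch-sampling noise of a 21-control normative SD still pushes planted
z-scores below threshold in >5% of runs, while at 40 s recovery of a
gain-2 single-electrode excess is reliable — 21 controls as in the study,
100 recovery replicates, 10,000 power-simulation draws, and 2,000
null-calibration contrasts. Band-power normalization is asserted to 1e-9,
z-scores against independent recomputation to 1e-12, exact signed-rank
p-values against 2^n enumeration to 1e-12, and Monte-Carlo estimates to
3 binomial standard errors.

## Known limitations

* EDF support is a minimal 16-bit implementation (1-s records, physical
  scaling from the data range); recordings are zero-padded to whole
  seconds on write. CSV round-trips exactly.
* The in-band filter droop near the 30 Hz edge slightly compresses beta
  relative power in absolute terms (identically for patients and
  controls).
* The pipeline assumes pre-cleaned data; artifact removal by ICA is a
  visual, manual step and is represented only by the preprocessing hook.
* No electric-field modelling, no source localization, no closed-loop
  operation: parameter selection stops at the published montage rule.
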