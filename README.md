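# tacstailor

Individualized ("tailored") transcranial alternating current stimulation
(tACS) from resting-state EEG, with the trial statistics to evaluate it.

Chronic-pain syndromes such as fibromyalgia show a thalamo-cortical
dysrhythmia: resting EEG power shifted toward slow rhythms over
fronto-central and sensorimotor cortex. Tailored tACS counters it per
patient: find the scalp site and frequency band where the patient's
relative band power deviates most from healthy controls, then stimulate
that site at a frequency chosen to normalize the rhythm. `tacstailor`
implements the full analysis chain for researchers running or replicating
such protocols:

* **Spectral analysis** — zero-phase 1–30 Hz band-limiting, 500 Hz working
  rate, common average reference, non-overlapping 2-s epochs, averaged
  Hamming-windowed periodograms, and relative power (%) in delta
  (1–4 Hz), theta (4.5–7.5), alpha1 (8–10), alpha2 (10.5–12.5) and beta
  (13–30).
* **Normative z-maps** — per channel × band,
  `z = (subject − control mean) / control SD`, flagged at two-sided
  p < 0.05; the *prevailing rhythm* is the largest significant excess.
* **Stimulation planning** — slow-band excess (delta/theta/alpha1) →
  30 Hz beta-tACS; fast-band excess (alpha2/beta) → 4 Hz theta-tACS;
  anode on the peak electrode, cathode on the ipsilateral mastoid (or the
  adjacent midline electrode for midline sites); 1–2 mA; plus waveform
  synthesis for tACS and the random-noise (RNS) active sham.
* **Crossover statistics** — ROI band-power aggregation and complete-case
  paired Wilcoxon signed-rank contrasts (T0/T1/T2 within and between
  conditions) with exact small-sample p-values, tie-corrected normal
  approximation, and Hodges–Lehmann estimates with signed-rank confidence
  intervals. No multiplicity correction, by design.
* **Power simulation** — Monte-Carlo power of the signed-rank test on a
  discrete difference distribution, with an exact-enumeration oracle.
* **Synthetic data** — 1/f-background EEG with band-limited oscillations,
  planted spectral anomalies, control cohorts with log-normal
  between-subject variability, and crossover outcome tables with
  configurable effects, so everything above is testable without clinical
  recordings.

## Worked example

```r
library(tacstailor)

spec <- cohort_spec(duration_s = 40)                 # 32-ch, 500 Hz
controls <- generate_control_cohort(21, spec, seed = 301)
model <- fit_normative(lapply(controls, band_power))

# a patient with a planted theta excess over the left motor cortex
patient <- generate_recording(spec, anomaly_spec("theta", "C3", 2), seed = 778)
zmap <- compute_zmap(band_power(patient), model)
rhythm <- prevailing_rhythm(zmap)
plan <- plan_stimulation(rhythm)
print(rhythm)
print(plan)
```

```
<prevailing_rhythm> theta excess at C3 (z = 3.44)
<stimulation_plan> tACS at 30 Hz, anode C3, cathode M1, 1-2 mA (slow-excess)
```

The z-map flags the planted theta excess at C3 (z = 3.44, well past the
1.96 significance threshold); since theta is a slow band, the plan counters
it with 30 Hz beta-tACS, anode over C3 and cathode on the left mastoid.

```r
res <- crossover_analysis(generate_outcomes(
  outcome_spec(n_subjects = 14,
               effects = data.frame(measure = "VAS", condition = "tACS",
                                    timepoint = "T1", shift = -2)),
  seed = 7))
subset(res, contrast == "tACS: T0 vs T1",
       select = c(contrast, n_pairs, statistic, p, estimate, ci_low, ci_high))
```

```
        contrast n_pairs statistic            p estimate   ci_low  ci_high
1 tACS: T0 vs T1      14       105 0.0001220703 2.140256 1.622528 2.613516
```

A planted 2-point pain-scale reduction after tACS is recovered: the
baseline-minus-T1 Hodges–Lehmann estimate is ≈ 2.1 VAS points
(95% CI 1.6–2.6), p < 0.001 by the exact signed-rank test on 14 pairs.

```r
simulate_power(example_vas_difference_distribution(), n = 14,
               n_sims = 10000, seed = 1)
#> <power_result> power 0.811 (MC SE 0.0039), 8114/10000 rejections at alpha 0.05, n = 14
```

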