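Package: tacstailor
Title: EEG-Informed Tailoring of Transcranial Alternating Current Stimulation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A pipeline for individualizing transcranial alternating current
    stimulation (tACS) from resting-state EEG, as used in crossover trials for
    chronic-pain thalamo-cortical dysrhythmia. Computes per-channel relative
    band power spectra (delta, theta, alpha1, alpha2, beta) from multichannel
    recordings, builds normative z-statistic topographic maps against a
    healthy-control cohort, derives stimulation parameters (frequency, anode,
    cathode) from the prevailing-rhythm excess, aggregates band power over
    regions of interest, analyses crossover clinical outcomes with paired
    Wilcoxon signed-rank tests and Hodges-Lehmann intervals, and estimates
    signed-rank test power by Monte-Carlo simulation with an exact-enumeration
    oracle. A synthetic-data module generates control cohorts, patients with
    planted spectral anomalies, and crossover outcome tables so the whole
    pipeline is testable without access to clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
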