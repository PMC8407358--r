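Package: neoburst
Title: Cortical Burst Detection, Sleep-Cycle Periodicity and Outcome
    Statistics for Neonatal EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies bursts of fast oscillations (8-30 Hz) in multichannel
    neonatal EEG recorded after hypoxic-ischemic encephalopathy. Detects bursts
    per channel by sliding-window RMS thresholding, computes duration-normalised
    band power, characterises bursts with Morlet wavelet time-frequency maps
    relative to a pre-onset baseline, estimates the ultradian sleep-cycle
    periodicity of burst power, and links per-infant burst power to
    neurodevelopmental outcome scores via Pearson and partial Pearson
    correlations with bootstrap confidence intervals, ROC analysis, and a
    Fisher-z sample-size calculation. Includes a synthetic-data generator that
    plants ground-truth bursts, artifacts, sleep-cycle modulation and
    burst-power/outcome effects, so the whole pipeline is testable without
    patient data, plus a minimal European Data Format (EDF) reader and writer.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
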