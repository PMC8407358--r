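# neoburst

Quantitative EEG analysis for survivors of neonatal hypoxic-ischemic
encephalopathy (HIE). After therapeutic hypothermia, term infants are
monitored with multichannel cot-side EEG; bursts of fast oscillations
(8–30 Hz) in these recordings index cortical excitatory activity, and their
power carries prognostic information about later cognitive, motor and
language development. `neoburst` implements the full analysis chain for
clinical neurophysiologists and biomedical-signal researchers:

- **Burst detection** — per channel, the RMS amplitude of the 8–30 Hz
  band-passed signal over sliding 400-ms windows; a burst is a maximal run of
  windows above 1.5 × SD of the channel's RMS series lasting ≥ 0.5 s. Each
  burst is scored by its duration-normalised band power
  `P = (1/T) ∫ x_bp(t)² dt` (µV²).
- **Artifact handling** — samples where any channel exceeds 500 µV are
  masked (±0.5 s pad), never excised, so hour-scale timestamps survive.
- **Time–frequency characterisation** — Morlet wavelet maps over a
  log-spaced 0.2–40 Hz grid (3–135 cycles), in dB relative to the 11 s
  preceding burst onset.
- **Sleep-cycle periodicity** — burst power binned to a regular series; the
  dominant Fourier period < 3.5 h is the sleep-cycle estimate, flagged
  unreliable for recordings under 4.5 h; plus the per-channel correlation
  between burst power and time since the last burst.
- **Outcome statistics** — Pearson and partial Pearson correlations of
  per-channel burst power with Bayley-III scores (bootstrap 95% CIs,
  significance requires p < .05 *and* a CI excluding zero), ROC/AUC against
  abnormal outcome (composite < 85) with a sensitivity-first cutoff rule,
  and the Fisher-z sample-size formula
  `n = ⌈((z₁₋α/₂ + z_power)/atanh r)² + 3⌉`.
- **Synthetic data** — a generator that plants ground-truth bursts,
  artifacts, sleep-cycle modulation and burst-power→outcome effects, so
  every stage is testable without patient data. A minimal EDF reader/writer
  is included.

## Worked example

```r
library(neoburst)

cfg <- sim_config(duration = 600, seed = 42)     # 10 min, 9 channels, 250 Hz
rec <- mask_artifacts(simulate_recording(cfg))   # >500 uV criterion
rec
#> <eeg_recording> 9 channels x 150000 samples @ 250 Hz (600.0 s, 592.2 s clean)
#>   channels: F3, F4, C3, C4, Cz, T3, T4, O1, O2

ev <- burst_power(rec, detect_bursts(rms_series(bandpass_recording(rec, 8, 30))))
head(summarise_bursts(ev, clean_duration(rec)), 4)
#>   channel n_bursts median_duration_s rate_per_s median_power_uv2 mean_power_uv2
#> 1      F3       58               2.0 0.09793393         1486.548       1567.497
#> 2      F4       54               1.9 0.09117987         1422.913       1442.999
#> 3      C3       50               1.9 0.08442580         1507.332       1507.437
#> 4      C4       55               2.1 0.09286838         1520.988       1574.881
```

Bursts occur about every 11 s per channel with median durations around 2 s —
the regime reported for term neonates after hypothermia. On a synthetic
cohort with a planted burst-power effect on outcome (R² = 0.26, the effect
size the analysis was powered for):

```r
coh <- simulate_cohort(cfg, cohort_config(n_infants = 41, seed = 7))
res <- run_outcome_analysis(coh, channels = "C4", n_boot = 1000, seed = 7)
subset(res$correlations, channel == "C4" & outcome == "cognitive")
#>  channel   outcome adjusted          r            p     ci_low    ci_high  n significant
#>       C4 cognitive    FALSE -0.4972757 0.0009406829 -0.6897233 -0.2717716 41        TRUE
#>       C4 cognitive     TRUE -0.4705686 0.0021819766 -0.6971761 -0.2074144 41        TRUE
```

Higher right-central burst power predicts a lower cognitive composite
(r ≈ −0.50), and the association survives adjustment for the MRI injury
covariate — the pattern the statistical layer is designed to detect. The
design sample size for this effect is

```r
required_sample_size(0.26, power = 0.80, alpha = 0.05)
#> [1] 28
```

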