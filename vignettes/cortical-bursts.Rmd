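---
title: "Methods: cortical burst analysis for neonatal EEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cortical burst analysis for neonatal EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neoburst)
```

## The problem

Term infants who survive hypoxic-ischemic encephalopathy (HIE) and undergo
therapeutic hypothermia are monitored for days with 9-channel cot-side EEG
(F3, F4, C3, C4, Cz, T3, T4, O1, O2 at 250 Hz). The neonatal EEG at this age
is dominated by discrete bursts of fast oscillations (8–30 Hz) that reflect
excitatory input to developing cortex. Their magnitude, and its modulation
by the hour-scale sleep cycle, are candidate prognostic markers for later
neurodevelopment. `neoburst` implements the measurement chain — burst
detection, power quantification, time–frequency characterisation,
sleep-cycle estimation — and the statistical layer that relates per-infant
burst power to Bayley-III outcome scores.

Because clinical recordings of this kind cannot be redistributed, the
package ships a synthetic-data generator whose planted ground truth defines
what every stage must recover. All claims the test suite makes are claims
about this synthetic regime; what that does and does not imply about real
data is discussed at the end.

## Detection model

Each channel is band-passed to 8–30 Hz with a 4th-order Butterworth filter
applied forward and backward (`signal::filtfilt`), i.e. zero-phase, so burst
onsets are not delayed by filtering. The zero-phase 4th-order response
passes the band centre essentially unchanged and attenuates a 10-Hz tone by
about 2.6% — a deliberate trade-off for a short, well-behaved filter; tests
assert 1% fidelity at 15 Hz and 5% near the band edge.

The RMS amplitude is computed over sliding 400-ms windows at a 100-ms hop
(75% overlap). The hop is a free parameter: 100 ms resolves the 0.5-s
duration criterion to about one hop while keeping the series 10× smaller
than the raw signal. The per-channel detection threshold is

> threshold = 1.5 × SD of that channel's RMS values over the whole recording,

computed over artifact-free windows only. Note this is an *absolute*
threshold, not mean + 1.5 SD: in neonatal EEG the inter-burst background is
low-amplitude, so the RMS standard deviation is dominated by the bursts
themselves and the multiple sits between background and burst levels. Two
consequences are handled explicitly:

* a channel whose RMS has zero variance (constant signal) has nothing to
  threshold and returns no events;
* the threshold scales with any channel gain, so detection is exactly gain
  invariant while normalised power scales with gain².

A burst is a maximal run of windows *strictly* above threshold (ties end a
run) whose window span lasts ≥ 0.5 s. With 400-ms windows a one-window run
spans 0.4 s and is rejected; two windows (0.5 s) suffice. Runs containing or
adjacent to artifact-flagged windows are discarded rather than truncated.
Event boundaries are the first window's start and the last window's end;
when overlapping windows would make two adjacent events overlap in time, the
boundary is split at the midpoint, so events at a channel never overlap.
Events separated by a single sub-threshold window are *not* merged — no
merge rule is part of the detection definition. Raising the threshold
multiplier shrinks the supra-threshold set monotonically; note it can still
*split* one long event into two shorter ones, so event counts themselves are
not monotone in the multiplier.

Burst power is the mean squared band-passed amplitude over the event
(equivalently, band power integrated over the burst divided by its
duration), in µV²; a pure sinusoid of amplitude A scores A²/2. This
time-domain definition is used for all statistics; the wavelet path below is
used for characterisation, and the two agree within 5% on narrowband bursts
(a cross-checked property).

## Artifact handling

High-amplitude segments — any channel exceeding 500 µV — are masked with a
0.5-s pad on each side. Masking marks samples as excluded but keeps the time
axis: excising artifact sections would compress the recording and bias the
hour-scale spectral period estimate. The clinical criterion "without a
physiological voltage field" requires topographic judgement that amplitude
alone cannot replicate; the automated criterion is amplitude-only, and the
masked total is reported so its influence can be checked (see the
reliability diagnostics below).

## Time–frequency maps

Detected bursts are characterised by convolution with complex Morlet
wavelets on a 60-point log-spaced grid over 0.2–40 Hz, with cycles growing
from 3 at 0.2 Hz to 135 at 40 Hz. The cycles schedule is linear in
*frequency*: this keeps each wavelet's spectral bandwidth (≈ f/cycles)
comparable to the grid spacing across the band, so oscillations falling
between grid points still register at the nearest grid frequency. (A
schedule linear in log-frequency was considered and rejected: it makes
mid-band wavelets an order of magnitude narrower than the grid spacing, and
a 10-Hz tone becomes invisible to a grid whose nearest point is 10.4 Hz.)
Wavelets are gain-normalised so a tone of amplitude A at an analysis
frequency reads A² of squared magnitude.

Each burst's epoch (11 s before onset to 4 s after) is converted to dB and
baseline-corrected by subtracting, per frequency, the mean dB over the 11-s
pre-onset baseline; corrected maps are then averaged across bursts. Doing
the correction in the log domain (a geometric-mean baseline) makes every
burst's baseline rows average exactly 0 dB — a property the tests assert to
1e-6 — and makes the map exactly invariant to overall recording gain.
Bursts whose epoch leaves the recording or touches masked samples are
skipped with a warning, not zero-padded: padded edges would inject spurious
low-frequency power.

## Sleep-cycle periodicity

Burst power is binned into a regular series (mean normalised power of
bursts with onset in each bin; default 60-s bins, comfortably resolving
periods of 0.25 h and longer). Empty bins are linearly interpolated and
flagged. The series is mean-removed and transformed with a plain (untapered)
discrete Fourier transform; the highest-magnitude bin with period below
3.5 h — the physiological upper bound for a neonatal sleep cycle — and above
twice the bin width is the sleep-cycle estimate. Automating the peak as an
argmax keeps the procedure deterministic and testable. For recordings whose
artifact-free duration is under 4.5 h the estimate is flagged unreliable:
at such lengths the identified period is predicted almost entirely by
recording duration. `cycle_reliability_check()` reproduces that diagnostic
on any collection of recordings by correlating estimated period and
amplitude against duration and masked fraction.

"Time since last burst" is measured as the silent gap (onset minus the
previous burst's offset), the most direct reading of elapsed inter-burst
silence; onset-to-onset intervals are available as an option. The
per-channel Pearson correlation between burst power and the preceding gap,
averaged over channels, quantifies the phase coupling between burst
magnitude and burst sparsity that characterises sleep cycling.

## Outcome statistics

Associations between per-channel mean burst power and outcome scores use
Pearson correlations, and partial Pearson correlations adjusting for the
6-point ordinal MRI injury score treated as numeric (the closed-form
partial-r formula, verified against the residual method to 1e-10).
Confidence intervals are percentile bootstrap over 1000 paired (case)
resamples with a fixed seed; case resampling is used for the partial
correlation as well. A result is significant only when p < .05 *and* the
bootstrap CI excludes zero — a deliberate conjunction, so either criterion
can veto. No multiplicity correction is applied by default, keeping each
association at its nominal level; a Benjamini–Hochberg option exists.

ROC analysis treats *higher* power as predicting abnormal outcome
(composite < 85). The direction is fixed rather than auto-oriented:
auto-orientation would inflate AUC on null data. The AUC is the
Mann–Whitney rank statistic (hence invariant to monotone transforms), and
the reported cutoff attains maximal sensitivity first and, among ties,
maximal specificity — the highest threshold that still catches every
abnormal case.

The sample-size helper inverts the Fisher-z power calculation,
n = ⌈((z₁₋α/₂ + z_power)/atanh r)² + 3⌉; at R² = 0.26, 80% power, α = .05
it returns 28, and a simulation at that design point shows the pipeline's
own significance rule rejects at ≈ 0.80 (the conjunction with the bootstrap
CI is very slightly conservative relative to the t-test alone).

## The synthetic generator

`simulate_recording()` plants everything the pipeline must recover:

* **Background**: white Gaussian noise low-passed at 40 Hz, scaled to
  15 µV RMS per channel. Real neonatal background (tracé alternant
  morphology, state-dependent continuity) is not modelled; the background
  exists to give the detector something realistic to reject.
* **Bursts**: per channel, a renewal process — exponential gaps with a
  sinusoidally modulated hazard, plus dead time during each burst — so
  events never overlap and, with no modulation, gaps are exactly
  exponential with the configured mean (1 burst per 11.5 s). Durations are
  gamma-distributed (shape 8) around 1.7 s, floored at 0.6 s. Each burst is
  a 10-Hz carrier with raised-cosine 0.2-s on/off ramps (avoiding spectral
  splatter outside 8–30 Hz), default amplitude 75 µV — 5× background, a
  signal-to-noise chosen so detector recall/precision is a meaningful test,
  not a claim about clinical amplitudes.
* **Sleep cycle**: a sinusoid of period 1.7 h scales burst amplitude by
  (1 + d·sin) and the burst hazard by (1 − d·sin), default depth d = 0.5.
  Suppressing the hazard in the *high*-amplitude phase reproduces the
  clinical observation that more powerful bursts follow longer inter-burst
  intervals. The modulator's starting phase is drawn at random per
  recording (shared across channels, as sleep state is global): recordings
  begin at arbitrary points of the sleep cycle, and a fixed phase would
  bias sub-cycle recordings toward one half of it.
* **Artifacts**: ~2 events/h of 1–5 s, 800-µV slow waves on all channels,
  comfortably beyond the 500-µV criterion.
* **Cohorts**: each infant gets a latent power level z_p and an independent
  latent injury level z_m; outcomes are built as
  score = 100 + 15·(−√R²·z_p − √c·z_m + noise), so the power–outcome
  correlation is exactly −√R² (higher power, worse outcome) and the MRI
  covariate shares c of the outcome variance. Effect channels share z_p
  exactly; others draw independent power. The Bayley scale is treated as
  continuous with Gaussian noise.

Everything is reproducible bit-for-bit from the config seed, and every
planted burst and artifact interval is returned for sensitivity/precision
scoring.

## Problem sizes and numerical choices

The shipped tests run the detector-versus-oracle comparison on 60-s
signals, planted-burst recovery on a 30-min 9-channel recording, cycle
recovery on 8-h event streams (signal synthesis is skipped where only burst
times and powers matter — `simulate_burst_events()`), time–frequency checks
on 2–4 min single-channel recordings, and the statistical calibrations on
2000 (power), 1000 (type-I) and 500 (null AUC) replicates with 200
bootstrap resamples each; the full suite completes in well under a minute.
Degenerate inputs are defined, not left to chance: zero-variance RMS yields
no events; a constant power series yields an absent period flagged
unreliable; a zero-variance covariate falls back to the plain correlation
with a warning; a covariate collinear with a variable returns NA with a
warning; ties at the detection threshold end a run.

## Limitations

Passing on synthetic data shows the measurement chain is internally
consistent and recovers what it plants; it does not validate the clinical
constructs. The background model has no tracé alternant alternation, no
seizures, and a single sinusoidal sleep modulator instead of discrete
states; artifact topography ("no physiological field") is approximated by
amplitude alone; per-channel duration differences (occipital bursts run
longer in real data) are not modelled. Detected durations are quantised to
the window/hop grid and inflated by roughly one window length relative to
planted durations. The statistics layer takes the cohort table as given —
the clinical imputation of untestable infants is out of scope — and the
paper-level patient results are not reproducible without the original
recordings.
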