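---
title: "Measuring facial and vocal digital markers: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring facial and vocal digital markers: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`dbmarkers` implements a remote digital-phenotyping measurement pipeline for
psychiatric research: vocal acoustic markers extracted from short smartphone
speech recordings, a baseline-normalized facial expressivity composite
computed from framewise facial action-unit (AU) intensity tables, PANSS-based
clinical severity scores, and the statistics that relate the two — Pearson
correlation tables with Benjamini-Hochberg false-discovery-rate adjustment
and test–retest intraclass correlation. Because study recordings of patients
are never distributable, the package ships first-class synthetic generators
with exact ground truth, and every stage of the pipeline is validated
against them.

## The measurement model

### Vocal acoustics

Six markers are computed per recording, all after log-MMSE speech
enhancement and resampling to a fixed analysis rate of 16 kHz:

* **Vocal intensity** (dB): energy-weighted mean of framewise
  `20·log10(RMS / 2e-5)` over speech frames. The reference is the
  conventional hearing-threshold pressure expressed in sample-amplitude
  units; with uncalibrated smartphone microphones the scale is relative,
  which is all a correlational analysis requires.
* **Fundamental frequency mean and SD** (Hz): framewise F0 by
  window-normalized autocorrelation (Boersma-style). Frames are 3 periods
  of the lowest search frequency long (default band 75–500 Hz, so 40 ms),
  hopped every 10 ms, Hann-windowed; the frame autocorrelation is divided
  by the window's own autocorrelation, and the best peak in the lag band is
  refined by parabolic interpolation. A frame is voiced when the normalized
  peak height reaches 0.45 and its amplitude exceeds 3% of the global peak.
  Summary statistics use voiced frames only; the SD is the population SD.
* **Vocal jitter** (%): Praat-convention *local jitter*, the mean absolute
  difference of consecutive glottal periods over the mean period. Cycle
  marks are placed by normalized waveform cross-correlation: each next mark
  maximizes the correlation between a roughly one-period template around
  the current mark and the signal 0.75–1.4 periods ahead, with parabolic
  sub-sample refinement. Matching each cycle against the previous cycle's
  actual waveform cancels the systematic peak shifts that formant ringing
  would induce on plain peak-picking.
* **Harmonics-to-noise ratio** (dB): per voiced frame, the normalized
  autocorrelation peak height `r` at the F0 lag estimates the periodic
  fraction of frame power, giving `10·log10(r / (1 − r))`; the marker is
  the mean over voiced frames, with `r` clamped inside (0, 1) so a
  numerically perfect frame saturates near 70 dB rather than overflowing.
* **Speech prevalence** (%): percentage of analysis frames flagged as
  speech. A frame is speech when it is voiced *or* its energy exceeds the
  noise floor (10th percentile of framewise energy in dB) by 9 dB; the
  energy branch catches unvoiced speech sounds, the voicing branch keeps
  quiet voiced stretches.

Degenerate inputs never produce `NaN`: markers that cannot be computed are
*missing with a reason code* (`"unvoiced"`, `"silent"`, `"too few
periods"`, …) that propagates into the tidy output tables.

### Speech enhancement

All audio is first passed through a classical log-spectral-amplitude MMSE
estimator (20 ms Hann frames at 50% overlap). The noise power spectrum is
initialized from the first 0.3 s of the recording and adapted during frames
a spectral-likelihood test deems non-speech; the a-priori SNR follows the
decision-directed rule with smoothing 0.98; spectral gains are floored at
−25 dB and capped at 1, so a band can be attenuated but never amplified —
which also guarantees enhancement cannot increase the energy of a
pure-noise input. These are the standard literature parameters for this
estimator.

### Facial expressivity

AU tables arrive in the OpenFace CSV dialect: one row per video frame with
a detection `confidence`, a `success` flag and 17 continuous AU intensity
columns (`AU01_r` … `AU45_r`). The pipeline:

1. drops frames with `success = 0` or confidence below 0.80 (the boundary
   is inclusive — a frame at exactly 0.80 is kept — and the same filter is
   applied to baseline and response segments);
2. computes a per-AU baseline mean over the pre-stimulus segment declared
   in the manifest (default: the first 3 s of the assessment), flooring any
   baseline mean below 1e-3 to 1e-3 with a per-AU flag, so the subsequent
   division is always defined while remaining auditable;
3. divides every framewise AU intensity by its AU's baseline mean, making
   the measure robust to inter-individual differences and to baseline motor
   abnormality;
4. reports **facial expressivity** as the grand mean of all normalized
   intensities over all retained frames — identical for evoked and
   spontaneous task contexts.

By construction the baseline segment scored against its own profile gives
exactly 1, and scaling all response intensities by `k` scales the composite
by `k`.

### Clinical scores

A PANSS record is 30 items (P1–P7, N1–N7, G1–G16), each 1–7. Subscale
totals are plain sums; the negative-symptom reference is the **Marder
negative factor** — N1, N2, N3, N4, N6 plus motor retardation (G7) and
active social avoidance (G16) — following the standard five-factor
solution; the item set is configurable for alternative solutions. Because
participants are assumed clinically stable over the observation window,
the two visits' derived scores are averaged (single-visit records pass
through with a warning). Averaging derived scores is equivalent to
deriving scores from per-item averages, a property the test suite checks.

### Statistics

Per-assessment markers are averaged per participant × task context ×
marker over non-missing values before comparison with clinical scores
(pairwise deletion, with the per-cell `n` always reported). Correlations
are sample Pearson coefficients with two-sided p-values from the exact
t transform on `n − 2` degrees of freedom; multiplicity is handled by
Benjamini-Hochberg step-up adjustment. Test–retest reliability between the
two study weeks uses ICC(A,1) — two-way, absolute agreement, single
measure — computed from the standard ANOVA mean squares.

**Multiple-testing family.** The family is configurable; the default
(`per_context_scales`) adjusts all marker-vs-scale cells of one task
context's table together and reports marker–marker intercorrelations
unadjusted, matching the per-table presentation such studies use. Whether
intercorrelations belong in the family is genuinely ambiguous, so
`per_context_all` is available.

## The synthetic generators

`synth_voiced_audio()` builds a glottal pulse train shaped by two fixed
second-order resonators (500 Hz and 1500 Hz, bandwidths 100 and 150 Hz — a
schematic vowel), with

* per-period multiplicative perturbations **rescaled so the realized local
  jitter of the true pulse sequence equals the target exactly** (cycle
  differences are only taken within a voiced segment);
* white noise **scaled so the harmonic-to-noise power ratio over voiced
  samples equals the target exactly by construction**;
* voiced segments alternating with silence in 1.25 s cycles to reach the
  requested voiced fraction, with silence leading each cycle the way
  natural captures open with a quiet stretch;
* an optional linear F0 glide and per-period Gaussian F0 drift;
* pulses placed with sub-sample accuracy (energy split across neighboring
  samples) and all randomness drawn from one seeded stream, so the output
  is bit-reproducible.

Ground truth (true pulse times, periods, segment boundaries, realized
jitter and HNR) is returned alongside the waveform. What the generator does
*not* emulate: real vocal-tract dynamics, coarticulation, amplitude
modulation, room acoustics or device codecs — so passing recovery tests
demonstrates correctness of the measurement chain, not field robustness on
real speech.

`synth_au_table()` draws baseline frames around a per-AU mean and response
frames around `multiplier × baseline`, with a controllable fraction of
frames assigned sub-threshold confidence, so the pipeline estimate of the
multiplier (and of the dropout fraction) can be checked against truth.

`simulate_cohort()` draws a latent severity `z ~ N(0, 1)` per participant;
each marker's assessment value is `mu + loading·z + noise` and each PANSS
item discretizes `0.7·z + noise` onto 1–7 through fixed ordinal cut points
(placed so item scores concentrate in the lower half of the scale, as in
stable outpatient cohorts). Loadings are calibrated from the requested
participant-level marker–severity correlation:
`loading = sign(r)·(noise_sd/√n_assessments)·|r|/√(1 − r²)`. The design
mirrors a two-visit, three-assessments-per-context remote study (free
behavior on days 2/7/14; evoked facial and vocal tasks on days 1/7/14).
With `render = "files"` the cohort is materialized as WAV audio (vocal
contexts), AU tables (facial contexts), a PANSS CSV, a YAML manifest and a
`ground_truth.json`, i.e. exactly the inputs the pipeline consumes.

## Numerical choices worth knowing

* **Octave cost.** For a perfectly periodic frame the autocorrelation peaks
  at 2×, 3× the true period match the fundamental peak to within
  normalization noise, so candidates are ranked with a 0.05-per-octave
  penalty on longer lags before the winner is interpolated. This is a
  static stand-in for the octave-cost dynamic programming of full pitch
  trackers; it is adequate for enhanced single-speaker speech. A
  running-median de-spiking pass afterwards un-voices isolated octave
  jumps, which otherwise occur in frames straddling a voiced/silence
  boundary.
* **Cycle-mark stepping.** The step size is the median of the last few
  measured periods, clamped to 0.7–1.45 of the region's median-F0 period,
  so marking can never lock onto a sub- or super-harmonic.
* **Jitter under noise.** Additive noise perturbs cycle-mark placement, so
  measured local jitter is biased upward at moderate HNR (about +0.4
  points at an HNR of 15 dB with 1% programmed jitter). The recovery
  tolerances (±25% relative) hold on clean synthetic voices; round-trip
  tests on noisy mixtures use correspondingly wider bands.
* **Enhancement and HNR.** Markers are deliberately computed on the
  *enhanced* signal, so measured HNR on a noisy recording is higher than
  the injected mixture ratio; HNR recovery is therefore validated on the
  raw synthetic signal, and the pipeline test asserts only that
  enhancement raises measured HNR.
* **Resampling.** Everything is analyzed at 16 kHz; 44.1 kHz input is
  polyphase-resampled first. Note that broadband noise above 8 kHz is
  removed by resampling, so HNR of full-band noisy material is not
  comparable across native rates — the rate-invariance tests use clean
  voices.
* **Problem sizes.** The bundled checks use 3–4 s recordings, cohorts of
  20–500 participants at marker level, 100 null cohorts for calibration of
  the false-positive rate, and a 50-participant audio-rendered cohort for
  the end-to-end determinism check; these sizes give stable estimates while
  keeping a full run in the minutes range on one CPU.

## Pipeline behavior

`run_pipeline()` is manifest-driven. Validation checks the task-context
contract (evoked-vocal entries need audio, evoked-facial entries need an AU
table, free-behavior entries at least one of the two) and every referenced
path. Per-assessment failures — unreadable audio, malformed tables — are
logged and skipped because remotely captured data is routinely partially
corrupt; the run is fatal only when nothing usable remains. Outputs are
tidy CSVs (per-assessment markers, participant profiles, clinical scores,
one correlation table per context, an ICC report) plus a run log recording
the effective configuration; re-running on the same bundle is
byte-identical except for timestamps in the log. The command-line front
end in `inst/scripts/dbmarkers-cli.R` is a thin wrapper over these same
functions (`validate`, `extract`, `analyze`, `run`, `simulate`).

## Known limitations

* The pitch tracker has no dynamic-programming path search; heavily
  octave-ambiguous material (creaky voice, strong subharmonics) would need
  one.
* Local jitter is reported as a dimensionless percentage — the standard
  definition — even though study write-ups sometimes label jitter in hertz.
* No shimmer, formant or spectral-envelope features; no diarization or
  transcription: markers outside the six implemented ones are out of scope.
* The AU-table path consumes OpenFace-style output; the package does not
  estimate action units from video.
* Synthetic cohorts use a single-factor severity model; real symptom
  structure is multidimensional, so cohort tests validate statistical
  machinery, not clinical effect sizes.
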