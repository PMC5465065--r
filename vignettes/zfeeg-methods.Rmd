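---
title: "Methods: simulating and analysing multichannel zebrafish seizure EEG"
author: "zfeeg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing multichannel zebrafish seizure EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`zfeeg` packages the analysis chain for non-invasive, four-channel scalp EEG
of adult zebrafish in acute pentylenetetrazole (PTZ) seizure experiments:
a ground-truth-labelled synthetic EEG generator, signal I/O with the
acquisition band-pass, automated detection and classification of
epileptiform discharges, Morlet time-frequency analysis, onset-channel
localization, an equivalent-circuit model of the dry skin-electrode
interface, and per-animal/cohort statistics. Because raw recordings from
such experiments are rarely deposited, the synthetic generator is a
first-class, tested component: it encodes the statistical structure the
analysis assumes, so every downstream stage can be validated against known
ground truth.

# The experimental timeline

A session is 60 min: 10 min of control (pre-injection) recording, the
convulsant application, a 90 s stabilization window that is excluded from
all analysis (electrode and fluid artefacts immediately after oral
injection), and the remainder as the analysis window. `timeline_marks()`
encodes these boundaries and every stage respects them: baseline statistics
come only from the control window, and no detected or planted event may
start before the stabilization window ends.

# Synthetic EEG generator

## Baseline activity

Non-invasive adult-zebrafish scalp EEG baseline is quiet: under 20 uV
peak-to-peak, with spectral content below 40 Hz. The generator produces
1/f-weighted (pink) Gaussian noise in the frequency domain, softly
low-passed at 40 Hz (eighth-power roll-off), and rescales each channel so
the *median* 2-s sliding-window peak-to-peak amplitude is 15 uV — clearly
under the 20 uV ceiling while leaving headroom for window-to-window
variation. The rescaling is empirical (computed on the realized trace), so
the amplitude calibration holds exactly for every seed.

## Ictal discharge morphologies

Two patterns are synthesized, matching the two discharge types seen in this
seizure model:

* **theta** (5–7 Hz): a high-amplitude sinusoid with slow (0.2–0.5 Hz)
  amplitude modulation, the typical generalized-seizure pattern;
* **spike_wave** (2–3 Hz): a repeating cycle of a brief (40 ms) biphasic
  spike followed by a slow half-sine wave of opposite polarity filling the
  rest of the cycle — a generic spike-and-slow-wave morphology consistent
  with "polyphasic spike/wave complexes". Cycle amplitudes jitter by
  ±10%.

Both are cosine-tapered at the edges so discharges emerge from and return
to baseline. Per-event peak-to-peak amplitudes are drawn uniformly from
60–200 uV, well above baseline. Constructor preconditions reject dominant
frequencies outside the class band and amplitudes at or below the baseline
ceiling.

## Cohort structure and event statistics

`animal_profile()` carries the per-animal generative distributions. The
defaults are the printed summary statistics of the reference 17-animal PTZ
experiment this package models:

| quantity | male | female | model |
|---|---|---|---|
| events / session | 6.50 | 3.38 | Poisson truncated at ≥ 1 |
| event duration (s) | 79 | 88 | log-normal, CV 0.5 |
| latency to first event (s) | 269 | 462 | log-normal, CV 0.5 |
| onset channel (1/2/3/4) | .32/.39/.10/.19 | .32/.39/.24/.05 | categorical |

Notes on these choices:

* The truncated Poisson is the simplest count model matching a printed
  mean for animals that, by definition of "responder", have at least one
  event; `trunc_pois_lambda()` solves for the rate giving the exact mean.
* Durations and latencies are log-normal (non-negative, right-skewed, the
  standard first choice for such quantities). Only the means are reported
  in the source experiment; the coefficient of variation 0.5 is this
  package's choice, applied to both, consistent with the wide box plots
  such experiments show.
* Onset channels: 39% left telencephalon (channel 2) and 32% right
  telencephalon (channel 1) in both sexes; the posterior remainder is
  lateralized by sex (males 19% right posterior, females 24% left
  posterior), with the small leftover mass assigned to the remaining
  posterior channel. The anterior proportions are reported values; the
  posterior split of the remainder is a stated assumption.
* Event class: theta with probability 0.7, spike-wave otherwise — theta is
  described as the typical pattern of generalized seizures, spike-wave as
  the rarer, longer absence-like runs. No class mix is printed anywhere;
  this is a package choice.
* Spread: each event is focal with probability 0.3, otherwise generalizes
  to all four channels with per-channel onset delays uniform in 0.1–2.0 s.
  Both focal and generalized events occur in the source experiment; the
  delay range is a package choice (no propagation delays are printed).
* `se_prob` can force a >300 s (status-epilepticus-like) event. The
  presets leave it at 0: the reference experiment saw SE-like events in
  5/17 animals, but forcing that rate would be inconsistent with the
  printed ~80 s mean durations the duration distribution is calibrated
  to — a genuine tension in the source numbers. SE-like durations still
  arise from the log-normal tail, and the >300 s flagging rule is fully
  implemented regardless.

The first event is placed at the latency draw (re-drawn if it falls inside
the stabilization window, a ~2% truncation); remaining events are placed
uniformly later in the session, non-overlapping with a ≥5 s gap, with
bounded retries before an explicit generation error.

Two presets ship: `"ptz17"` (8 male / 9 female with 1 + 2 non-responders,
the full reference cohort) and `"ptz14"` (its 14 seizing animals, 7 + 7).
Everything is deterministic in `(config, seed)`; per-animal seeds are
derived from the cohort seed.

## What the generator does *not* emulate

No opercular-movement or handling artefacts, no anaesthesia-depth drift,
no electrode impedance drift, no inter-channel crosstalk, and no
biophysical forward model — discharges are planted additively on
independent per-channel noise. Detector performance on this clean synthetic
data is therefore an upper bound; the ≥0.95 sensitivity/precision shown in
the tests demonstrates correctness of the implementation, not expected
field performance on real recordings.

# Acquisition band-pass

The acquisition chain band-passes 0.1–55 Hz to exclude 60 Hz line noise.
`bandpass()` realizes this as a zero-phase Butterworth: the *squared*
analytic Butterworth magnitude (the amplitude response of a
forward–backward pass) is applied in the frequency domain. This is exactly
linear and zero-phase, has no startup transient, and costs one FFT
round-trip for two channels. The default order is 5 per edge: order 4 —
the conventional first choice — leaves 60 Hz attenuated by only ~19 dB
(zero-phase) with these band edges, short of the ≥20 dB the 60 Hz
rejection requirement implies, while order 5 gives ~21 dB with the
passband still flat within 1 dB at 10 Hz. Signals are zero-padded past the
high-pass settling time (10 / low_cut seconds) to suppress circular
wrap-around.

# Seizure detection

The detector automates the operational screening definition — high-voltage
repetitive discharges faster than 2.5 Hz:

1. **Baseline scale** — per-channel MAD over the control window only.
   A zero-variance control window is an error, not a silent zero threshold.
2. **Amplitude rule** — the local rectified peak envelope (sliding maximum
   of |x| over 0.25 s) must exceed `k` × MAD, `k = 4` by default. A
   sliding *maximum* rather than a moving average is used because
   spike-wave energy is concentrated in brief spikes; an averaged envelope
   under-weights them and misses low-amplitude spike-wave runs. `k` is a
   tunable, since the implicit threshold of a human screener is unknown.
3. **Repetition-rate rule** — peaks of |x| above threshold, counted in a
   2 s sliding window, must exceed 2.5 per second. A 2–3 Hz spike-wave
   complex passes because each cycle contributes several rectified peaks
   (spike phases plus wave); a 1 Hz spike train fails.
4. **Windowing** — samples before the end of the stabilization window are
   never candidates.
5. **Segmentation** — per-channel candidate runs separated by less than
   `merge_gap` (2 s default) merge; candidates overlapping in time across
   channels unify into one multichannel event that keeps each channel's own
   onset (a propagating discharge is one seizure). Events shorter than 5 s
   are discarded, matching the event-counting convention.
6. **Classification** — dominant frequency is the periodogram argmax over
   1–40 Hz on the onset channel; 4.5–7.5 Hz is theta, 1.5–3.5 Hz is
   spike-wave, anything else `other`. The half-band margins keep planted
   5 Hz or 3 Hz events from falling between classes through spectral
   leakage.
7. **Status epilepticus** — strictly longer than 300 s, independent of
   spread (focal SE-like events exist).

No explicit "polyphasic" morphology operator is applied; the
repetition-rate rule subsumes it, since no morphological criterion is
specified anywhere in the source description.

# Time-frequency analysis

`morlet_cwt()` implements the complex Morlet continuous wavelet transform
in the standard FFT formulation, with centre frequency `omega0 = 6` (the
usual admissibility-respecting choice) and scales labelled by their
equivalent Fourier frequencies. The default grid is 100 log-spaced
frequencies over 0.5–50 Hz, matching the plotted range of such analyses.
Power inside the cone of influence (within sqrt(2)·scale of an edge) is
zeroed. `global_wavelet_spectrum()` is the time-mean of power per
frequency. `onset_confirmation()` cross-checks localization independently
of the detector: per channel, band-limited power must first exceed 10× its
pre-event median; ties break to the lowest channel index and are flagged.

# Onset localization

The onset channel is the channel with the earliest per-channel onset
(ties → lowest index, flagged). The montage maps channels 1/2 to
right/left telencephalon and 3/4 to the left/right posterior brain. The
anatomical naming of the posterior pair is reported inconsistently in this
literature (midbrain in the montage description, cerebellum in the onset
statistics); the labels are configurable and default to neutral
"posterior left/right". "Generalized" requires involvement of all four
channels — the source contrasts generalized with focal without defining a
channel-count cut-off, so the strictest reading is used; three-channel
events are focal.

# Skin-electrode impedance model

The dry-electrode/skin interface is modelled as a series chain:
`R_s + (R_sub ∥ C_sub) + (R_ct ∥ CPE)` — series resistance, a subcutaneous
RC block (skull, epidermis, scales), and the electrode double layer as a
charge-transfer resistance in parallel with a constant phase element
`Z_CPE = 1/(Q (jω)^n)`, which captures the non-ideal capacitance of the
mucous skin surface. The series chain is the minimal realization of the
"subcutaneous block plus electrode block" description; the topology is a
declared design choice since only a block diagram is given in the source.

`fit_circuit()` minimizes residuals of `log10 |Z|` (log space balances the
MΩ-to-kΩ range across 1–50 Hz) with Levenberg–Marquardt on box-bounded
parameters (`R_s`, `R_ct`, `Q` in log10, `n` in [0, 1]). With only five
magnitude points — the bundled reference spectrum — the subcutaneous block
is dropped (`model = "reduced"`, 4 parameters) to stay identifiable; dense
spectra use the full model. Goodness of fit is a chi-square on relative
magnitude residuals assuming a 10% per-point coefficient of variation; the
statistic's definition is a package choice, as the source reports only a
p-value without defining its test.

# Cohort statistics

Per-animal metrics: event count (≥5 s, post-stabilization), count of
events > 2 min, mean duration, latency from injection to first event, and
an SE flag. Group comparisons use the classical pooled-variance two-sample
t-test (df = n1 + n2 − 2), matching the equal-variance df = 12 convention
for 7-vs-7 groups in this literature. Cohort summaries average seizing
animals only, with non-responders tallied separately — the source
experiment's stated convention. With the preset means, the pooled
event-weighted mean duration is ≈ (6.50·79 + 3.38·88)/(6.50 + 3.38) ≈ 82 s;
the separately printed 85 s overall mean is treated as a
sampling-level discrepancy, not a constraint.

# Numerical and reproducibility choices

* Default sampling rate 500 Hz (no rate is printed for the source
  hardware; 500 Hz covers the 0.1–55 Hz band with ample margin), minimum
  200 Hz. Cohort-scale validation experiments in the tests and the
  acceptance script run at 250 Hz — the signal content is below 40 Hz, so
  125 Hz Nyquist is ample — which keeps a 20-seed, 280-recording
  experiment in the minutes range.
* All randomness flows through per-call seeds; generators save and restore
  the caller's RNG state. Identical (arguments, seed) give
  bitwise-identical output, and derived child seeds keep per-animal
  reproducibility inside cohorts.
* FFT lengths are padded to 2/3/5-smooth sizes; two real channels share
  each complex FFT in noise synthesis and filtering.
* EDF export uses 16-bit encoding with a ±500 uV physical range;
  out-of-range samples are an error, never silent clipping. Quantization
  (~0.015 uV/bit) is the declared round-trip tolerance.
* Event placement retries are bounded (200); an infeasible configuration
  (total event time exceeding the session) raises a generation error.

# Known limitations

* The detector is threshold-based and tuned to clean synthetic data;
  artefact-laden real recordings would need artefact rejection beyond the
  band-pass.
* The equivalent-circuit topology and the goodness-of-fit definition are
  declared choices; with five magnitude points, `R_s` and the subcutaneous
  block are weakly identified, which is why the reduced model is the
  sparse-spectrum default.
* The latency truncation at the stabilization boundary biases planted mean
  latencies upward by ~1–2% for male-like profiles (more for very short
  sessions).
* Phase fitting of impedance spectra is supported but not validated
  against reference values (none are printed; phase appears only
  graphically in the source literature).
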