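---
title: "Methods: photometry and behaviour analysis for Pavlovian lever autoshaping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: photometry and behaviour analysis for Pavlovian lever autoshaping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pavphot)
```

# The problem

During Pavlovian lever autoshaping (PLA) a lever (CS+) predicts food
delivery, and rats split into *sign-trackers* (STs), who approach and press
the lever, and *goal-trackers/intermediates* (GT/INTs), who wait at the food
cup. Dual-channel fiber photometry with a fluorescent dopamine sensor
records a dopamine-sensitive channel (465 nm excitation) and an isosbestic
control channel (405 nm) whose fluorescence is dopamine-independent and
therefore captures photobleaching and motion. `pavphot` implements the full
analysis chain for such experiments — session design, behavioural phenotype
scoring, isosbestic correction, event-aligned z-scoring and its derived
metrics, and signal-inclusion QC — plus a simulator that generates both the
behaviour logs and the raw streams with known ground truth, so every stage
can be validated by parameter recovery rather than by eye.

# Session designs

Three session types are generated by the `schedules` functions, mirroring
the standard training sequence:

* **Magazine acclimation** (`magazine_schedules()`): 25 reward-only trials
  (two pellets 0.5 s apart) split over sessions of 7, 8 and 10 trials on a
  variable-interval (VI) 60 s (50–70 s) schedule.
* **PLA** (`pla_schedule()`): 25 CS+ and 25 CS− lever trials, 10 s cue, on
  VI 45 s (35–55 s). The analytic expected span is
  `n_trials * (cue_dur + vi_mean)` = 2750 s ≈ 46 min.
* **RPE probe** (`rpe_schedule()`): 48 CS+-lever trials split 24 *expected*
  (cue → reward), 12 *positive* (unsignalled reward in the inter-trial
  interval, ITI) and 12 *negative* (cue, reward omitted).

Two conventions are deliberate choices where the design was open. First,
"pseudorandom order" is implemented as a seeded shuffle with at most three
consecutive trials of the same type — a common autoshaping convention; the
cap is configurable, and when it is unsatisfiable (a single trial type) a
plain shuffle is used. Second, VI draws are uniform over the stated bounds,
the simplest distribution consistent with a mean of 45 s on 35–55 s.
Unsignalled rewards are placed uniformly inside the ITI at least 5 s from
any cue interval so that reward-aligned epochs never overlap cue epochs.

# The signal model and its correction

The simulator emits already-demodulated streams (carrier modulation and
lock-in demodulation happen in acquisition hardware and add nothing
testable):

$$\mathrm{sig}(t) = B(t)\,(1 + A(t))\,F_0\,(1 + T(t)) + \varepsilon_s,
\qquad
\mathrm{iso}(t) = B(t)\,(1 + A(t))\,F_{0,iso} + \varepsilon_i,$$

where \(B\) is a double-exponential bleaching curve (non-increasing by
construction), \(A\) a sparse train of Gaussian motion bumps shared
*multiplicatively* by both channels, and \(T\) the dopamine transient
train, present only in the signal channel. Transients are
difference-of-exponentials kernels, peak-normalised, with rise 0.1 s and
decay 0.6 s by default — sub-second off-kinetics in the range of
genetically encoded dopamine sensors. The decay default also keeps fast
reward responses essentially confined to the first two seconds
post-delivery, which is what makes "no negative RPE" configurations (dip
amplitude zero) genuinely null in the later analysis bins rather than
contaminated by the tail of the expected-reward response.

The correction exploits the shared multiplicative structure exactly as the
standard isosbestic regression does: smooth the isosbestic channel
(zero-phase 1 s moving average with reflected ends; `smooth_isosbestic()`),
regress the signal channel on it by ordinary least squares
(`fit_reference()`), and form
\(\Delta F/F = (\mathrm{sig} - \mathrm{fit})/\mathrm{fit}\)
(`compute_dff()`). With transients off and noise off this removes the
artifact *exactly* up to the smoothing bandwidth, which is the
identifiability property the tests verify: the corrected trace decorrelates
from the injected artifact (|r| < 0.1) while the raw 465 trace correlates
strongly with it. The 1 s window is wide enough to suppress channel noise
and narrow enough to pass the ≥ 2 s-wide motion structure it must capture.

Patch-cord disconnects are detected, not assumed: samples where **both**
channels fall below 5% of their session medians for at least 100 ms are
masked, and any trial whose analysis window overlaps a masked run is
excluded and logged (`detect_disconnects()`). The floor and duration are
package conventions (no standard exists), chosen to catch full dropouts
without ever clipping transients, and both are configurable.

# Simulator parameters and what they emulate

Defaults are phenotype- and day-conditioned to emulate acquisition:

| parameter | default | meaning |
|---|---|---|
| `cs_plus_onset` amplitude | day 1: 0.010; day 5 ST: 0.060, GT/INT: 0.030 ΔF/F | cue-evoked transient |
| `reward` amplitude | day 1: 0.050; day 5 ST: 0.020, GT/INT: 0.030 ΔF/F | delivery-evoked transient |
| `rpe_positive_bump` / `rpe_negative_dip` | 0.050 / −0.040 (GT/INT), 0 dip in ST | prediction-error components |
| `spontaneous` | 0.015 ΔF/F at 6 events/min | background dopamine release |
| `artifact_rate`, `artifact_amp`, `artifact_width` | 6/min, 0.25, 2 s | motion of a freely moving rat |
| `noise_sd` | 1.5 / 0.9 a.u. on \(F_0\) = 100 / 60 | photoreceiver noise (≈1.8% ΔF/F) |
| press/poke rates | ST day 5: 0.8 / 0.05 s⁻¹; GT day 5: 0.05 / 0.6 s⁻¹ | cue-directed behaviour |

The day-1 → day-5 interpolation encodes the US-to-CS transfer: reward
responses dominate on day 1 for everyone, and by day 5 the cue response
dominates in STs only. The positive bump and negative dip are modelled as
*delayed slow components* (rise 0.3 s, decay 1.5 s, onset 1.5 s after
delivery/omission), so that group divergence between expected, unsignalled
and omitted trials appears in the second 2-s bin after the event — the
window in which prediction-error contrasts are evaluated downstream. The
spontaneous-transient background is what gives per-trial metrics realistic
variance; without it, trial-to-trial variability would be photon-noise
only and group tests would be unrealistically powerful.

What the simulator does **not** emulate: spectral bleed-through and
autofluorescence, hemodynamic artifacts, sensor saturation, within-session
satiety drift, and any attempt to match the distributional detail of real
recordings. Passing recovery tests on these synthetic data therefore shows
the *pipeline* is correct under the stated generative assumptions, not
that those assumptions exhaust real data.

# Behaviour scoring

`score_trials()` counts lever presses and food-cup entries strictly within
each cue's `[onset, offset)` window; first-response latencies default to
the full 10 s cue duration when no response occurs (the maximum observable
value). The Pavlovian conditioned approach score (`pca_score()`) is the
mean of three components in \([-1, 1]\):

* response bias: \((\text{presses} - \text{pokes})/(\text{presses} + \text{pokes})\), session totals;
* probability difference: \(P(\text{press}) - P(\text{poke})\) across CS+ trials;
* latency score: \((\text{poke latency} - \text{press latency})/10\,\text{s}\), session means.

Components with undefined denominators (0/0) contribute zero — a neutral
response, not a missing one. Session-mean (not median) latencies are used;
this is configurable upstream of the score by editing the trial table.
`classify_tracking()` labels a rat ST when the mean of its day-4 and day-5
scores is ≥ 0.5, GT/INT otherwise — a closed boundary at exactly 0.5.
Pre-trial food-cup checking (`pretrial_check_rate()`) counts entry events
(not dwell time) in the 10 s before each trial's cue onset or unsignalled
delivery, grouped by the preceding trial's type.

# Event-aligned z-scores and derived metrics

`epoch_and_zscore()` cuts ΔF/F into windows (default −5 to +20 s) around
cue onset or reward delivery and z-scores each trial against its own
baseline (−5 to 0 s): this per-trial normalisation is what makes the
"2 z above baseline" criterion well-posed, and a session-wide
normalisation can be had by passing a wider baseline window. Omission
trials align to the scheduled (omitted) delivery time, i.e. lever
retraction; unsignalled deliveries use the 5 s preceding the drop as
baseline. Two degenerate cases are defined rather than left to chance: an
exactly constant segment maps to z ≡ 0 and is kept, while a zero-variance
baseline under a varying segment cannot be normalised and excludes the
trial with a logged reason.

AUC is the trapezoidal integral of z over a stated window, in z·s
(quadrature and units are package choices; mean-z-times-window would only
rescale). The session contrasts are

* Δ lever extension AUC = mean CS+ − mean CS− AUC over 0–2 s from onset,
* Δ cue period AUC — the same over the full 0–10 s cue,
* Δ cue-reward AUC = mean CS+ onset AUC − mean delivery AUC (2 s each),
  positive when the cue response dominates (US-to-CS transfer),

and the RPE readout is the per-trial mean z in three half-open 2-s bins
covering 0–6 s after delivery/omission. `score_signal_correlation()` is an
ordinary least-squares fit of a per-rat signal metric on per-rat PCA
scores, reporting \(R^2\) and the two-sided slope test.

# Inclusion QC

Two criteria gate a rat's signal, and both must pass
(`inclusion_decision()`):

1. **Peak amplitude** (`peak_inclusion()`): the trial-averaged z trace
   reaches ≥ 2 z (the one-sided p = 0.05 point of the baseline
   distribution) within 0 to +20 s of cue onset, on day 1 or day 5.
2. **Bootstrap consistency** (`bootstrap_trace_ci()`): a pointwise 95%
   percentile band from 1000 resamples of trials (with replacement) of the
   day-5 CS+ trial-mean trace stays above zero for at least 40 ms
   consecutively.

The percentile bootstrap was chosen over BCa as the simplest method
consistent with the construction; with trials z-scored against their own
baselines, "above baseline" is exactly `ci_low > 0`. Onset latency (the
first post-onset significant point; most robust responders fall within
70 ms) is reported but is not itself a gate, matching the two-criterion
inclusion rule. No multiple-comparison correction is applied across
timepoints — the band is descriptive, and the calibration tests document
the consequence: with 25 trials the pointwise one-sided exceedance on null
data runs near 3–4% rather than the nominal 2.5%, the familiar
small-sample anticonservatism of percentile intervals. Fewer than 5 trials
is an error, not a wide interval.

# Numerical conventions and problem sizes

All randomness is seeded: schedules, behaviour and photometry draws, and
bootstrap resampling each take explicit integer seeds, and equal
(input, seed) pairs reproduce results bit-exactly. Epoch extraction uses
nearest-sample indexing on the uniform grid (rates are validated to 1 ppm
against time spacing); AUC windows are closed, binning half-open. The test
and analysis scripts run the full 50-trial / 48-trial session designs at
50–100 Hz sampling and reserve 1 kHz for the onset-latency checks where
40–70 ms structure matters — at 4+ samples per kernel rise time the
sampling-rate validator refuses anything coarser. Property suites use 20
seeded replicates and report fractions, sized so the whole validation runs
on a laptop in minutes.

# Known limitations

* The isosbestic regression assumes strictly multiplicative shared
  structure; additive channel-specific contamination (e.g. room light)
  would violate it and is not modelled or corrected.
* Inclusion QC evaluates CS+ epochs of one reference session; rats whose
  signal emerges only under other alignments would be missed, a
  restriction inherited from the criteria themselves.
* The simulator's behaviour model is Poisson-within-window; it reproduces
  rates, probabilities and order statistics of latencies, but not serial
  dependence of responding within a cue.
* Serialisation uses plain CSV (plus JSON for QC reports); at 1 kHz a full
  session is ~50 MB of text, so long recordings are better regenerated
  from seeds than stored.
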