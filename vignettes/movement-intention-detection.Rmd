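---
title: "Detecting movement intention from EEG, EMG and inertial signals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting movement intention from EEG, EMG and inertial signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Patients with upper-limb tremor are candidates for closed-loop therapies in
which functional electrical stimulation (FES) is triggered the moment a
voluntary movement is being *prepared*, before it is executed.  The trigger
must come from physiological precursors of movement: the event-related
desynchronization (ERD) of the sensorimotor EEG rhythms, corticomuscular
coupling visible as EEG–EMG coherence, and — in patients with rest tremor —
a characteristic reorganization of the tremor itself just before movement
onset.  `tremorbci` implements this multimodal detection pipeline: it turns
each modality into a stream of candidate "intention" events, scores every
stream against the actually executed movements, and fuses the per-channel
scores to find the best predictor (or association of predictors) for a
given patient.

## The quality parameter

Every detector in the package is summarized by the same statistic.  Let
*p* be the fraction of detected events that fall inside the target span of
some movement (the true-positive or "probability of stimulation" side: if
FES fired at every event, *p* is the chance the stimulation was right),
and let *d* be the fraction of movements that received at least one true
positive (the coverage side).  The quality parameter is their geometric
mean, in percent:

$$\mathrm{QP} = 100\sqrt{p \cdot d}.$$

The geometric mean is deliberate: a detector cannot score well by being
trigger-happy (high *d*, low *p*) or mute (high *p* on one lucky event,
low *d*).  `qp_score()` implements the statistic; the raw product
`p * d` is available behind `combine = "product"` for comparison, since
both forms circulate in the field.

Target spans differ by modality, reflecting when each precursor is
expected:

* EEG ratio events: the 2-s pre-movement window `[start − 2000, start)`.
  Two seconds is the standard extent of cortical motor preparation.
  Events during execution count as false positives by default (the module
  predicts intention, not movement); `count_in_movement = TRUE` relaxes
  this.
* Corticomuscular coherence: the extended movement window plus the 2-s
  pre-window, `[extended_start − 2000, end)` — corticomuscular coupling
  persists into execution.
* Kinematic events: `[extended_start − 500, start)` — the early-warning
  margin just before mechanical onset.

## Movement ground truth

All scoring needs to know when movements actually happened.  The
magnetometer defines the basic movement window: the vector magnitude of
the baseline-subtracted triaxial signal is smoothed into a 50-ms envelope
and compared against `mean + k·SD` of the rest-segment magnitude
(`k = 3`).  Three design choices matter and are exposed as arguments:

* the envelope (50 ms moving average) prevents single noise samples from
  opening windows; threshold statistics still come from the *raw* rest
  magnitude, so the margin reflects the signal's own variability;
* windows closer than 500 ms merge (finger-to-nose repetitions are
  seconds apart), and merged windows shorter than 200 ms are discarded —
  a voluntary reaching movement lasts much longer than any noise excursion;
* the rest segment defaults to the first second of the recording, which
  in the deposited runs is a documented silent lead-in.

Accelerometer and gyroscope react before the magnetometer, so
`extend_windows()` scans up to 500 ms backwards from each onset and moves
`extended_start` to the earliest *sustained* (≥ 10 ms) deviation beyond
one rest-segment SD on any channel.  The run-length requirement keeps the
onset sample-accurate while making a single noise sample unable to extend
a window.  Whether the SD should be taken over a rest segment or the whole
run is ambiguous in the field; the rest segment was chosen as the variant
that stays meaningful when most of a run contains movement.

## The spectral engine

All spectrograms share one engine: a Hamming-windowed short-time Fourier
transform evaluated by the Goertzel recursion at exactly the requested
frequencies (integer Hz bins — 1–40 Hz for EEG, 1–20 Hz for the
gyroscope), with window 256 samples and overlap 250.  Goertzel rather than
an FFT because the analysis grid is a frequency *list*, not a power-of-two
grid; the recursion is exact (tested to 10⁻⁹ against a direct DFT).  Frames
are timestamped at their centers, a trailing partial frame is dropped, and
frames are not detrended (nothing in the pipeline requires it; the
band-pass conditioning already removes DC).  The one-sided PSD
normalization is

$$P(i,j) = \frac{2\,|S(i,j)|^2}{F_s \sum_{n=1}^{L} w(n)^2},$$

which integrates to the signal's mean square (checked on sinusoids to 5%).

The EEG ratiogram is, per frame,
$10\log_{10}\big[(\sum_{\beta} P)^n / \sum_{\alpha} P\big]$ with
`n ∈ {1, 2}`; band edges are inclusive on the integer grid.  Events are
supra-threshold peaks: a run of consecutive supra-threshold frames
collapses to its maximal frame, and a run already in progress at the first
frame is not counted (a peak requires an upward crossing — this also gives
the simulator's threshold sweep its correct behaviour at extreme
thresholds).  Note that under run-collapsing the event *count* is not
strictly monotone in the threshold: raising the threshold can split one
run into two peaks.  The default threshold rule is `mean + c·SD` of the
trace (`c = 1`), matching the simulator's sweep parameterization.

`band_pair_scan()` scans the full catalog of alpha sub-bands (8–12, 8–10,
10–12 Hz) against a nested split of 13–40 Hz.  The catalog is config-driven
and deduplicated; no fixed pair count is asserted, since the natural
factorization of the published list is ambiguous.

## Corticomuscular coherence

EMG is low-pass filtered at 30 Hz, both channels are cut into consecutive
non-overlapping 200-ms segments, and each segment pair yields a Welch
magnitude-squared coherence with 8-sample Hamming sub-windows, overlap 6,
zero-padded to an FFT length of 512:

$$C_{xy}(f) = \frac{|P_{xy}(f)|^2}{P_{xx}(f)\,P_{yy}(f)} \in [0, 1].$$

Two numerical choices: sub-windows are demeaned before tapering (an
8-sample window has an enormous spectral mainlobe, so a constant offset
would otherwise contaminate every bin — demeaning makes coherence exactly
invariant to affine rescaling of either channel), and the sub-window taper
is Hamming, consistent with the rest of the pipeline ("modified
periodogram" implies a taper but does not name one).  With so few
effective averages per 200-ms segment the estimator has a large positive
bias on independent signals; the suite pins that bias against a
brute-force oracle rather than pretending it away.  Non-overlapping
segments were chosen for the coherogram's time axis; the
`"probability of stimulation"` summarizes the 13–30 Hz band (the classic
corticomuscular beta band; configurable) and thresholds it at
`mean + 1·SD` of the band-mean trace.  A bare `1·SD` threshold (without
the mean) is scale-inconsistent for a nonnegative trace but is kept as an
option (`threshold_rule = "sd"`).

## Kinematic early detection

Rest tremor transiently reorganizes just before voluntary movement: the
tremor oscillation drops out for on the order of 200 ms, and low-frequency
power rises.  The detector follows the published rule exactly: from the
1–20 Hz gyroscope spectrogram compute, per frame, the band-power ratio
high/low (7–20 over 1–7 Hz, boundary bin in both) and the maximum PSD in
the low band; threshold each at its own standard deviation (two separate
SDs — the wording "the standard deviation of the ratio and the maxPSD"
reads most naturally as one per feature); flag a potential movement where
*both* exceed their thresholds, collapsing runs to their first frame.  The
published motivation (a *rise* of low frequencies) sits oddly beside a
high/low ratio that *falls* when low power rises; the conjunction is
implemented as printed and the tension is simply documented.  The 200-ms
tremor gap is treated as a validity check on the detector's input (the
suite verifies the tremor-band PSD collapses inside it) rather than as an
extra trigger, since the printed algorithm conditions only on the two
features.  The low band nominally starts at 0 Hz but is evaluated from
1 Hz, where the spectrogram grid starts.

## Fusion

`build_tree()` collects per-channel results into a deterministic
module/source hierarchy; `combine_predictors()` merges event streams by
union (default) or intersection, and `rank_tree()` orders everything by
QP with ties broken toward smaller predictor sets, then lexicographic
names.  Union is the default combination because it reproduces the
clinically observed failure mode: adding a noisy axis to a good one
dilutes precision and *lowers* the combined QP.  Intersection uses a
100-ms co-occurrence tolerance (about one order of magnitude above the
6-ms frame step).  One caveat found while testing: with a nonzero
tolerance the intersection keeps the *first* stream's event times, so an
event just outside a span can be validated by a partner event just inside
it — coverage monotonicity is exact only at zero tolerance.  Leaves carry
a `statistic` label (`qp` vs `stimulation_probability`) instead of forcing
the two quantities onto one scale.

## The artificial-EEG simulation

Whether a patient's ERD is strong enough for a BCI can be asked on
synthetic data: generate EEG with known desynchronizations and sweep the
detection threshold.  The generator follows the published recipe: at
250 Hz, each band (delta 0.5–4, theta 4–8, alpha 8–13, beta 13–40, gamma
36–44 Hz) is a sum of four unit-amplitude sinusoids with frequencies
uniform in the band and phases uniform in [0, 2π); segments of 8 s are
drawn independently (a phase reset at every boundary) and concatenated to
32 s; bands are superimposed.  Four desynchronization events, 2–4 s long,
non-overlapping, uniformly placed, multiply the alpha component by an
attenuation factor (default 0.2) with 100-ms cosine ramps —
multiplicative alpha attenuation is the standard ERD model, and it raises
the beta/alpha ratio as required.  Per-band amplitudes default to 1
(equal), the simplest reading of the recipe.

Per trial the composite is analyzed exactly like patient EEG (Goertzel
0.5–44 Hz, window 256, overlap 250) and both ratio traces are thresholded
at `mean + k·SD` for `k` from −10 to +10 in steps of 0.1 — 201 grid
points.  "Steps of 0.1" is read in SD units: a fixed dB step over an
SD-defined range would give a data-dependent grid size, inconsistent with
a fixed threshold axis.  True positives are peaks inside ERD intervals;
QP is aggregated across trials with SD and a normal-theory 95% CI.

The one genuinely open choice is the ratio band pair, which the published
description of the sweep does not name.  The package defaults to the
narrow reactive pair **beta 26–33 Hz over alpha 8–10 Hz** — the example
bands of the ratio definition itself — rather than the broad 13–40/8–13
pair, for a concrete reason: with the narrow pair the simple-ratio trace
operates around −7 dB and the squared trace around `mean + 1 SD ≈ +8` dB,
bracketing the documented example thresholds (−4.8 and 9.5 dB), whereas
the broad pair puts both traces in ranges inconsistent with those numbers.
Under the narrow defaults the trial-averaged QP curve plateaus in the
high-60s of percent, the regime the method is known for; under the broad
pair detection becomes nearly perfect (plateau above 90%), which no
reported operating point supports.  The plateau is estimated as the
maximum of the trial-averaged curve after a light 9-point (0.9 SD) moving
average: at small trial counts the raw maximum of 201 noisy grid points
is biased upward, and the smoothed estimate is what converges.  ERD depth
remains a free parameter; sensitivity is easy to explore
(`sim_config(erd_attenuation = ...)` with, say, 0.1/0.2/0.5) and the
plateau moves by only a few points across that range because the narrow
band pair, not the ERD depth, limits detectability.

## The synthetic multimodal fixture

`make_multimodal_fixture()` builds a full recording emulating one
finger-to-nose run: magnetometer plateaus over each movement epoch;
accelerometer bursts starting 300 ms pre-onset; a gyroscope rest tremor
(default 5 Hz) with the 200-ms pre-onset suppression gap, a combined
3 Hz + 12 Hz burst in the 500–200 ms pre-onset span (the low-frequency
rise plus the high-band component the conjunction rule needs), and a slow
voluntary-movement component during epochs; EEG with a 10 Hz alpha rhythm
attenuated ×0.2 during every 2-s pre-movement window, constant 22 Hz
beta, and a 20 Hz component on channel C3 shared with the first biceps
electrode during pre-windows; white noise everywhere at `1/snr`
(amplitude SNR, default 10).  Movements repeat every 5 s, onset `i` at
`5000·i` ms.

What the fixture does *not* emulate matters for interpreting green tests:
there is no 1/f background, no eye/muscle artifacts, no nonstationary
tremor amplitude, no inter-channel EEG correlation, and its event timing
is metronomic.  Passing tests demonstrate that the implementation recovers
exactly the structure it injects at realistic SNR — they do not
demonstrate clinical performance, which the original patient recordings
(only one of which is publicly deposited) would be needed to assess.

## Numerical choices and degenerate inputs

* Resampling is band-limited polyphase (`signal::resample`, half-length
  10), not sample repetition; empty series resample to empty series.
* Band-pass conditioning (0.5–60 Hz) is zero-phase forward–backward
  Butterworth (order-2 high-pass + order-4 low-pass cascade): zero phase
  preserves the event timing QP depends on, and the cascade stays
  numerically stable at a 0.001 normalized corner where a single
  order-8 bandpass is fragile.
* Zero alpha-band power makes a ratio frame `+Inf`; such frames are
  flagged and excluded from thresholds and peaks.  All-zero coherence
  segments yield flagged `NaN` columns.  Signals shorter than one window
  give zero-frame spectrograms, not errors.
* QP with zero movements is an error (undefined), with zero events it is
  0.  Per-pair failures inside `band_pair_scan()` become flagged rows,
  not aborts.
* All randomness flows through R's RNG: `set.seed()` (or the fixture's
  `seed` argument) makes trials, curves and fixtures bit-reproducible.

## Problem sizes in the test suite

The suite exercises the full simulation at its native size (2875 trials,
about three minutes) together with a 300-trial scaled-down replicate, the
coherence bias check at 10 000 segments, Goertzel–DFT equivalence on 1000
random signals, and fixtures of 10 movements at SNR 10 — sizes chosen so
the whole suite completes in a few minutes while every headline number is
computed at, or validated against, full scale.

## Known limitations

* The fixed sub-band catalog and SD-based thresholds are global per run;
  adaptive thresholds for nonstationary activity are future work.
* Coherence statistics use the first-listed stream's event times; see the
  intersection caveat above.
* The simulator reproduces the published generation recipe only; its
  plateau level depends on the (unreported) ERD depth and band pair, and
  the package documents its choices rather than claiming uniqueness.
* Nothing here is a clinical claim: the package quantifies detectability,
  on deposited-format data and on synthetic ground truth.
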