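---
title: "Detecting sleep apnea from abdominal IMU signals: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting sleep apnea from abdominal IMU signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(imuapnea)
```

## The problem and the signal

Obstructive and central sleep apnea are graded by the apnea-hypopnea
index (AHI): the hourly rate of ≥ 10-s episodes in which airflow stops
(apnea, > 90 % amplitude reduction) or is markedly reduced (hypopnea,
> 30 %). The diagnostic gold standard, polysomnography (PSG), is
laboratory-bound; most cases are never tested. An inertial measurement
unit (IMU) strapped over the lower abdomen sees breathing directly:
respiratory wall motion modulates tri-axial acceleration by roughly
10–30 mG and angular rate by 10–30 dps — an order of magnitude above
what wrist-worn devices see — making consumer phones and trackers
plausible screening sensors.

`imuapnea` turns a raw six-channel IMU recording into detected
respiratory events (REs), hourly indices, an estimated AHI, and a
severity grade, and provides the evaluation machinery to validate the
detector breath by breath against PSG-style annotations.

## The detection model

**Per-axis band-pass (0.13–0.7 Hz).** Respiration above 0.13 Hz (cycle
length < 7.7 s) passes; DC and slow drift, pulse waves (0.7–2.5 Hz),
gross body movements (2–4 Hz) and cardiac vibration (≥ 8 Hz) are
rejected. Critically, when breathing stops for longer than ~7.7 s there
is simply no in-band energy, so the filtered amplitude collapses during
any scorable apnea (≥ 10 s). Filtering is applied per axis *before* any
combination so the dominant-axis waveform (below) remains available.

**Respiratory amplitude.** $RA_t = \sqrt{X_t^2 + Y_t^2 + Z_t^2}$ over
the three filtered axes. As a norm it is invariant to any fixed rotation
of the sensor frame, so posture changes that merely rotate the
respiratory motion vector leave it untouched.

**Respiratory frequency.** Every 30 s the axis with the largest
excursion range (max − min) is selected; chosen segments are
concatenated with per-epoch polarity flips for phase continuity,
re-filtered with the same band-pass to clean the junctions, and cycle
lengths are measured between successive negative-to-positive zero
crossings. Each sample takes the reciprocal cycle length of the cycle
containing it (step interpolation); samples outside the first/last
crossing take the nearest cycle's value.

**Dual envelope criterion.** The fast (3-s) and slow (30-s) moving
95th-percentile envelopes of $RA_t$ track breath-by-breath amplitude and
baseline amplitude respectively. Samples where
$\mathrm{fast} < 0.7 \times \mathrm{slow}$ mark a > 30 % amplitude
reduction; maximal runs lasting 10–90 s become amplitude REs. Because
the criterion is a self-ratio, absolute gain, body habitus, nightclothes
and bedding drop out — multiplying $RA_t$ by any positive constant
changes nothing. Runs longer than 90 s are discarded outright: they
indicate signal loss, not an event.

**Frequency pathway.** Effortful obstructive apneas can preserve
amplitude on an abdominal sensor; breathing *frequency*, however,
contrasts between the event and the recovery breaths. $RF_t$ falling
> 30 % below its own 30-s upper envelope for 10–90 s is an RE, except
where the amplitude condition is already active — that suppression
prevents double counting of the same episode by both pathways.

**Indices, AHI and severity.** Event counts divided by monitoring time
(recording duration) give RAEI and RFEI per channel. A device-specific
linear model maps (RAEI\_acc, RFEI\_acc, RAEI\_gyro, RFEI\_gyro) to the
respiratory event index REI = max(0, linear predictor), an AHI estimate.
Severity uses lower-closed intervals: the AHI grid is 5/15/30; REI
cutoffs are per device (GPS tracker 5/17/30, Android phone 5/15/30,
iPhone 5/13/36).

## Tunable parameters

| parameter | default | unit | why |
|---|---|---|---|
| passband | 0.13–0.7 | Hz | breathing band; 0.13 Hz ⇒ 7.7-s cycle cap |
| FIR length | ≈ 8·fs/0.13, odd | taps | usable attenuation at the low edge |
| fast / slow window | 3 / 30 | s | breath-scale vs baseline-scale envelopes |
| envelope percentile | 95 | % | maximum would chase transient spikes |
| reduction factor | 0.7 | – | "> 30 % reduction" criterion |
| event duration | 10–90 | s | scoring minimum; signal-loss cap |
| dominant-axis epoch | 30 | s | posture-change timescale |
| minimum cycle | 1/0.7 ≈ 1.43 | s | shortest in-band cycle; ripple guard |

All detector thresholds live in one `detection_config()` object;
regression coefficients and cutoffs are data (`device_model`,
YAML-overridable), not code.

## Numerical choices

- **Zero-phase filtering.** The kernel is a symmetric (linear-phase)
  windowed-sinc band-pass, applied in a *single centred pass* with
  reflection padding. A symmetric kernel is already exactly zero-phase
  when centred; a forward-backward pass would square the magnitude
  response for no benefit. Taps are mean-subtracted so DC gain is
  exactly zero, then normalized to unit gain at the passband's geometric
  centre.
- **Moving percentile.** R's default quantile definition (type 7) over a
  centred window truncated at the boundaries, implemented in C++
  (`nth_element` per window) and verified sample-for-sample against a
  per-window `stats::quantile()` oracle. Centred (not trailing) windows
  keep event onsets aligned with the underlying physiology; the choice
  is deliberate and documented because either reading is defensible.
- **Junction polarity.** The natural rule — pick the sign minimizing the
  value jump at the epoch junction — proved fragile: when a junction
  lands near a zero crossing of the waveform, a continuing segment can
  be spuriously sign-flipped, manufacturing extra zero crossings, a
  short cycle, an inflated RF envelope, and false frequency events
  (about 2/h on an event-free simulated night). The implemented cost
  adds a slope-continuity term, weighted by $1/(2\pi f_c)$ with $f_c$
  the passband's geometric centre so value and slope contribute equal
  amplitude for an in-band sinusoid. With it, event-free nights yield
  zero false detections across seeds.
- **Zero crossings.** Located by linear interpolation between bracketing
  samples; crossings closer than the minimum in-band cycle length are
  merged into the following cycle, guarding against residual ripple.
- **Gaps.** Missing samples are flagged, never dropped; before filtering
  they are linearly bridged so window arithmetic stays on a uniform time
  base, and any event lying entirely within a bridged span (padded by
  the fast-window width, since condition masks smear slightly past the
  span) is discarded.
- **Degenerate inputs.** Recordings under 5 min are rejected (envelopes
  unstable); a waveform with fewer than two zero crossings raises "no
  respiratory cycles detected"; all-zero envelopes cannot fire the
  criterion (`0 < 0.7·0` is false).
- **Envelope adaptation bounds what a dropout can do.** With a 30-s slow
  window, a total signal dropout can keep the amplitude condition true
  only for ~15 s at each edge — the envelope adapts in between. The
  90-s discard rule therefore acts on slowly-evolving real signals, and
  prolonged flat loss degrades to short edge transients at worst; the
  tests pin both behaviours.

## The evaluation layer

Breath-by-breath concordance maps detected REs and reference
apnea/hypopnea annotations onto breaths delimited by respiratory nadir
points (half-open intervals). Matching allows a configurable breath gap
(default one breath) because annotation flags may sit anywhere between
event onset and termination; matching is **non-consuming** — one
reference breath may legitimize adjacent detections — which is the
simplest reading of a one-breath tolerance and the convention under
which sensitivity is provably non-decreasing in the gap. Macro-F1 over
the 4×4 severity confusion uses the zero-for-undefined convention for
empty classes; this is the convention under which all four verifiable
published per-device macro-F1 values are reproduced exactly (two
published test-split matrices are not reproducible from their printed
counts under any consistent convention — a typesetting ambiguity — and
are shipped flagged `verified = FALSE` and excluded from tests).
Bland-Altman limits use the 1.96-SD convention; AUC is trapezoidal over
the empirical ROC and equals the tie-corrected Mann-Whitney statistic
(tested against that independent oracle); the optimal cutoff maximizes
Youden's J, ties to the lower cutoff.

The shipped regression coefficients deserve a caveat: applying the
published per-device coefficients to the published cohort-mean indices
yields implausibly low predictions, suggesting a typesetting problem in
the source table. They are shipped verbatim as defaults because they are
the published operating points, but they are data, overridable by YAML,
and `fit_device_model()` refits them by ordinary least squares from any
labelled data set. No acceptance check depends on them.

## What the synthetic generator does and does not establish

The generator emulates the *stated* properties of abdominal IMU signals:
a quasi-sinusoidal carrier at 14 cycles/min with lognormal per-cycle
period jitter (CV 5 %) and slow ±20 % amplitude drift over minutes
(periods drawn from 4–7 min), amplitude 20 mG / 20 dps projected onto a
posture-dependent unit direction, scheduled apneas (depth ≥ 0.9),
hypopneas (depth 0.6) and frequency-only obstructive events (amplitude
preserved, rate reduced 45 %), raised-cosine 1.5-s event edges, and
out-of-band contaminants: a pulse tone near 1.1 Hz, sparse 2–4 Hz
movement bursts, a 9.2-Hz cardiac vibration tone, and white noise.
Defaults not fixed by the problem statement (noise amplitudes, drift
period, ramp length) were chosen once as physiologically plausible
values and are spec parameters, not tuning knobs.

A green end-to-end test therefore establishes that the pipeline recovers
events whose signal signature matches the stated model — clean
amplitude/frequency reductions against a stable breathing baseline. It
does **not** establish clinical performance: real recordings contain
arousal-related movement storms, sensor repositioning, non-stationary
breathing (e.g. Cheyne-Stokes crescendo patterns), partial-night
wakefulness, and device-specific transduction differences, none of which
the generator models. The published clinical correlations (r ≈ 0.84–0.96
against PSG AHI) require a clinical cohort and are deliberately *not*
claimed by any test here; the test suite instead pins (a) exact metric
arithmetic on the published validation tables, (b) brute-force oracle
equivalence for every algorithmic primitive, and (c) recovery,
false-alarm, posture-robustness and determinism properties on the
synthetic world (breath-level F1 ≥ 0.8 at one-breath gap on the
moderate scenario; ≤ 2 false events/h on an event-free night; posture
delta ≤ 0.1 in F1).

## Known limitations

- Monitoring time is recording time; no sleep/wake discrimination, so
  indices dilute if the recording brackets long wakefulness.
- No apnea subtype classification (obstructive vs central vs mixed).
- The frequency pathway depends on a coherent dominant-axis waveform;
  under sustained chaotic movement RF is undefined physiologically and
  the amplitude mask does most of the suppression work.
- Device models are linear and cohort-derived; transfer to other devices
  or populations requires refitting.
- Severity discrimination near the no-SA/mild boundary is weak even in
  the published data (two-thirds of no-SA subjects over-graded on the
  training split of the reference tables — recomputed by the acceptance
  script); the intended use is screening for moderate-to-severe disease.
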