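---
title: "Composite pulmonary vascular impedance: model, pipeline and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Composite pulmonary vascular impedance: model, pipeline and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pvztools)
```

## The physiological model

Pulmonary vascular impedance (PVZ) is the frequency-domain ratio of
pulmonary-artery pressure to flow. At harmonic 0 it is the familiar
resistance (mean pressure over mean flow); at higher harmonics it captures
the pulsatile load the right ventricle works against — arterial compliance,
proximal stiffness and wave reflection. A compliant pulmonary tree shows a
modulus that falls steeply from the resistance value toward a
high-frequency plateau (the characteristic impedance) and a negative phase
at low harmonics (flow leads pressure).

The package computes a *composite* spectrum: pressure comes from a
right-heart-catheterization screen capture, flow from an
echocardiographic Doppler capture acquired minutes earlier or later. The
two records never share a time base; what they share is the cardiac cycle.
Each capture's own ECG strip provides beat timing, each signal is reduced
to one average representative beat (ARB), and the impedance is formed by
pairing pressure and flow **by harmonic index** — harmonic k of pressure
over harmonic k of flow, regardless of the slightly different absolute
frequencies. This index pairing is exact when both hearts beat at the same
rate and degrades gracefully with rate mismatch, which is why
`check_hr_match()` warns (default tolerance 10% relative, configurable per
stage) but never aborts: asynchronous pairing is the method's premise, and
the investigator decides whether a flagged pair is usable.

## Pipeline stages and their tunable parameters

**Border detection.** All three trace kinds are single-valued functions of
time on clinical displays, so detection is a column-wise scan. Line traces
(pressure, ECG) use the intensity-weighted centroid of pixels at or above
the threshold — sub-pixel resolution, robust to stroke width. Doppler
envelopes use the outermost super-threshold pixel from the zero-velocity
baseline: an envelope is the maximum-velocity edge, not the brightest
(modal) velocity. We flag this as the one place where conventions in the
field genuinely differ; maximum-edge tracing reads slightly higher
velocities than modal tracing would. The detection threshold defaults to
0.5 normalized intensity (traces are drawn near-white on near-black;
gridlines render well below 0.5) and is overridable per capture in the
config. The envelope is median-smoothed over a fixed 5-column window with
symmetric shrinkage at the ends; an asymmetric end window would bias steep
systolic ramps by many pixels.

**Occlusions.** Cursors and annotations leave undetected columns. Interior
gaps are linearly interpolated between detected neighbours; leading and
trailing gaps are trimmed, never extrapolated — extrapolation would invent
data. A capture with more than 50% undetected columns in a region is
rejected outright.

**Calibration and resampling.** Two anchors per axis (pixel column to
seconds, pixel row to physical value) define affine maps; rows grow
downward, handled by a signed y-slope. No OCR of on-screen scales is
attempted: reading two anchors off the display is the explicit,
reviewable user step. Signals are resampled to a uniform 1000 Hz by linear
interpolation without a pre-filter: a clinical sweep packs well under 500
Hz of content into its pixel columns, and linear interpolation preserves
monotone bounds (no ringing).

**R peaks and beats.** The ECG is detrended by median subtraction;
candidate peaks are local maxima above 0.6 of the peak detrended
amplitude, accepted tallest-first under a 0.3 s refractory period (up to
200 bpm). The amplitude reference is the maximum rather than a high sample
quantile: R waves are narrow (tens of milliseconds per beat), so any
percentile of the sample distribution tracks the baseline, not the QRS. A
full filter-bank detector would be out of proportion for clean strips; a
config flag inverts negative-polarity leads. Beats run R-to-R; partial
first/last cycles are discarded; inclusion defaults to all beats with
explicit 0-based exclusion in the config, mirroring investigator-driven
beat selection in cardiac-output work.

**Averaging.** Beats are linearly time-normalized to the mean included R-R
length before point-wise averaging. Truncating to the shortest beat would
misalign diastole; normalization keeps systolic/diastolic phase roughly
aligned across beats of unequal length. Averaging n beats attenuates
uncorrelated noise by the square root of n — the test suite checks the
fourfold reduction at n = 16.

**Harmonics and impedance.** The ARB is decomposed by FFT with one-sided
normalization: harmonic 0 is the mean; for k >= 1 the complex amplitude is
(2/L) times the DFT coefficient, so its magnitude is the physical cosine
amplitude. The normalization cancels in the pressure/flow ratio but fixes
reported |P(k)|, |Q(k)| in the spectra table. Ten harmonics are computed by
default; the catheter-fidelity limit (3rd harmonic for fluid-filled
systems) is carried as metadata and plot shading, never silently
truncating output. Phase is pressure minus flow in degrees, wrapped to
(-180, 180]. A flow harmonic below 1e-12 of the larger of |Q(0)|, |Q(1)| is
treated as genuinely zero (symmetric synthetic flows do produce exact
nulls) and raises a degenerate-flow error rather than an astronomically
large modulus.

**Parameters.** TPR = PVZ(0); Zc = mean of PVZ moduli at harmonics 2-4;
Zs = PVZ(1) + PVZ(2). Zc averages *moduli*, the common convention; both
harmonic choices are overridable (`zc_range`, `zs_indices`) for
higher-fidelity pressure signals. Mean PA pressure is taken from the
re-digitized trace itself, not from a monitor-reported mean, keeping the
ratio internally consistent. Unit conversions: 1 mmHg·s/mL = 1333.22
dyn·s·cm^-5 = 16.67 Wood units.

**Cross-sectional area.** CSA = pi d^2 / 4 from the pulmonic-valve
diameter — the standard echo assumption of a circular PA cross-section and
a flat velocity profile. No Womersley profile correction is applied; that
(and wave-separation analysis) is out of scope.

## The synthetic truth model

Fixtures use a three-element Windkessel — characteristic resistance Rc in
series with parallel peripheral resistance Rp and compliance C — because
it is the simplest model whose input impedance

    Z(f) = Rc + Rp / (1 + i 2 pi f Rp C)

is non-flat in both modulus and phase, exercising every harmonic the
pipeline reports. Flow is a half-sine ejection pulse occupying 35% of the
cycle and carrying the full stroke volume (samples normalized so each
beat's integral is exact); pressure is synthesized per-harmonic in the
frequency domain, i.e. exactly, so no integrator error contaminates the
oracle. Beat-to-beat R-R jitter (3% default) emulates sinus variability;
the two captures of a stage are simulated independently to emulate
asynchronous acquisition, so their mean heart rates differ by realistic
fractions of a percent. Default physiologic ranges used by the randomized
tests: HR 50-110 bpm, SV 40-100 mL, Rc 0.02-0.08, Rp 0.2-1.2 mmHg·s/mL,
C 1-6 mL/mmHg.

A half-sine pulse has exact spectral nulls where the harmonic index times
the ejection fraction hits 1.5, 2.5, ...; with the default 35% ejection
fraction harmonic 10 is such a null. The degenerate-flow guard exists
precisely for these synthetic symmetries; digitized real (or rendered)
signals never produce exact nulls.

**Rendering.** Captures are drawn as a waveform panel over an ECG strip on
a dark background with dim gridlines. Line traces are anti-aliased across
the two pixels straddling the true path, so the centroid detector can
recover the path to sub-pixel accuracy; a dim vertical connector keeps
steep traces visually continuous without entering the detection mask. The
Doppler spectrogram is a filled band from the baseline to the envelope,
with seeded speckle: in-band pepper dropouts below the drawn envelope
boundary, and salt within a 1-pixel margin outside it, emulating spectral
broadening at the edge. The sweep resolution defaults to 250 px/s — a
full-HD capture of a 6-8 s sweep — which keeps the envelope's per-column
curvature small enough that the 5-column median suppresses speckle without
blunting systolic peaks. All stochastic steps take explicit seeds;
identical seeds give byte-identical images.

**What the fixtures do not emulate**, and hence what passing tests do not
demonstrate about real data: true ultrasound speckle statistics and
spectral-broadening physics, respiratory modulation of velocities and
pressures, arrhythmia beyond mild R-R jitter, catheter ringing and damping
artifacts in the pressure trace, and compression artifacts of hospital
screen-capture exports. The round-trip accuracy numbers are therefore a
floor for clean captures, not a clinical validation.

## Numerical choices and degenerate inputs

- Problem sizes in the shipped tests: 6-8 s captures (roughly 6-14 beats),
  1000 Hz resampling, 10 harmonics, 20-50 seeds per stochastic property —
  sizes at which every property is measurable with comfortable margins.
- Detection needs at least 50% of columns and, after trimming, at least 2;
  beats need at least 2 R peaks and one complete R-R cycle inside the
  signal span; decomposition needs L >= 2N + 1 samples for N harmonics.
- Ties in the R-peak greedy acceptance resolve by sample order (earlier
  peak wins at equal height); peak times are reported at sample resolution.
- `select_beats` copies; the original beat set is never mutated.
- The pipeline is deterministic end to end — identical config and images
  yield byte-identical CSV/JSON exports; only fixture generation consumes
  randomness, always through explicit seeds.
- Errors are classed conditions (`pvz_input_error`, `pvz_detection_error`,
  `pvz_config_error`, ...) and stage orchestration re-signals them prefixed
  with the stage label and capture kind, so a three-stage batch failure
  names its culprit.

## Open design points

One pressure plus one Doppler capture per stage is deliberate: pairing is
explicit in the config and auditable. Clinical workflows that average
several accepted captures per stage (as cardiac-output software does) are
an extension point — averaging spectra versus averaging parameters is a
genuine methodological fork we did not resolve; the per-stage artifacts
expose everything needed to do either downstream. Ectopic-beat rejection
is manual (exclusion lists) by design; automatic arrhythmia screening is
out of scope.
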