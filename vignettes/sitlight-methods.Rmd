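---
title: "From seat vibrations to ambient light: the sitlight processing model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From seat vibrations to ambient light: the sitlight processing model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sitlight)
```

sitlight is the offline computational core of a sensor-augmented office
chair for workplace health promotion. A film pressure sensor in the seat pan
picks up the ballistocardiogram (BCG) — the recoil of the body at each
heartbeat — while six force-sensing resistors (FSRs, three per side) measure
the sitting pressure distribution. From these two streams the system derives
a continuous stress proxy (heart-rate variability, HRV), the accumulated
continuous sitting time, and the current posture, and renders all of them
onto a 28-LED ambient light strip under the monitor. This vignette explains
each processing stage, the tunable parameters, the numerical choices, and
what the synthetic-data generators do and do not establish.

## 1. BCG to inter-beat intervals

The pipeline (`process_bcg()`) is a fixed four-stage composition.

**Wavelet detail denoising.** The raw signal is a sum of per-beat
oscillatory bursts (≈10–20 Hz), low-frequency respiratory drift (≈0.2–0.4
Hz) and broadband noise. We keep only the level-4 Haar (db1) detail band,
which at the default `fs = 256` Hz spans roughly 8–16 Hz and so isolates the
heartbeat bursts. Two transforms are implemented:

* `method = "swt"` (default): the undecimated (à trous / stationary) Haar
  decomposition. Its level-*j* detail is the difference of two centred box
  means, $d_j = \mathrm{box}_{2^{j-1}}(x) - \mathrm{box}_{2^j}(x)$, a
  shift-invariant FIR band-pass. The decomposition is exactly additive:
  the four details plus the 16-sample smooth reconstitute the signal to
  machine precision.
* `method = "dwt"`: the classical decimated orthogonal transform (zero all
  other coefficients, invert, trim).

The undecimated variant is the default for a measured reason: the decimated
transform is shift-variant, so the shape of a reconstructed burst depends on
where the beat falls relative to the 16-sample block grid. In controlled
noise-free experiments this alone moved detected beat times by 20–130 ms
depending on heart rate — an order of magnitude more than the interval
accuracy the rest of the system is built to deliver. The shift-invariant
detail removes that artefact while keeping the identical frequency band;
the decimated variant remains available and tested.

**Envelope extraction.** `moving_mad()` computes, per sample, the mean
absolute deviation of the signal from its own mean over a centred window,
with truncated (not padded) windows at the edges. Quiet stretches map to
≈0 and each burst becomes a smooth nonnegative hump. The window default is
100 ms. It must be shorter than the ≈150 ms beat complex: a window that
covers the whole complex produces a flat-topped envelope — every window
position containing the full burst scores the same — and the peak position
becomes undefined to within ±75 ms. At the same time it should cover at
least one full cycle of the ≈15 Hz oscillation (67 ms) so the deviation
estimate is stable. 100 ms ≈ 1.5 cycles satisfies both.

**Beat detection.** `detect_beats()` implements the moving-maximum rule: a
sample is a beat iff it is the most significant peak of *every* 400 ms
window containing it, i.e. it dominates its ±(window − 1 sample)
neighbourhood. Ties break toward the earliest sample (strictly greater than
everything earlier, at least as large as everything later), and a one-window
refractory gap is enforced explicitly even though the dominance criterion
already implies it. A flat or all-zero envelope yields no beats. The
implementation is checked for exact agreement against an independent oracle
that enumerates every window.

**Intervals and the validity gate.** Successive beat differences (ms)
become inter-beat intervals (IBIs). An interval is *valid* when it lies in
300–1500 ms (heart rates 40–200 bpm) **and** within ±30% of the previous
valid interval, which rejects both missed beats (double-length intervals)
and double detections. The first in-range interval anchors the jump test.

## 2. The recursive HRV estimator

Per valid interval the running pair is updated as

$$\mathrm{HRV}_{40}' = \frac{39\,\mathrm{HRV}_{40} + |\,\mathrm{IBI} - \mathrm{IBI}_{40}\,|}{40},
\qquad
\mathrm{IBI}_{40}' = \frac{39\,\mathrm{IBI}_{40} + \mathrm{IBI}}{40},$$

with the deviation update applied first, i.e. using the pre-update running
mean (the alternative order is a one-line change and documented as such).
The recursion is an exponentially weighted mean absolute deviation with a
≈40-beat memory, not a literal windowed SDNN; on i.i.d. normal intervals its
steady state converges to $\sigma\sqrt{2/\pi}$, which the tests verify. The
first valid interval seeds $\mathrm{IBI}_{40}$ with $\mathrm{HRV}_{40}=0$,
and the state is flagged warm-up until 40 valid intervals have been
consumed; downstream consumers (the breathing detector in particular) ignore
warm-up values because the seed-to-steady-state climb would mimic a genuine
HRV rise.

The classical SDNN (population standard deviation of valid intervals,
`sdnn()`) is used only for per-user calibration: one minute of relaxed slow
breathing gives the user's maximal HRV, the minute following physical
exercise the minimal one. An inverted range is a calibration-failed error
rather than silently swapped, since it indicates an unusable protocol run.

## 3. Posture classification

A three-layer feedforward network maps one six-channel pressure frame to
posture-class probabilities: inputs are normalised per channel by stored
calibration maxima (adapting the network to a user's weight and
weight-shift range), the hidden layer uses logistic sigmoids, the output is
a softmax. The published description of the network omits biases and
activation functions; we include biases in both layers, which is the
standard trainable topology.

Training (`train_lm()`) minimises the sum of squared errors against one-hot
targets with Levenberg–Marquardt: each step solves
$(J^\top J + \lambda\,\mathrm{diag}(J^\top J))\,\delta = -J^\top r$ on the
full residual Jacobian, with $\lambda$ starting at $10^{-3}$, ÷10 after an
accepted step, ×10 after a rejected one, stopping at a relative loss change
below $10^{-8}$ or 200 accepted iterations. The accepted-step loss trace is
stored and non-increasing by construction. Weights initialise uniform
(−0.5, 0.5) from a seed; because the objective is non-convex and a single
start occasionally stalls in a local minimum, training uses up to three
seeded restarts and keeps the lowest-loss fit, skipping later restarts once
the residual is below 0.05 SSE per sample. With identity activations the
network is linear and LM converges to the ordinary least-squares solution,
which the tests exploit as a closed-form cross-check.

The seven posture archetypes (upright, lean left/right/forward, slouch
back, edge sit, empty) are a package design choice — the class taxonomy of
the original system is not published. Channels f1–f3 are the left triplet
(front/mid/rear), f4–f6 the right. Occupancy is a simple total-pressure
threshold (default 72 units ≈ 20% of an upright sitter's total), and the
sedentary clock accumulates continuous sitting, pausing on brief stand-ups
and resetting after 60 s unoccupied or a completed exercise.

## 4. Microbreak detection and the light modes

All mappings are clamped affine maps (`linmap()`), with colour handled as
HSB (hue in degrees; saturation and brightness on the LED-native 0–255
scale) and converted by the standard HSV formula.

* **Ambient intervention** — sitting time 10–30 min → brightness 10–255;
  HRV from the calibrated maximum *down to* the minimum → saturation
  10–255; hue fixed at orange (30°). Below 10 min the brightness floors at
  10, the "almost invisible" resting state. More sitting and more stress
  therefore mean a brighter, more saturated orange.
* **Stretch guidance** — a five-phase state machine (`cue_left`/`cue_right`
  → `moving` → `hold` → `switch`). The cue is a 6-LED wipe segment
  travelling at 14 LEDs/s toward the target side; during movement the hue
  interpolates blue (240°) → green (120°) proportionally to progress toward
  the lateral-shift threshold; at the target a seeded sparkle re-randomises
  30% of the LED brightnesses per tick; after a 3 s hold the side flips and
  the colour resets to blue. One rep is a completed left+right cycle. The
  wipe and sparkle parameters are package choices (the original effects
  come from lighting libraries whose parameters are not published).
* **Breathing biofeedback** — the current IBI 550–1150 ms → brightness
  10–255, so the light literally breathes with respiratory sinus
  arrhythmia; HRV from calibrated minimum *up to* maximum → saturation
  10–**250**; the hue is user-chosen (default 200°). The 250 ceiling,
  though inconsistent with the intervention mode's 255, matches the
  published design and is deliberately preserved, as is the opposite
  saturation direction of the two modes.

Exercise-start detection watches 5 s of frames: a lateral weight-shift
index $|L-R|/(L+R)$ above 0.35 sustained for 2 s starts a stretch; a stable
posture with the (post-warm-up) HRV estimate climbing faster than 10% of
the calibrated range per 30 s starts breathing biofeedback. Stretch takes
precedence. After an exercise completes, detection pauses for a 30 s
cooldown so the tail of the user's own movement cannot immediately
re-trigger a session; the sedentary clock resets, returning the display to
its resting state.

## 5. Synthetic data: what it emulates and what it does not

`gen_bcg()` builds each heartbeat as a Gaussian-windowed 15 Hz sinusoid
with 150 ms support — chosen to land mid-band in the level-4 detail at 256
Hz — plus a respiratory sinusoid (default 0.25 Hz) and white Gaussian
noise, with exact ground-truth beat times. `gen_ibi_stream()` produces
breathing-modulated intervals (respiratory sinus arrhythmia as a sinusoid
on the tachogram). `gen_pressure()` draws frames from archetype means with
per-channel Gaussian noise clipped at zero; the reference spread is 10% of
the mean pairwise distance between archetype means (the empty seat gets
only a small sensor noise floor instead). `gen_session_script()` composes
these into annotated timelines at 10 Hz: a 35 min sedentary buildup, a
stretch break with two lean cycles, and a slow-breathing break.

These generators establish that the implementation recovers known ground
truth under controlled conditions. They do **not** establish performance on
real seat recordings: genuine BCG morphology varies beat to beat (I/J/K
wave structure), motion artefacts are not modelled beyond additive noise,
real pressure maps drift with clothing and position, and real respiratory
sinus arrhythmia is neither sinusoidal nor stationary. Accuracy figures on
synthetic data are therefore upper bounds of a sort: they validate the
algorithmic chain, not the sensor physics.

## 6. Numerical choices and problem sizes

* Sampling rate defaults to 256 Hz (the original hardware's rate is not
  published); the generator refuses rates below 8× the 15 Hz carrier.
* Moving windows truncate at series edges everywhere (no padding).
* SDNN uses the population (divide-by-*n*) form.
* Moving-max ties break earliest; the refractory gap equals the detection
  window (400 ms).
* The pipeline accuracy experiment used in tests runs heart rates
  {50, 60, 75, 100} bpm for 120 s each at five seeds, noise at 10% of beat
  amplitude — about 2,800 intervals — and the posture experiment trains on
  7 archetypes × 120 frames over three seeds. Both finish in well under a
  minute; these sizes give stable estimates while keeping the suite quick.
* All generators are pure functions of their arguments including the seed;
  RNG state is saved and restored around every draw.

## 7. Known limitations

Single-channel BCG only (the two film sensors of the physical pad are
assumed premixed); no frequency-domain HRV; no per-user transfer of the
posture network beyond channel normalisation; the stretch session cannot be
user-cancelled mid-rep (a simulated session ends on script command or rep
completion); ADC quantisation is ignored (signals are unit-free floats).
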