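---
title: "Fall-direction detection from simulated FMCW radar maps: models and methods"
author: "radarfall"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fall-direction detection from simulated FMCW radar maps: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(radarfall)
```

## The problem

Falls are a leading cause of injury among the elderly, and the *direction*
of a fall (forward, backward, leftward, rightward, or a collapse from
standing) carries clinical information: different directions injure
different body parts, so knowing the direction helps responders plan
treatment.  Millimetre-wave FMCW radar is an attractive sensor for this
task — it works in the dark, through light occlusion, and without
cameras in private spaces.  `radarfall` implements a complete,
reproducible desk-scale pipeline for the task: a physics-based echo
simulator, the standard range–time (RT) and Doppler–time (DT) map
processing, a two-stage map denoiser ("pattern feature extraction",
PFE), and a dual-branch convolutional classifier that fuses both maps.

Because no public dataset of radar fall-direction recordings exists, the
package treats the *simulator as the data source*: every experiment in
the documentation and test suite is generated, end to end, from seeds.

## Signal model

The radar transmits linear chirps of slope $\beta = B/T_c$ starting at
carrier $f_c$.  A point target at range $d$ returns an echo delayed by
$t_d = 2d/c$; after mixing, the baseband signal during one chirp is a
complex tone at the beat frequency

$$ f_b = \beta \, t_d = \frac{2 \beta d}{c}, $$

inverted by the range equation $d = c f_b / (2\beta)$.  Across chirps
(slow time) the carrier phase advances as $4\pi f_c d(t)/c$, so the
slow-time frequency is $(2 f_c / c)\,\dot d(t)$ — the micro-Doppler
signature, **negative while the target approaches**.  That sign
convention ties the two maps together: an approaching walk paints a
descending RT ridge and a negative DT ridge.

`synthesize_cube()` writes exactly this model into a fast-time × slow-time
complex matrix: per-chirp beat tones at the instantaneous range, the
slow-time carrier phase, a $1/d^2$ amplitude law normalised at the
starting range, an optional static clutter return, and complex white
Gaussian noise at a configurable per-sample SNR.  Deliberately *not*
modelled: transmitter phase noise (no spec to calibrate against),
multi-limb micro-Doppler (a single torso-dominant scatterer suffices
for the gross class signatures), antenna patterns, and multi-target
scenes.  Only one receive channel is synthesised; the RT/DT maps used
here gain nothing from more.

## Class templates

The five classes are encoded as radial trajectories $d(t)$: a walk phase
at `walk_speed` (default 1 m/s), a fall phase with a smooth half-cosine
range excursion, then rest.  For a subject walking toward the radar:

* **forward / left fall** — the range keeps decreasing; the fall
  steepens the descent.  Excursions 0.9 m vs 0.3 m (at 1.75 m height).
* **backward / right fall** — the range reverses and increases during
  the fall.  Excursions 0.7 m vs 0.25 m.
* **fall from standstill** — constant range, then a 0.5 m excursion
  with a seed-drawn sign; zero Doppler before the fall.

Away-from-radar variants mirror every trend, and both variants share
one class label per direction.  Excursions scale with
`subject_height / 1.75` — taller subjects displace more during a fall,
which is what makes height matter for recognition accuracy.  A 5%
seeded jitter on speeds and excursions, uniform draws for onset,
duration, start distance and height, keep samples distinct.

A note on internal consistency: for a forward fall while approaching,
a *negative* Doppler excursion (faster approach) logically accompanies a
*decreasing* range; the templates follow the Doppler/kinematic reading
throughout, so RT and DT maps of every class agree with each other.

## From cube to maps

* **RT map** (`range_time_map`): unitary DFT along fast time per chirp;
  power against chirp time.  Bin $k$ sits at $k \cdot c/(2 B_s)$ where
  $B_s = \beta N_s / f_s$ is the bandwidth actually swept during the ADC
  window — equal to the nominal $B$ when the ADC spans the whole ramp,
  smaller when (as in the default parameter set: 256 samples at 5 MHz
  inside a 60 µs ramp) it does not.  Calibrating with $B_s$ rather than
  the nominal $B$ is what makes the map peak land on the true range.
* **DT map** (`doppler_time_map`): fast-time DFT, then an *active range
  gate* — the bins whose slow-time variance exceeds the median variance
  (the moving returns; static clutter self-excludes).  When a cube is
  slow-time-deterministic the variance gate is degenerate and the gate
  falls back to mean power, so a noiseless static target still shows
  its 0 Hz line.  The gated bins are summed coherently and a short-time
  Fourier transform (Hann window, 32 chirps, hop 8, 64-point FFT by
  default) produces Doppler power against time, zero-Doppler centred,
  spanning ± half the chirp repetition frequency.

The STFT numerics are free parameters of the method; the defaults
resolve walking Doppler (≈400 Hz at 60 GHz and 1 m/s) and fall peaks
(≈1 kHz) with ≈13 ms time resolution at the desk profile's 2.5 kHz
chirp rate.  Chirps of consecutive frames are concatenated on one
uniform slow-time axis; inter-frame gaps are not modelled separately.

Both maps are stored in **decibels above a floor** set `floor_db`
(default 60 dB) below the map maximum, i.e. values in $[0, 60]$.
Non-negativity matters: the PFE threshold below is an *additive* blend
of mean and extremes and behaves as a between-mean-and-max cut only on
non-negative maps.  With the floor disabled the raw dB power is kept,
under which the RT map conserves total cube power exactly (a Parseval
identity used in the tests).

## Pattern feature extraction

PFE cleans a map in two stages:

1. **Adaptive power threshold**: $P_{th} = (1-a)\bar P + a(\max P + \min P)$,
   cells below $P_{th}$ are floored to the map minimum.  $a \in [0,1]$
   interpolates from the mean ($a=0$) to $\max + \min$ ($a=1$; note the
   additive form is kept verbatim — no $/2$ — so $a$ near 1 can exceed
   the maximum, in which case nothing survives but exact-maximum
   cells).  The default $a = 0.25$ places the cut far enough above the
   Rayleigh-noise floor to erase it while keeping ridges tens of dB
   deep.  $a$ is a per-map-kind constant, not re-estimated per map:
   the "adaptive" part of the name refers to the map statistics
   entering the formula.
2. **Hampel filter** along the time axis of each feature bin (each row
   as a time series): within the window $[k-K, k+K]$ (truncated at the
   boundaries) compute the median $m_k$ and
   $S_k = 1.4826 \cdot \mathrm{median}(|x_j - m_k|)$, and replace $x_k$
   by $m_k$ when $|x_k - m_k| > n_{th} S_k$.  Defaults $K = 5$,
   $n_{th} = 3$.  When $S_k = 0$ (a majority-constant window) any
   deviation from the median is replaced — that is what removes
   isolated specks sitting on a flat floor.  The filter is
   non-recursive, never invents values outside the window's range, and
   the row-wise orientation preserves vertical (range/Doppler) structure
   while killing isolated time-axis specks.

Applied in this order — threshold first, then Hampel — because
thresholding flattens the background, which makes the Hampel windows
tight and the outlier decision sharp.

## The dual-branch classifier

Each branch consumes one map kind as a 54×54×3 tensor and applies
Conv(3→16, 3×3) → MaxPool(2×2) → Conv(16→32) → MaxPool →
Conv(32→64) → MaxPool → Conv(64→128) → Flatten, all convolutions
valid (no padding) with ReLU.  A 54×54 input is the unique common image
size under which this chain flattens to exactly 1×1152 per branch
(128 channels × 3×3); the two branches concatenate to 1×2304 and a
fully connected layer produces 5 logits, softmaxed to class
probabilities.  A softmax with cross-entropy replaces the nominal
sigmoid head: the task is single-label, five-way.

Maps become tensors by min–max normalisation to $[0,1]$, bilinear
resampling to 54×54, and replication to three identical channels
(grayscale; a colormap would add an arbitrary choice without
information).  RT maps are first cropped to the 0.5–7 m band the scene
occupies — without the crop, a few-metre scene occupies a sliver of the
14.9 m unambiguous span and sub-pixel class differences vanish.

Training: Adam at learning rate 5e-4, 50 epochs, batch 32, step decay
halving the rate every 10 epochs, stratified 80/20 split.  Activations,
optimiser and batch size are standard choices where the protocol leaves
them open.  The implementation (RcppArmadillo, single precision,
im2col + BLAS GEMM over whole minibatches) is seeded end to end:
initialisation, shuffling and splits all derive from one integer, and
refits reproduce histories bit for bit on one machine.

## Numerical and design choices

* **Seeds**: every stage draws from sub-seeds derived deterministically
  from one master seed (`derive_seed`), so stages re-run in isolation
  reproduce full-pipeline artifacts.
* **Sampled-bandwidth calibration** (above) rather than nominal-\(B\);
  the two coincide when the ADC covers the ramp.
* **Fall-duration cap**: the drawn fall duration is capped at 95% of
  the window remaining after onset so short test records stay valid; at
  the default 3 s records the cap never binds.
* **Continuity guard**: cubes refuse trajectories whose per-chirp range
  step exceeds 10× the larger of the walk speed and the fall's peak
  half-cosine speed — a tripwire for discontinuous $d(t)$ functions.
* **Degenerate inputs**: constant maps preprocess to flat 0.5 images
  with a warning; all-zero cubes give uniform floor maps; empty gates
  fall back to all bins.
* **Desk profile**: the default full parameter set (256 samples/chirp,
  160 µs chirp interval, 10 s records) is faithful to a real 60 GHz
  device but data-heavy; the `desk_radar_config()` profile keeps the
  waveform and halves nothing physical — it records 64 fast-time
  samples and stretches the chirp interval to 400 µs (2.5 kHz Doppler
  span, comfortably above the ≈±1.1 kHz the kinematics produce), with
  3.02 s records, fall onset U[1.2, 1.8] s and start distance
  U[3.5, 4.5] m so that away-from-radar tracks stay inside the
  unambiguous range.  All simulation studies in the tests and the
  acceptance script use this profile.
* **Problem sizes**: the headline study uses 150–200 samples per class,
  50 training epochs and 3 training seeds (median reported); the PFE
  ablation uses 60–80 samples per class at 5 dB SNR with 1% speckle.
  These sizes give stable medians while keeping a full run in minutes
  on a single CPU.

## What the simulation does and does not show

The generator reproduces the *gross* RT/DT signatures that distinguish
fall directions — monotone vs reversing range trends, large vs small
excursions, Doppler sign tied to range rate, height-scaled excursions —
plus Gaussian noise, static clutter and speckle outliers.  It does not
reproduce limb-level micro-Doppler, real clutter statistics,
multi-path, or between-subject gait variability.  Passing the test
suite therefore demonstrates that the pipeline implements the method
correctly and that the method separates the encoded signatures; it does
not certify field accuracy on real falls, and the near-perfect
accuracies on clean synthetic data should be read as a ceiling, not a
forecast.

## Known limitations

* Single point scatterer; no angular information; one RX channel.
* The 24×24/same-padding network variant is not provided; the
  architecture is fixed to the 54×54 valid-padding chain.
* Cubes and maps persist via R's native serialisation rather than a
  cross-language container; manifests (CSV), configs (YAML) and reports
  (CSV/JSON) are portable text.
* The Hampel stage assumes outliers are isolated along time; bursts
  wider than the half-window survive.
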