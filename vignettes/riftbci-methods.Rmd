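---
title: "Simulating and decoding a rapid-invisible-frequency-tagging BCI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and decoding a rapid-invisible-frequency-tagging BCI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riftbci)
```

## The system being modelled

Rapid invisible frequency tagging (RIFT) drives a visual stimulus with
luminance flicker above the perceptual fusion threshold — here 56 Hz on a
left screen patch and 60 Hz on a right patch, sampled on a 1440 Hz frame
clock. The flicker is invisible, but visual cortex responds with a
narrowband steady-state evoked field at the tagging frequency, and covert
spatial attention (attending a patch without looking at it) multiplies the
power of the attended patch's frequency. A brain-computer interface can
therefore decode *where a user is attending* from a handful of occipital
MEG sensors and use it to control, tick by tick, which side of the screen a
pong bar sits on.

`riftbci` implements that entire loop as a simulation: stimulus sequencing,
a generative model of the MEG/gaze/trigger stream, the online path
(100 ms blocks feeding a 1 s ring buffer), spectral feature extraction and
a linear SVM decoder, the pong game itself, and the offline analysis suite
(filtering, epoching, time-frequency decomposition, spectral SNR,
information transfer rate, sliding-window power, cluster-based permutation
statistics, and eye-movement confound checks). Everything is deterministic
under a seed and runs headless.

## The generative model

A synthetic participant is a `subject_profile()`. During tagging, MEG
channel $c$ carries

$$x_c(t) = g_{c,56}\, a_{56}\, m_{56}\, \sin(2\pi\,56\,t + \phi_{56})
        + g_{c,60}\, a_{60}\, m_{60}\, \sin(2\pi\,60\,t + \phi_{60})
        + \nu\, \eta_c(t) + \alpha\, r_c(t),$$

where $a_f$ are the response amplitudes, $m_f$ equals the attention gain
when frequency $f$'s side is attended and 1 otherwise (so attention acts
multiplicatively on amplitude and quadratically on power), $g_{c,f}$ are
per-sensor gains, $\eta_c$ is 1/f background noise, and $r_c$ is an
amplitude-modulated 10 Hz alpha rhythm. Phases are randomized per trial.
This is the simplest model that reproduces the narrowband, lateralized,
attention-modulated power structure the decoder relies on; it makes no
claim about response waveforms in real cortex.

Specific choices, and why:

* **Sensor layout.** Seven named occipital channels: three left-hemisphere
  (larger 60 Hz gains — visual hemifields project contralaterally, and the
  right patch is tagged at 60 Hz), three right-hemisphere (mirrored), one
  midline with equal gains. The gain values are configuration defaults,
  not measurements.
* **Background noise.** 1/f noise is generated by spectral shaping of
  white Gaussian noise, with a fixed power spectral density normalized so
  a one-second stretch has unit variance. Fixing the *density* rather than
  the per-realization variance matters: it makes the noise floor at the
  tagging bins identical whether noise is produced in short blocks or long
  records, so calibration on one-second windows transfers to full
  sessions. The default log-log slope is −1; alpha is a 10 Hz carrier
  under a slowly wandering envelope, and contributes essentially nothing
  at the 54–62 Hz bins used for decoding and SNR.
* **Amplitude calibration.** `calibrate_amplitude()` finds the response
  amplitude whose measured narrowband SNR (power at the tagged frequency
  over the mean power of its ±2 Hz neighbours, spectra averaged over many
  one-second windows and the ratio averaged over the seven sensors) equals
  a target. The defaults target SNR 3.1 at 56 Hz and 2.0 at 60 Hz — the
  magnitudes reported for human MEG under this paradigm, with the slower
  flicker eliciting the stronger response. The search iterates a
  multiplicative fixed point (excess SNR scales with squared amplitude)
  against a common-random-numbers measurement, so it is deterministic
  under its seed and converges in a few evaluations. Spectra are averaged
  *before* the ratio: the ratio of single-window bin powers is upward
  biased (bin powers are roughly exponential), whereas the
  averaged-spectrum ratio correctly anchors a flat spectrum at SNR 1 and
  amplitude 0.
* **Attention gain.** Default 1.25 (amplitude ratio). This was chosen once
  so that, at the calibrated SNR, mean 4-fold cross-validated decoding
  accuracy over simulated subjects lands in the 60–75 % band observed in
  human participants (we measure ≈ 0.70 over eight seeds).
* **Gaze.** Fixational drift is an Ornstein–Uhlenbeck process
  (SD 0.4°, time constant 0.25 s) plus occasional brief excursions
  (rate 0.18 s⁻¹, 3.5 × drift SD), tuned once so that ≈ 97 % of samples
  fall within 1° of fixation and ≈ 1 % outside 2°, the containment
  reported for fixating humans. Blinks arrive as a Poisson process
  (default 6 min⁻¹, 150–400 ms) and mark the gaze channels with `NA`;
  gaze never couples to the MEG channels, which is what makes the
  eye-confound null check meaningful.
* **Neural lag.** Attention shifts take effect on tagged power after a
  configurable lag (default 300 ms). This makes the closed loop
  non-trivial — the decoder's one-second window straddles recent shifts —
  without contradicting anything measured.

## Training protocol and decoder

`simulate_training_session()` emits exactly 80 trials (40 attend-left,
40 attend-right, randomly ordered under the profile seed): 1 s baseline
without tagging, 2 s bilateral tagging with the attended side's frequency
boosted, 1 s rest so offline epochs of [−1, +3] s fit. Features are the
raw (untapered) single-bin DFT powers at 56 and 60 Hz on each of the seven
sensors — 14 features per one-second window; training uses the second half
of the tagging phase, matching the online buffer length.

`rift_decoder()` z-scores the features and fits a linear SVM (C = 1,
no class weighting — the design is balanced). Accuracy is estimated by
stratified 4-fold cross-validation with fold-internal standardization;
the returned model is refit on all trials. The decision score is oriented
so positive means "left"; a score at zero (to numerical tolerance) keeps
the previous side, which prevents bar chatter at the hyperplane.
Standardization is a deliberate addition: raw bin powers differ by orders
of magnitude across sensors, and a linear SVM on unstandardized power is
dominated by the strongest sensor.

The online path mirrors acquisition: 100 ms blocks are pushed into a
one-second ring buffer; classification starts only once the buffer has
filled (during warm-up the bar holds its starting side). The simulation
advances in block ticks with no wall-clock coupling, so runs are exact and
fast.

## The game

The pong world uses normalized screen coordinates (origin top-left,
y downward). The ball resets uniformly into the top quarter, falls at half
speed for its first second (orientation period), and reaches the collision
height (y = 0.9) in about 3 s at full speed. The bar teleports to the
decoded side each tick; the hit rule is side equality at collision. On a
hit the downward motion is reflected 90° into horizontal motion toward the
nearer wall, where the ball bounces and descends; each completed trial —
hit or miss — ends in a reset, so resets = hits + misses + 1 over a
session. Ball speeds and geometry are configuration (`game_config()`)
chosen to give a human-like trial rate (≈ 60–70 trials per 5-minute game);
the exact values are not claims. Trials with an eye-tracker gap of at
least 50 ms (the standard pupil-loss criterion; the discard rule itself is
part of the modelled protocol) in the last second before the collision are
flagged invalid and excluded from accuracy, though they still appear in
the raw score.

## Offline analysis

* `preprocess()`: zero-phase 4th-order Butterworth band-pass 1–80 Hz plus
  a 2 Hz-wide zero-phase notch at 50 Hz, MEG channels only; deliberately
  no artifact rejection or baseline correction.
* `tfr_hanning()`: per frequency $f$ in 40–70 Hz, a Hanning-tapered
  sliding window of 20 cycles ($20/f$ s) in 25 ms steps, trial-averaged.
  Edge time points whose window does not fit are `NA`, never zero-filled.
  Power is normalized so an on-grid sinusoid yields its squared amplitude.
* `sliding_power()`: untapered single-bin DFT power over a trailing
  one-second window slid in 1 ms steps and decimated to 100 Hz, mirroring
  the online buffer. Implemented as a cumulative-sum sliding DFT,
  floating-point-identical to per-step recomputation.
* `itr()`: Wolpaw bits per minute. The default divides $(1-P)$ by $N-1$;
  the variant dividing by $N$ (seen in print) is available as
  `convention = "printed"` but is negative at chance for $N = 2$, which is
  why it is not the default.
* `cluster_permutation()`: dependent-samples t per time point, clusters as
  maximal same-sign supra-threshold runs (forming threshold: two-tailed
  p < 0.05 of the t distribution — the field default; the inference rule
  does not depend strongly on it), null distribution of the *maximum*
  cluster |t-sum| under within-subject sign flips, which controls
  family-wise error over time points. `exact = TRUE` enumerates all $2^n$
  flips; with random permutations p-values use the add-one estimator so
  they stay in (0, 1].

## Numerical and degenerate-input choices

DFT bin alignment is enforced: `psd_at()` rejects frequencies not on the
window's bin grid rather than silently leaking. Single-class or
undersized training sets, mismatched buffer blocks, out-of-bounds epochs,
shape-mismatched condition matrices, and zero SNR denominators all raise
errors; empty event selections warn and return empty epochs. Scores within
1e-9 of the hyperplane are treated as ties (hysteresis). Serialized
decoders carry a format version and the feature order, and prediction
refuses mismatched channel order.

## What the simulation does and does not show

Passing tests demonstrate that the pipeline is internally correct: the
decoder recovers exactly the statistical structure the generator puts in,
at the SNR magnitudes reported for humans, and the offline statistics
behave (exact permutation agreement, controlled type-I error, chance-level
behaviour under shuffled labels or absent attention modulation). They do
not show that real MEG is this friendly: the generator has no sensor
noise correlations, no forward-model topography, no microsaccades, no
artifacts beyond blinks, no non-stationarity in the response amplitudes,
and phase-locked sinusoidal responses. Closed-loop accuracy here speaks to
the software, not to human performance.

## Problem sizes

The shipped tests and the acceptance script use the study-scale problem
sizes: 80-trial training sessions, 5-minute games at 100 ms ticks, eight
simulated subjects, 1500 one-second windows for SNR calibration and
measurement, 200 label shuffles for the empirical chance level, 1000
(or exhaustive) permutations per cluster test, and 500 simulated null
datasets for the family-wise error check.
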