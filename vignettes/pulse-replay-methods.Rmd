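---
title: "Methods: simulated pulse tactile record-and-replay"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulated pulse tactile record-and-replay}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pulsereplay)
```

`pulsereplay` is a software twin of a pulse tactile record-and-replay
system: a PVDF-film recorder captures radial pulse vibrations under a known
palpation force, and a piezoelectric-bender player replays them so that a
trainee can feel the same pulse later. Every stage — the wrist, the sensor,
the player, the inverse models — is simulated, so each link of the chain
can be studied, perturbed and verified in isolation. This vignette explains
the models, the tunable parameters, the numerical choices, and what the
synthetic benchmark does and does not demonstrate.

## Signals and units

All waveforms are tibbles (`time_s`, `value`) with a sampling rate and a
unit tag: `"volt"` for sensor or driving voltages, `"du"` for displacement
in arbitrary displacement units. Real wrist-pulse amplitudes in physical
units are not knowable here, so displacement is relative throughout; one du
is, by construction, roughly the percussion amplitude of a moderate-force
pulse.

## Synthetic pulses

One beat is the sum of three Gaussian bumps above a baseline: the
percussion wave (the early systolic peak, the largest feature, default
timing 15% of the beat period), the tidal wave (late systolic shoulder,
35%) and the dicrotic bump (rebound, 55%). A Gaussian template was chosen
because it is smooth, differentiable and feature-controllable; the raised
cosine alternative behaves equivalently for every property tested.
Amplitudes must satisfy percussion > tidal > dicrotic > 0, and heart rate
is restricted to the physiological 0.6–2 Hz band. Beat-to-beat variability
perturbs only the period (coefficient of variation `beat_jitter`, default
2%); morphology is held fixed within a recording, the simplest
physiologically plausible variation. Measurement-like noise is additive
white Gaussian displacement noise, because no finer characterization is
available for the target system.

The three palpation-force presets encode the familiar clinical pattern
that lightly pressed pulses are faint and noisy:

| preset   | amplitude scale | relative noise sd | representative force |
|----------|----------------|-------------------|----------------------|
| light    | 0.4            | 5%                | 0.6 N                |
| moderate | 1.0            | 2%                | 1.2 N                |
| heavy    | 1.3            | 1%                | 1.8 N                |

## Recorder model

PVDF piezo film produces charge proportional to strain, so the observed
voltage is proportional to the displacement *rate*; the waveform is
recovered by integration. The simulator uses the first difference times
the sampling rate (padded at the first sample) for the derivative and the
cumulative trapezoid for the integral. These are not exact inverses: their
composition is a half-sample moving average, which attenuates content near
the Nyquist rate. At the 1 kHz recording rate this error is negligible for
pulse content; it matters for the broadband noise component (see the
training-error pattern below).

Integration of a noisy voltage accumulates a random walk, so every
integration in the pipeline offers (and the pipeline uses) a least-squares
linear detrend. A consequence adopted deliberately throughout the package:
integrated recordings are only defined *modulo an affine function of
time* — the DC level is unobservable to a rate sensor and the linear
component is sacrificed to drift suppression. Training pairs and verified
waveform pairs are therefore always projected into that same quotient
space before being paired or scored (`verify(align = "trend")`).

Mean-filter downsampling averages non-overlapping windows aligned to the
first sample, so 8 s at 1 kHz becomes exactly 2000 points at 250 Hz while
suppressing noise. The recorder-screening score is the sum of the profile
fit (R²) and the normalized peak output voltage, both in [0, 1]; the
normalization base for the peak voltage is taken as given rather than
computed, since it depends on the set of candidate designs being screened.

The cam-verification protocol wraps this up: a one-second cam profile (one
noiseless synthetic beat — the physical cam geometry it stands in for is
not published, so the fixture is synthetic by necessity) is recorded
repeatedly at 60 rpm, integrated, and scored. The default sensor noise for
this protocol is 2% of the peak recorded voltage.

## Empirical mode decomposition

Sifting repeatedly subtracts the mean of the cubic-spline envelopes of the
local maxima and minima. Numerical choices, all deterministic:

- **Extrema**: strict sign changes of the first difference; plateaus at a
  turning point take the plateau midpoint.
- **Envelopes**: natural cubic splines through the extrema, with the two
  extrema nearest each end mirrored about the endpoints — the standard
  remedy for spline end swings.
- **Stop criterion**: sifting of one component stops when the Cauchy-type
  ratio `SD_k = Σ(h_{k-1}-h_k)²/Σ h_{k-1}²` falls below 0.1 *and* the
  candidate satisfies both IMF conditions — extrema and zero-crossing
  counts differing by at most one, and an envelope mean below 5% of the
  component's peak amplitude away from the boundary 5% of samples. The SD
  criterion alone (the published threshold) can stop a component while it
  is still visibly under-sifted; requiring the IMF conditions as well makes
  every returned component a genuine intrinsic mode at the cost of a few
  extra sift iterations (capped at `max_sift_iters`, default 50).
- **Decomposition stop**: the running residue is considered the monotonic
  trend once it has fewer than two maxima or two minima; a literal
  monotonicity test never triggers on noisy data. At most `max_imfs`
  (default 7) components are extracted.

Reconstruction — the element-wise sum of all IMFs plus the residue — equals
the input to floating-point precision by construction (the decomposition is
telescoping), and this identity is property-tested on every input class.

Each IMF carries an energy weight (sum of squares, normalized to sum 1
over IMFs; the residue is excluded from the normalization) and, after
`normalize_imfs()`, a peak-amplitude scale. Normalization to unit maximum
absolute value (rather than unit energy or a DAC range) was chosen because
the scales then recombine the normalized IMFs *exactly* back into the
residue-removed waveform — the algebraic identity the replay step relies
on. The energy weights order the components by importance; the amplitude
scales are what multiply the per-IMF driving signals during recombination,
because only they restore the waveform's amplitude.

On the noiseless default pulse morphology the first three IMFs carry the
three largest energy weights. With additive instrument noise the
decomposition first splits off one or two broadband noise components of
near-zero weight, shifting the heart-rate fundamental to a later slot; the
energy-ordering property is therefore stated for the morphology, not for
any particular noisy realization.

## The simulated player (plant)

The default plant is memoryless:

```
y = linear_gain * (v + cubic_coeff * v^3 / v_limit^2) * (1 - force_damping * force)
```

with the drive clipped to ±48 V rails. Defaults: `linear_gain` 0.04 du/V
(so the stroke at amplified unit drive spans about one du, the synthetic
pulse scale, with headroom to the rails), `force_damping` 0.05 /N (finger
pressure suppresses bender vibration; about 9% attenuation at heavy
force), and an amplifier gain `drive_gain` of 24 (≈ 80 Vpp from 3.3 Vpp)
applied to unit-amplitude normalized driving signals.

`cubic_coeff` controls how nonlinear the player is, and its default (3,
i.e. a 30% gain deviation at typical ±24 V drives) is the one genuinely
free design choice of the benchmark: the real player's transfer
characteristics are unpublished, and the defining feature of the system
being emulated is that a *linear* drive model reproduces pulses poorly
while the neural inverse reproduces them well. A much weaker cubic makes
the linear baseline essentially optimal and the comparison vacuous; a much
stronger one breaks the per-IMF drive-combination approximation for *any*
inverse model (see below). The default sits where both halves of the
published comparison are visible: the linear model is significantly worse,
and the neural replay still meets the published fidelity bounds.

A memoryless plant is not incidental: the inverse models map one
displacement sample to one voltage sample, which can only invert a
memoryless map. The optional play-operator hysteresis
(`hysteresis_strength` > 0) exists to demonstrate that limit, not for the
benchmark.

## Inverse models and training

Training data follow the published protocol. Each recorded pulse signal is
downsampled to 250 Hz, integrated, decomposed; the normalized IMFs
(zero-padded to exactly 7 slots; the residue, being the basic trend, is
never driven) are amplified and played through the plant at the regime's
representative force; the re-recorded, integrated vibration is the model
input `p`, the driving voltage the model output `u`. Drives are upsampled
to 1 kHz before playing and the recording is downsampled back, exactly as
in reproduction — training and replay must see the same chain. Ten pulse
sets × 7 IMFs × 2000 points give 140,000 pairs per force regime.

The neural inverse is a 1-10-1 multilayer perceptron: logistic sigmoid
hidden layer, hyperbolic-tangent sigmoid output, trained by mini-batch
back-propagation (batch 64, shuffling and ±0.5 uniform initialization
seeded) with learning rate 0.8 and 10⁴ epochs by default. Inputs are
affine-scaled to [0.05, 0.95] and outputs to [−0.9, 0.9]; the margins keep
activations out of saturation. Two implementation choices beyond the bare
recipe:

- the learning rate decays exponentially to 0.8% of its initial value over
  the epochs — constant-rate stochastic gradient descent orbits the
  minimum in a noise ball roughly proportional to the step size, which is
  large at a rate of 0.8;
- `fast_train_config()` (150 epochs on a 16,000-pair subsample) is the
  recipe used by the test suite and the benchmark. The map being learned
  is a smooth scalar curve, so the reduced recipe reaches the same
  accuracy regime as the full one; the full recipe remains the default of
  `train_config()`.

The linear baseline is the least-squares gain and offset on the same
pairs. Per-(set, IMF) training NRMSE is reported for both kinds. In this
simulation the energy-carrying IMFs 2–3 train best; the late, slow IMFs
are worse (their small PVDF voltages are noisier relative to the fixed
sensor noise, and few periods survive the detrend), and the broadband
noise component IMF1 of light-force signals is worst of all, because the
discrete record/replay chain attenuates content near the Nyquist rate in a
frequency-dependent way no pointwise model can invert. The low-error
components are exactly the high-energy ones, so they dominate the
recombined drive.

## Reproduction and verification

Replay follows the training flow in reverse: downsample, integrate,
decompose, normalize; the force-matched model predicts a driving signal
per IMF; each drive is multiplied by its IMF's amplitude scale and all are
summed; the combined drive is upsampled to 1 kHz by linear interpolation
(the minimal choice), played, re-recorded and integrated. The residue is
excluded from driving and therefore from comparison: the replay is scored
against the residue-removed original on the 250 Hz grid, in the
detrended/mean-free quotient space described above. Fidelity is
`NRMSE = RMSE / (max − min)` of the original, and R² as the coefficient of
determination (the stricter of the two common readings; squared Pearson
correlation is available via `method = "correlation"`).

Per-IMF inversion then scale-weighted summation is itself an
approximation: a nonlinear plant does not satisfy
`f(Σ s_i d_i) = Σ s_i f(d_i)`. With the default plant this superposition
error is the dominant term in the end-to-end error budget — it is the
price of the pointwise, per-IMF architecture, and it grows with the
plant's nonlinearity.

`run_benchmark()` executes the full design: per force regime, 10 training
sets and 8 held-out sets (subject heart rates drawn from 0.9–1.5 Hz),
sensor noise 0.3 V (about 2% of the peak recorded voltage of the reference
moderate pulse, matching the cam-protocol noise level), one neural and one
linear model, 24 verification trials in all, and pooled-variance
independent-sample t-tests (Welch available) comparing the two model kinds
on NRMSE and on R² per force level and overall. Problem sizes were chosen
so the complete benchmark runs in well under a minute; all conclusions the
package asserts about it are computed by the test suite and
`scripts/acceptance.R` at run time.

## What the synthetic benchmark does not show

The generator emulates beat morphology, force-regime amplitude/noise
structure and a rate-sensing acquisition chain. It does not emulate:
sensor nonlinearity or temperature drift, bender resonances or
frequency-dependent mechanical response (the plant is static), contact
mechanics of skin on silicon, pulse-morphology pathology, or any
perceptual question. Passing the benchmark shows the *pipeline* is
self-consistent and that the neural inverse recovers a nonlinear static
plant map better than a linear one — it says nothing about how a physical
player would feel. Degenerate inputs are handled explicitly: constant
signals decompose to a bare residue, signals without two maxima and two
minima have no envelope (a termination condition, not an error), zero
IMF slots carry zero weight, and constant originals make the fidelity
metrics undefined (an error, since the NRMSE denominator vanishes).
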