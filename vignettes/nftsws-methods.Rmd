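---
title: "Modelling slow-wave-sleep stimulation with a corticothalamic neural field"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling slow-wave-sleep stimulation with a corticothalamic neural field}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nftsws)
```

## The model

`nftsws` simulates the electrical activity of sleeping cortex with a
mean-field model of the corticothalamic system. Four neural populations are
represented by their mean firing rates: cortical excitatory (`e`, the
pyramidal cells whose activity dominates the EEG), cortical inhibitory
(`i`), thalamic reticular (`r`) and thalamic relay (`s`). Each population's
mean soma voltage $V_a$ integrates its synaptic input through a
second-order synapto-dendritic response,

$$\frac{1}{\alpha\beta}\ddot V_a + \Big(\frac1\alpha + \frac1\beta\Big)\dot V_a + V_a
  = \sum_b \nu_{ab}\,\phi_b(t - \tau_{ab}),$$

with $\alpha$ and $\beta$ the inverse decay and rise times. Voltage maps to
firing rate through the sigmoid
$Q_a = Q_{\max} / (1 + e^{-(V_a - \theta)/\sigma_\rho})$, a logistic
approximation to the cumulative normal distribution of firing thresholds.
Only the excitatory population has axons long enough for spatial
propagation to matter; its field $\phi_e$ obeys a damped wave equation on a
two-dimensional periodic sheet,

$$\frac{1}{\gamma_e^2}\ddot\phi_e + \frac{2}{\gamma_e}\dot\phi_e + \phi_e
  - r_e^2\nabla^2\phi_e = Q_e,$$

while $\phi_a = Q_a$ for the other populations. The only nonzero conduction
delays are the corticothalamic one-way delays
$\tau_{es} = \tau_{se} = \tau_{re} = t_0/2$. The relay nucleus additionally
receives the external drive $\phi_n(\mathbf r, t)$: spatially white Gaussian
noise (the net input from brainstem and periphery) plus, when stimulating,
a localised pulse train.

The default parameter set (`nft_params()`) is an operating point between
the spindle-dominated N2 and slow-wave N3 sleep stages, taken at two thirds
of the straight-line trajectory in connection-strength space between the
two published stages, with steady drive $\phi_n^{(0)} = 1\,s^{-1}$. At this
point the linearised output spectrum shows both the low-frequency
slow-oscillation lobe and a spindle-band resonance just above 9 Hz, so both
event types occur spontaneously. `interpolate_stage()` reproduces the
trajectory construction for user-supplied endpoint parameter sets.

## Numerics

The integrator (compiled code) uses explicit Euler stepping at
`dt = 1e-4` s on a 16 x 16 torus of side 0.5 m, a standard 5-point
Laplacian, and ring buffers of `round(t0/(2 dt))` = 425 steps for the
delayed fields. Under the reduced-parameter convention the inhibitory
population receives exactly the excitatory population's cortical drive, so
$V_i \equiv V_e$ for identical initial conditions; the implementation
exploits this identity instead of integrating a redundant copy. Every run
starts with a 6-second stimulation-free burn-in from the requested initial
state (all-zero by default), consuming the run's own noise stream; the
main run stores the spatial mean of $\phi_e$ at 100 samples per second by
plain decimation and subtracts its temporal mean to form the EEG-like trace
$x(t)$.

Noise is drawn once per node per integration step with the stated mean and
standard deviation (3.11 s^-1, i.e. 9.67 s^-2 of per-node power), with no
$\sqrt{dt}$ rescaling and no rectification of negative samples. The noise
stream comes from a dedicated deterministic generator seeded by the run
seed, so a SHAM run is an exact noise-paired baseline for any stimulated
run with the same seed, and identical configurations reproduce bit-identical
results. An integration guard aborts with an error if any voltage exceeds
1 V or any field exceeds $10\,Q_{\max}$, which catches unstable
user-supplied parameter or step-size combinations.

A zero-noise run started at the fixed point stays at it to machine
precision, and the Welch spectrum of a low-noise run matches the closed-form
linearised transfer function — including its absolute scale, since per-step
noise of variance $\sigma^2$ has one-sided spectral density
$2\sigma^2 dt$ and spatial averaging over $N$ independent nodes divides the
uniform-mode drive variance by $N$. These two cross-checks validate the
integrator and the analytic module against each other; both are exercised
in the test suite at reduced run lengths (30 s and 120 s).

In the transfer function, the spatial term enters the denominator as
$+k^2 r_e^2$ (the Fourier transform of the damped wave operator); the
default evaluation uses $k = 0$ because spatial averaging of the output
retains only the uniform mode.

## Stimulation

Six pulse shapes are supported, parameterised by duration and energy;
amplitude is derived by inverting each shape's closed-form energy
(`pulse_amplitude()`). The "rectangular trapezoid" is realised as a flat
top over the first half of the pulse followed by a linear decay, the only
simple geometry consistent with its printed energy coefficient $2A^2D/3$.
The truncated-Gaussian width is solved numerically once so that its energy
coefficient is exactly 0.3957. Waveforms are sampled at step midpoints,
keeping the discrete energy within 2 % of the analytic value for all
durations down to 25 ms.

The one-channel pulse is mapped onto the sheet through a
difference-of-Gaussians receptive field centred at node (7, 7) with widths
1 and 2 in node units, evaluated literally as
$w(r) = e^{-d^2/\sigma_E^2}/(2\pi\sigma_E) - e^{-d^2/\sigma_I^2}/(2\pi\sigma_I)$.
Open-loop delivery is periodic (STIM-P) or Poisson (STIM-R, exponential
inter-arrival times clamped below at the pulse duration so pulses never
overlap); both are restricted to a stimulation-free 5-second head and tail.

## Closed-loop phase locking

The closed-loop driver estimates the instantaneous phase of the ongoing
activity at a central frequency of 0.85 Hz and releases a pulse when the
phase enters a ±9° hysteresis window around the target (sine convention:
0° = rising zero-cross, 90° = up-peak). The estimator is the printed
two-stage IIR design: an inverse-notch resonator (zeros at ±1 and 1, poles
at $0.9999 e^{\pm i\omega_0}$ and the origin, numerator scale $10^{-4}$),
an envelope normaliser (peak hold with exponential decay at 12.5 s^-1 and a
one-period counter reset), and a quadrature stage (zeros
$-0.5 e^{\pm 0.495\pi i}, -0.9$; poles $0.9999 e^{\pm i\omega_0}, 0.999$).

Two design choices were genuinely open and were resolved by analysing the
printed filters:

* **Controller rate.** The filters are meaningful only relative to the tick
  period $h$ through $\omega_0 = 2\pi f_0 h$. At $h = 0.01$ s (the stored
  sampling rate) the resonator bandwidth is 0.0016 Hz — a flywheel with a
  ~100 s time constant that cannot follow the rhythm — and the quadrature
  stage's shift at $\omega_0$ is ~177°, leaving the in-phase/quadrature
  pair nearly collinear and phase recovery ill-conditioned. At the
  integration rate ($h = 10^{-4}$ s) the bandwidth is ~0.3 Hz and the shift
  ~-113°. The controller therefore runs at the integration rate by default
  (`ctrl_decim = 1`), with the tick exposed for experimentation.
* **Phase recovery.** The quadrature stage's complex response at
  $\omega_0$ — gain $g$ and shift $\psi$ — is known at design time, so the
  cosine component is reconstructed as
  $\hat c = (y/g - z\cos\psi)/\sin\psi$ and the phase read off as
  $\operatorname{atan2}(z, \hat c)$, which realises the arctangent plus
  quadrant detection exactly at the tracked frequency.

The raw estimate carries tick-level jitter on broadband input, which a
threshold trigger converts into systematically early, multiple firings. The
trigger therefore (i) compares a 0.15 s sliding vector average of the
quadrature pair against the target (the reported phase stays raw), (ii)
refuses to start a pulse while the previous one is still playing, and
(iii) re-arms only after the smoothed phase has demonstrably traversed the
opposite half-cycle (135°–270°) and then passed 342°, making the trigger
one-shot per cycle for any input. The smoothing window, about one eighth of
the tracked period, was chosen on SHAM-signal pilot diagnostics as the
point where trigger-phase scatter stops improving; its ~20° group lag
partly offsets the residual early-crossing bias of thresholding a noisy
phase. With these choices the circular-mean pre-onset phase at stimulus
onset is within ±30° of targets 0°, 45° and 90° on 60 s runs.

Validating delivered phase on stimulated recordings needs care: the evoked
response leaks backwards through any zero-phase offline filter, so the
acausal analytic-signal phase *at* the onset mostly reflects the evoked
wave. Assessments therefore use the pre-onset phase (a least-squares
sinusoid fit at $f_0$ over the two preceding cycles, evaluated at onset);
`offline_phase()` provides the conventional acausal reference for
un-stimulated traces and whole-trace comparisons.

## Event detection

Detection operates on the stored 100 Hz trace against the noise-paired SHAM
baseline. Slow oscillations: band-pass 0.5–1.25 Hz (order-4 Chebyshev
type-I, $10^{-6}$ dB ripple, forward–backward for zero phase), candidates
delimited by consecutive positive-to-negative zero crossings of the
z-scored filtered trace (one candidate per cycle, holding one down-peak),
then three gates — negative peak below $-10^{-6}$ in original units,
peak-to-peak above 1.25 times the SHAM mean candidate peak-to-peak, and
duration within 0.8–2 s. Spindles: z-score by the SHAM mean/SD, band-pass
9–16 Hz, moving RMS over 0.2 s smoothed by a same-length Hamming window,
and an event wherever the smoothed RMS exceeds the SHAM smoothed-RMS mean
by more than 1.25 SHAM RMS standard deviations for at least 0.5 s (the
floor is configurable; note that the two 0.2 s windows widen a burst's
suprathreshold span by roughly their combined length). The mean-plus-SD
form of the spindle threshold is the standard RMS-detector convention; a
threshold proportional to the SD alone would be permanently exceeded by
the mean RMS level of any stationary signal.

Co-occurrence matching is greedy and chronological: each spindle pairs with
the unmatched slow oscillation of greatest overlap, requiring at least
0.25 s; ties go to the earlier oscillation, and every event participates in
at most one match, so the match count never exceeds the smaller event
count. Spindle timing is summarised by the delay from the slow-oscillation
down-peak to the spindle centre, histogrammed at 0.1 s over ±1.5 s.

## Spectral indices and statistics

`morlet_scalogram()` computes the continuous wavelet transform with the
Morlet template $e^{-t^2/2} e^{i\omega_0 t}$, $\omega_0 = 15$, on 300
log-spaced scales whose pseudo-frequencies span 0.1–30 Hz, by
frequency-domain convolution under $L^2$ normalisation (the band index
below is invariant to the normalisation constant). Edge samples are
included in band sums. The stimulation effect on a band is the power
difference index

$$I = \frac{\sum_{s \in \text{band}}\sum_t |S_x| - |S_b|}
           {\sum_{s \in \text{band}}\sum_t |S_x| + |S_b|} \in [-1, 1],$$

antisymmetric under swapping the stimulated and SHAM scalograms and
invariant to common rescaling.

Scalar summaries are compared across conditions after Shapiro–Wilk
screening of both groups at $\alpha = 0.05$: Welch's t-test when neither
rejects normality, otherwise Wilcoxon (signed-rank when paired by seed,
rank-sum otherwise — the convention adopted here for unpaired groups).
Timing-delay distributions are compared with the two-sample
Kolmogorov–Smirnov test. Event rates are normalised by the analysed
duration, which excludes the 5 s stimulation-free margins.

## What the synthetic conditions do and do not show

All inputs are generated internally: the simulator itself provides the
"recordings", and the detection tests use constructed tones, bursts and
white noise with known ground truth. Passing tests therefore demonstrate
internal consistency — the integrator agrees with the analytic steady
state and transfer function, detectors recover constructed events, the
closed loop locks to its target on the model's own dynamics — but not
fidelity to human sleep EEG, which has non-stationary stage structure,
1/f background, artefacts and electrode-dependent amplitudes that the
model does not emulate. The detectors accept any uniformly sampled
single-channel series, but their thresholds are defined relative to a
paired baseline recording, which real-data use must supply.

Reduced problem sizes are used throughout the checks (60–120 s runs, two
to three seeds, against the reference setup of 910 s and five seeds);
stochastic quantities (event rates, indices, co-occurrence counts) are
asserted as orderings and bands rather than point values at this scale.

## Known limitations

* Explicit Euler with a fixed step: stable for the shipped parameters, but
  stiff user-supplied parameter sets require a smaller `dt` (the guard
  turns blow-ups into errors rather than silent garbage).
* Storage decimation applies no anti-alias filter; output power above
  50 Hz (negligible for this model, which decays steeply beyond the
  spindle band) would fold down.
* The closed-loop estimator is tuned to a single central frequency and
  degrades when the dominant rhythm wanders far from it; targets far from
  the rising zero-cross show a few tens of degrees of systematic timing
  bias, consistent with threshold-crossing statistics on a noisy phase.
* Poisson onset trains clamp inter-arrival times at the pulse duration,
  biasing the realised mean interval upward by well under 1 % at the
  default rates.
* Time-mirrored ramp pulses inject identical linear band power (time
  reversal preserves a pulse's magnitude spectrum), so the band
  power-difference indices separate the two ramps only through nonlinear
  effects. In this implementation that separation is small — about 0.01 on
  indices of 0.07–0.19, with the rising ramp marginally ahead — whereas the
  decreasing ramp produces slightly more detected events per minute at
  matched energy. Ramp rankings are therefore better read from event rates
  than from band indices here.
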