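---
title: "Model, estimators and calibration of the ELL-EGp circuit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model, estimators and calibration of the ELL-EGp circuit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ellshape)
```

This vignette is the package's account of its science: the spiking model,
the correlation estimators, the linear-response layer, how the three
non-legible strengths were calibrated, the numerical choices, and what the
test suite does and does not establish about real recordings.

## The circuit model

Three populations of leaky integrate-and-fire (LIF) neurons represent the
open-loop feedback pathway of the electrosensory lateral line lobe (ELL):

* **Deep ELL pyramidal cells** (`N_D = 800`): membrane time constant
  `tau_D = 10` ms, bias `mu_D = -56` mV, threshold `V_th = -55` mV, reset
  `V_r = -65` mV. Each neuron receives intrinsic white noise of voltage
  standard deviation `sigma = 1` mV plus electroreceptor afferent input of
  strength `g_A` (mV, calibrated). For a stimulus-locked neuron the
  afferent input splits into a common white stimulus `s(t)` with weight
  `sqrt(c)` and private noise with weight `sqrt(1 - c)`, so the afferent
  input correlation between two locked neurons is exactly `c`
  (`c = 0.1` local, `c = 0.2` global). Under local stimulation only a
  random 5% of deep neurons (chosen by the seed, membership logged) is
  locked; under global stimulation all are.
* **EGp granule cells** (`N_E = 200`): `tau_E = 10` ms, `mu_E = -60` mV,
  intrinsic noise `sigma`, driven by the pooled deep spike train with
  delta synapses of weight `J_DE / N_D` (all-to-all: the projection is
  diffuse and no connection probability is specified, so uniform pooling
  is the minimal choice).
* **Superficial ELL pyramidal cells** (`N_S = 2`, the recorded pair):
  `tau_S = 15` ms, `mu_S = -56` mV, afferent input as for locked deep
  neurons with correlation `c` across the pair, plus the feedback drive
  `(J_ES / N_E) * sum_j (alpha * y_j)(t)` with `alpha(t) =
  exp(-t / tau_s) / tau_s`, `tau_s = 5` ms, and `J_ES <= 0` (the
  stimulus-locked component of the pathway is net inhibitory; a helper,
  `effective_coupling()`, maps a mixed excitatory/inhibitory projection
  onto this single effective scalar). `feedback = FALSE` sets `J_ES = 0`.

The model stimulus is temporally white. The non-basilar (nBP) cell class
differs only in the superficial pair's receptive field: local stimuli
already saturate it, so the pair's afferent correlation is `c = 0.2` in
both scenarios while the deep drive is unchanged; the nBP-global circuit
therefore coincides with the BP-global circuit.

### Integration

Euler–Maruyama at `dt = 0.05` ms by default, noise increments scaled by
`sqrt(dt)`, initial voltages uniform on `[V_r, V_th]`, 1 s burn-in
discarded. Threshold crossings are tested at the step endpoints *and*
corrected with a Brownian-bridge excursion probability
`exp(-2 (V_th - V_0)(V_th - V_1) / s^2)` (with `s^2` the per-step noise
variance): without the correction, endpoint-only tests miss
within-step excursions and bias all rates low by `O(sqrt(dt))` (about 4%
at 0.05 ms here), which would propagate through the feedback chain and
spoil the theory–simulation agreement. With the correction, halving `dt`
moves population rates by well under 1%, so the heavier test-suite
simulations run at `dt = 0.1` ms. The simulator draws ~10^3 normal
variates per step from a seeded xoshiro256++/ziggurat generator compiled
with the package; a given seed reproduces stimulus, locked subset and all
private noise exactly.

## Estimators

Spike trains are binarised at `Delta t = 0.5` ms (one spike per bin is
enforced; the value is a package choice — it satisfies the
one-spike-per-bin premise with wide margin at the rates involved).
Covariance functions are computed on the `+-250` ms lag grid in rate
units, count series use maximally overlapping windows by default, and the
across-trial statistics average over all ordered trial pairs `k != l` of
a frozen-noise ensemble (ordered and unordered averaging have identical
means; ordered keeps the summation symmetric). A correlation with a
zero-variance count series returns `NaN` with a warning, never silently 0.

Spectra use Welch's averaged modified periodograms: Hann taper, segment
length the power of two nearest 4 s (8192 bins, resolving 0.24 Hz while
averaging ~29 segments per minute of data), 50% overlap, global (not
per-segment) mean subtraction so slow power is retained. The Fourier
convention is ordinary frequency in Hz with kernel `exp(-2 pi i f tau)`
throughout. Count statistics and spectra are linked by the squared-sinc
window kernel `(sin(pi f T) / (pi f))^2`; the three routes to a count
covariance (direct counts, triangular-kernel lag integral, sinc-kernel
spectral integral) agree to estimator tolerance and are tested against
each other.

## Linear-response layer

Single-neuron inputs are summarised by an operating point
`(mu_eff, sigma_eff)` per population:

* deep: `sigma_eff^2 = sigma^2 + g_A^2` (locked and unlocked neurons have
  the same total variance, hence one susceptibility);
* EGp: mean `mu_E + tau_E J_DE r_D`; variance adds the pooled shot noise
  `J_DE^2 r_D tau_E / (2 N_D)` and the shared stimulus-locked drive,
  membrane-filtered (effective-diffusion approximation for this coloured
  common input — using the raw drive variance instead would overestimate
  the EGp rate badly, which simulation confirms);
* superficial: mean `mu_S + tau_S J_ES r_E`; variance adds the pooled
  spontaneous EGp variability (`1/N_E`) and the stimulus-locked feedback
  component, both filtered through the synaptic kernel and the membrane.

Stationary rates come from the Siegert first-passage integral (written
with `erfcx` for numerical stability; the deterministic `sigma = 0`
branch is closed-form). The susceptibility `A(f)` and the
first-passage-time transform behind the spike-train power spectrum
`C0(f)` are computed by backward threshold integration of the
Fokker–Planck equation (RK4 on a voltage grid of ~40 points per noise
standard deviation, lower bound 6 standard deviations below the reset or
bias; the reset sits exactly on the grid). `A(0)` is evaluated
analytically as `dr/dmu`, and both `A(f) -> dr/dmu` as `f -> 0` and
`C0(f) -> r0` as `f -> infinity` are enforced by tests. Theory curves on
arbitrary grids are spline-interpolated in `log f` from a 160-point
master grid (0.1–800 Hz).

The serial feedback filter composes the stages
`F(f) = tau_S |J_ES| s~(f) A_E(f) tau_E J_DE p A_D(f) sqrt(2 tau_D) g_A
sqrt(c)`, with `s~(f) = 1 / (1 + 2 pi i f tau_s)`. Two points were
genuinely open and are resolved as follows (switches retained):

* the locked fraction enters the deep stage multiplicatively
  (`p sqrt(c)`, the default `deep_stage`), which is what the pooled-drive
  bookkeeping gives; the `sqrt(c)`-only variant is available;
* the denominator of the predicted correlation includes the
  stimulus-driven variance term (`denominator = "total"`), matching the
  measured within-trial count variance; the pure-`C0` variant is
  available.

The stimulus gain is `G(f) = A_S(f) (a_ff - Lambda F(f))` with
`a_ff = sqrt(2 tau_S) g_A sqrt(c)` and `Lambda = 1` only under global
stimulation; it is directly comparable with `estimate_gain()` output from
a simulation because the simulator returns its stimulus with unit
spectral density. The predicted pair correlation is

```
rho(T) = Int [ |G|^2 S_ss + S_shared |A_S|^2 ] K_T df /
         Int [ C0 + |G|^2 S_ss + S_shared |A_S|^2 ] K_T df ,
```

where `S_shared` is the un-cancellable common feedback noise (pooled
spontaneous EGp variability plus pooled deep shot noise relayed through
EGp, both through `s~` and the membrane). This term goes beyond the
classic gain-only prediction; it is negligible when the feedback is weak
but sets the correlation floor when the stimulus-locked component is
strongly cancelled. `include_shared_noise = FALSE` recovers the classic
formula. Above 800 Hz the spike spectrum is treated as flat at `r0` and
the window-kernel tail is integrated analytically.

## Calibration

Three strengths are not legible constants of the model and are fixed once
by `calibrate_circuit()` through the theory layer:

1. `g_A = 1.947` mV — deep population rate 36 Hz;
2. `J_ES = -6.10` mV — superficial rate 12 Hz, averaged over the local
   and global scenarios (the EGp operating point, and hence the tonic
   inhibition, is scenario-dependent, so the two scenario rates straddle
   12 Hz by about ±8%, "similar" but not identical);
3. `J_DE = 11.02` mV — near-complete cancellation of the low-frequency
   global stimulus drive, `F(0)/a_ff = 0.95`.

The third anchor deserves comment. Along the one-parameter family that
the two rate constraints leave free, the low-frequency cancellation depth
spans everything from weak attenuation to over-cancellation, and the two
regimes trade off incompatible observables: deep cancellation produces
the falling global correlation-versus-window curve and a global 50 Hz
transfer about 5% above the local 4 Hz transfer; shallow cancellation
preserves more low-frequency distractor transfer after a feedback block.
Near-complete cancellation is the regime this package adopts — it is the
stated behaviour of the pathway (the feedback is a negative image of the
stimulus) and it reproduces the correlation shaping that is the point of
the model. The consequence is owned openly: with this calibration,
removing the feedback raises the 0–10 Hz distractor-band gain power
roughly twenty-fold, so the feedback-off signal-to-noise ratios in
`snr_table()` come out near 0.05–0.09 rather than ~0.7; and the
superficial LIF susceptibility at a 12 Hz operating point falls by
~45% between 4 and 50 Hz, which caps the global-50 Hz SNR near 2.4.
These are structural properties of the Table-of-constants LIF model, not
tuning artifacts; the decision and the full trade-off surface are
recorded with the calibration code.

The signal-to-noise analysis spends exactly one further degree of
freedom: the input signal-to-distractor power ratio `kappa` is fixed so
the local-4 Hz/feedback-on SNR equals 2.3 and is then shared by all four
scenarios (whether the two signal frequencies really carried identical
input amplitudes is not recoverable; the shared-`kappa` convention is
flagged in the table attributes). The feedback-off rows drop only the
stimulus-locked filter term while keeping the intact operating point —
the tonic component of the feedback, and hence the cellular response, is
unchanged — which is what makes the local-signal transfer exactly
feedback-independent.

## What the synthetic generators do and do not emulate

`correlated_poisson_pair()` (thinning) and `cox_ensemble()` (doubly
stochastic with an exponential rate kernel, frozen stimulus, optional
trial-variable common and private modulations) exist so that every
estimator is validated against closed forms computed by independent
time-domain algebra — e.g. the count covariance of the filtered-noise
rate is `g^2 (T - tau_k (1 - exp(-T / tau_k)))`. They are
seed-deterministic, return their own ground truth, and clip negative
rates with a budget of 0.1% of bins (exceeding it is an error, because
the closed forms assume no clipping). They deliberately do *not* mimic
refractoriness, bursting, or rate nonstationarity; passing tests on them
certifies the estimators' algebra, not robustness to every feature of
real electrosensory recordings. Real spike-time tables can be analysed
through `read_spike_table()`, but the package has no spike-sorting or
thresholding layer and no hypothesis-testing layer.

## Problem sizes and numerical tolerances in the test suite

The acceptance-style tests simulate 12 seeds x 150 s for the local/global
contrast and 8 seeds x 120 s for the feedback-block and nBP variants, at
`dt = 0.1` ms (the bridge-corrected integrator is dt-insensitive at this
step; the default remains 0.05 ms). These sizes put the Monte-Carlo
standard error of the pair correlation near 0.002–0.004 per window, well
below the long-window shaping effect (~0.04) and below the short-window
effect (~0.01). Gain agreement between theory and simulation is asserted
band-averaged (1–3–10–30–100 Hz) at 10% relative with a small absolute
allowance of 3% of the gain scale where the cancelled global gain passes
near zero, since a relative criterion is vacuous at a zero crossing;
predicted correlations must sit within 3 Monte-Carlo standard errors of
the simulated means. Seeds are fixed throughout, so every reported
outcome is reproducible bit for bit.

## Known limitations

* The linear-response layer is first order: at `c = 0.2` the simulated
  short-window synchrony runs ~20–30% above the prediction, and the
  EGp rate under global stimulation is overestimated by a few percent
  (the effective-diffusion treatment of the strong shared drive is the
  weakest approximation in the chain).
* The feedback-off SNR values and the block effect at 5 ms windows
  reflect the near-complete-cancellation calibration discussed above.
* No refractory period is modelled (none is specified); at the simulated
  rates the one-spike-per-bin premise still holds with large margin.
* The closed-loop direct feedback pathway (a different cell class, with
  delay-induced oscillations) is intentionally out of scope.
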