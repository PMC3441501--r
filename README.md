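# ellshape

Correlation shaping in the electrosensory ELL–EGp feedback circuit.

In weakly electric fish, the spatial extent of an electrosensory stimulus
controls the *timescale* of correlations between superficial pyramidal
neurons of the electrosensory lateral line lobe (ELL): spatially broad
("global") stimuli increase spike synchrony at short counting windows while
*de*-correlating slow rate co-variations, relative to spatially compact
("local") stimuli. The mechanism is an open-loop feedback pathway — deep ELL
pyramidal neurons drive granule cells of the posterior eminentia granularis
(EGp), whose parallel fibers deliver a low-pass, net-inhibitory "negative
image" of the stimulus back onto superficial pyramidal neurons. Global
stimuli recruit this cancellation signal; local stimuli do not.

`ellshape` provides the complete computational chain for this problem:

- **`ell_circuit()` / `simulate()`** — a three-population leaky
  integrate-and-fire (LIF) network (800 deep, 200 EGp, 2 superficial
  neurons; Euler–Maruyama with a Brownian-bridge threshold correction,
  compiled in C++) under local/global stimulation, basilar (BP) or
  non-basilar (nBP) receptive-field variants, with the feedback pathway
  intact or blocked.
- **Spike-train statistics** — binarisation, covariance functions
  `c_ij(τ)`, windowed spike-count correlations `ρ(T)` (within- and
  across-trial, for frozen-noise protocols), Welch cross-spectra
  `C_ij(f)`, the count–spectrum relations
  `Var N(T) = ∫ C(f) (sin(πfT)/(πf))² df`, and stimulus-gain estimation
  `G(f) = S_ys(f)/S_ss(f)`.
- **`predict()` (linear-response theory)** — stationary rates (Siegert),
  cellular susceptibility `A(f)` and spike-train spectrum `C₀(f)` by
  Fokker–Planck threshold integration, the serial feedback filter
  `F(f) = τ_S|J_ES| s̃(f) A_E(f) τ_E J_DE p A_D(f) √(2τ_D) g_A √c`, the
  stimulus gain `G(f) = A_S(f)(a_ff − ΛF(f))`, and the predicted
  correlation `ρ(T)` from sinc-kernel integrals of `|G|²S_ss` and `C₀`.
- **`snr_table()`** — the signal-versus-distractor analysis: the linearised
  population response to a 4 Hz local or 50 Hz global sine in the presence
  of a flat 0–10 Hz global distractor, with and without feedback.
- **Synthetic generators** — thinned correlated Poisson pairs and
  doubly-stochastic (Cox) ensembles with closed-form statistics, so every
  estimator is validated against an independent ground truth.

Spike-time tables (CSV: `neuron_id, trial_id, spike_time_s`) and stimulus
traces can be read and written with `read_spike_table()` /
`write_stimulus_trace()` and friends, so recorded data can be analysed with
the same estimators.

## Worked example

```r
library(ellshape)
circ <- ell_circuit("global")           # calibrated Table-1 parameters
sim  <- simulate(circ, seed = 1, duration = 60, dt = 1e-4)
sim
#> <ell_sim> global/BP/feedback on: 1 trial(s) x 60.0 s (dt 0.1 ms)
#>   mean rates: deep 36.4 Hz, EGp 24.2 Hz, superficial 10.9 Hz

correlation_curve(sim$superficial, 1, 2,
                  windows_T = c(0.005, 0.02, 0.1, 0.2), stride = 0.002)
#> <correlation_curve> (within_trial)
#>  T_ms     rho
#>     5 0.02381
#>    20 0.02121
#>   100 0.01458
#>   200 0.01439

predict(circ, type = "rho", T_grid = c(0.005, 0.02, 0.1, 0.2))
#> <correlation_curve> (predicted)
#>  T_ms      rho
#>     5 0.016720
#>    20 0.015780
#>   100 0.006807
#>   200 0.005247
```

The deep population fires near 36 Hz and the superficial pair near 11–13 Hz
(local/global average 12 Hz), as the calibration targets. Under global
stimulation the pair's count correlation *falls* with window length — the
recruited EGp feedback cancels the slow common signal — whereas a local
simulation (`ell_circuit("local")`) shows the opposite, rising profile.
The linear-response prediction reproduces the simulated curve shape; at
short windows the spiking network carries somewhat more synchrony than the
first-order theory.

```r
snr_table(circ)
#>         signal frequency_hz extent feedback        snr
#> 1   4 Hz local            4  local     TRUE 2.30000000
#> 2   4 Hz local            4  local    FALSE 0.08707098
#> 3 50 Hz global           50 global     TRUE 2.41052339
#> 4 50 Hz global           50 global    FALSE 0.05233570
```

With feedback intact the population transmits a local 4 Hz signal (SNR 2.3,
the κ-calibration anchor) and a global 50 Hz signal (SNR 2.4) well above
the 0–10 Hz global distractor; removing the feedback lets the distractor
through and collapses both SNRs.

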