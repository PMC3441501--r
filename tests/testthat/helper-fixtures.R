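# shared fixtures: small deterministic spike trains and generators

# homogeneous Poisson train on the bin grid (at most one spike per bin)
poisson_train <- function(rate, duration, seed, bin_width = 5e-4) {
  set.seed(seed)
  n <- floor(duration / bin_width)
  bins <- runif(n) < rate * bin_width
  spike_train((which(bins) - 0.5) * bin_width, duration, bin_width)
}

toy_train <- function(times_ms, duration_ms, bin_ms = 1) {
  spike_train(times_ms * 1e-3, duration_ms * 1e-3, bin_ms * 1e-3)
}

# direct-summation cross-covariance oracle, the definition evaluated by
# explicit loops over lag and time bins (independent of the FFT path)
brute_cross_cov <- function(a, b, max_lag) {
  dt <- a$bin_width
  ya <- bin_spikes(a) / dt
  yb <- bin_spikes(b) / dt
  n <- length(ya)
  m <- round(max_lag / dt)
  vals <- sapply(-m:m, function(lag) {
    s <- 0
    for (bb in seq_len(n)) {
      j <- bb + lag
      if (j >= 1 && j <= n) s <- s + ya[bb] * yb[j]
    }
    s / n - mean(ya) * mean(yb)
  })
  list(lags = (-m:m) * dt, values = vals)
}

# circuit with small populations for fast structural tests
small_circuit <- function(scenario = "global", feedback = TRUE, ...) {
  ell_circuit(scenario, "BP", feedback,
              ell_params(N_D = 40L, N_E = 20L, ...))
}
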