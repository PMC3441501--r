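test_that("Poisson power spectrum is flat at the firing rate", {
  tr <- poisson_train(40, 120, seed = 4)
  S <- estimate_spectra(tr)
  expect_true(all(Re(S$values) >= 0))
  expect_true(all(Im(S$values) == 0))
  band <- S$f > 10 & S$f < 800
  expect_equal(mean(Re(S$values[band])), firing_rate(tr), tolerance = 0.05)
})

test_that("total spectral power matches the time-domain variance", {
  tr <- poisson_train(35, 60, seed = 6)
  S <- estimate_spectra(tr)
  x <- bin_spikes(tr) / tr$bin_width
  # two-sided integral over [-Nyquist, Nyquist]
  total <- 2 * pracma::trapz(S$f, Re(S$values))
  expect_equal(total, stats::var(x), tolerance = 0.03)
})

test_that("cross-spectra are Hermitian-consistent and invertible to counts", {
  pair <- correlated_poisson_pair(30, 0.5, 60, seed = 10)
  Sab <- estimate_spectra(pair$a, pair$b)
  Sba <- estimate_spectra(pair$b, pair$a)
  expect_equal(Sab$values, Conj(Sba$values), tolerance = 1e-10)

  # zero-frequency limit: for large T the count covariance approaches
  # T * C(0) (kernel narrows onto the origin)
  expect_error(count_stats_from_spectra(Sab, 10), "too coarse")
})

test_that("white-noise spectral density of the stimulus objects is one", {
  stim <- make_stimulus("white", duration = 60, dt = 5e-4, seed = 3)
  S <- estimate_spectra(stim)
  # unit-variance samples at dt: two-sided density = dt * var = dt
  expect_equal(mean(Re(S$values[S$f > 5])), stim$dt_sample,
               tolerance = 0.05)
})

test_that("gain estimation recovers the generator's known filter", {
  spec <- cox_pair_spec(r0 = 36, tau_k = 0.02, g_common = 2,
                        duration = 400, seed = 17)
  ce <- cox_ensemble(spec)
  G <- estimate_gain(ce$ensemble$trains[[1]][[1]], ce$stimulus)
  truth <- cox_ground_truth(spec, f = G$f)$gain
  # band-average the complex gain (single Welch bins carry noise of
  # sd ~ sqrt(S_yy / n_seg), which would bias per-bin moduli upward)
  edges <- c(0.5, 4, 8, 16, 40)
  for (b in seq_len(length(edges) - 1)) {
    sel <- G$f >= edges[b] & G$f < edges[b + 1]
    g_est <- mean(G$values[sel])
    g_true <- mean(truth$values[sel])
    expect_lt(Mod(g_est - g_true) / Mod(g_true), 0.10)
  }
})

test_that("gain of a stimulus-independent train is indistinguishable from zero", {
  tr <- poisson_train(30, 60, seed = 23)
  stim <- make_stimulus("white", 60, dt = 5e-4, seed = 24)
  G <- estimate_gain(tr, stim)
  band <- G$f > 1 & G$f < 100
  # per-bin estimator noise: sqrt(S_yy / (S_ss n_seg)); the complex band
  # mean shrinks it by sqrt(#bins)
  S_yy <- mean(Re(estimate_spectra(tr)$values[band]))
  S_ss <- mean(Re(estimate_spectra(stim)$values[band]))
  sd_bin <- sqrt(S_yy / (S_ss * G$n_seg))
  expect_lt(Mod(mean(G$values[band])), 4 * sd_bin / sqrt(sum(band)))
})

test_that("gain-based count covariance predictions are exact for known gains", {
  f <- seq(0, 600, by = 0.05)
  zero <- structure(list(f = f, values = rep(0 + 0i, length(f)),
                         provenance = "theory"), class = "gain_fun")
  flatS <- structure(list(f = f, values = rep(1 + 0i, length(f)),
                          dt = 5e-4, seg_len = NA, n_seg = NA,
                          kind = "power"),
                     class = "spectral_density")
  expect_equal(predict_count_cov_from_gains(zero, zero, flatS, 0.1), 0)

  # Lorentzian gain pair: sinc-kernel integral has the closed form
  # g^2 (T - tau (1 - exp(-T / tau)))
  tau <- 0.02; g <- 1.5
  lor <- zero
  lor$values <- g / (1 + 2i * pi * f * tau)
  for (T in c(0.01, 0.05, 0.2)) {
    got <- predict_count_cov_from_gains(lor, lor, flatS, T)
    expect_equal(got, g^2 * (T - tau * (1 - exp(-T / tau))),
                 tolerance = 0.01)
  }
  # real-valued for Hermitian input by construction
  expect_true(is.numeric(predict_count_cov_from_gains(lor, lor, flatS, 0.1)))

  expect_equal(
    predict_across_trial_rho(lor, lor, flatS, 2, 2, 0.05),
    predict_count_cov_from_gains(lor, lor, flatS, 0.05) / 2)
  expect_warning(
    r <- predict_across_trial_rho(lor, lor, flatS, 0, 1, 0.05), "zero")
  expect_true(is.nan(r))
})
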