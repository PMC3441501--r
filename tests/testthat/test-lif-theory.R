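test_that("stationary LIF rate: deterministic limits and Siegert branch", {
  expect_equal(lif_rate(-57, 0, 0.01), 0)
  mu <- -52
  expect_equal(lif_rate(mu, 0, 0.01),
               1 / (0.01 * log((mu + 65) / (mu + 55))))
  # far-subthreshold noisy neuron is silent
  expect_equal(lif_rate(-80, 1, 0.01), 0)
  expect_error(lif_rate(NaN, 1, 0.01))

  # Siegert integral agrees with the Fokker-Planck stationary solution
  for (prm in list(c(-56, 2.2, 0.010), c(-57.5, 1.5, 0.015),
                   c(-54.5, 1.0, 0.010))) {
    r_sie <- lif_rate(prm[1], prm[2], prm[3])
    r_fp <- lif_linear_response(prm[1], prm[2], prm[3], f = 1)$r0
    expect_equal(r_fp, r_sie, tolerance = 2e-3)
  }
})

test_that("stationary rate matches a long direct simulation", {
  # single-population check through the network simulator: deep neurons
  # with uncorrelated afferent input of known total strength
  circ <- ell_circuit("global", "BP", TRUE,
                      ell_params(N_D = 60L, N_E = 1L, N_S = 1L,
                                 J_DE = 0, J_ES = 0))
  sim <- simulate(circ, seed = 5, duration = 60, dt = 5e-5)
  r_sim <- population_rates(sim)[["deep"]]
  r_th <- lif_rate(-56, sqrt(1 + circ$params$g_A^2), 0.010)
  expect_equal(r_sim, r_th, tolerance = 0.03)
})

test_that("susceptibility obeys the fluctuation-response relation at f -> 0", {
  mu <- -56.5; sig <- 2.0; tau <- 0.012
  lr <- lif_linear_response(mu, sig, tau, f = c(0, 0.1, 1))
  dmu <- 1e-3
  slope <- (lif_rate(mu + dmu, sig, tau) - lif_rate(mu - dmu, sig, tau)) /
    (2 * dmu)
  expect_equal(Re(lr$A[1]), slope, tolerance = 0.01)
  # continuity: the 0.1 Hz value approaches the analytic limit
  expect_equal(Mod(lr$A[2]), slope, tolerance = 0.01)
})

test_that("susceptibility is low-pass and the spectrum approaches the rate", {
  lr <- lif_linear_response(-56, 2.2, 0.015,
                            f = c(1, 100, 500, 2000))
  expect_lt(Mod(lr$A[3]), Mod(lr$A[1]))
  expect_true(all(lr$C0 >= 0))
  expect_equal(lr$C0[4], lr$r0, tolerance = 0.02)
})

test_that("theory spectrum and susceptibility match Welch estimates from simulation", {
  # 80 uncoupled neurons, 60 s: population-averaged spectrum vs C0
  prm <- ell_params(N_D = 80L, N_E = 1L, N_S = 1L, J_DE = 0, J_ES = 0)
  circ <- ell_circuit("global", "BP", TRUE, prm)
  sim <- simulate(circ, seed = 8, duration = 60, dt = 5e-5)
  acc <- NULL
  for (tr in sim$deep$trains[[1]]) {
    S <- estimate_spectra(tr)
    acc <- if (is.null(acc)) Re(S$values) else acc + Re(S$values)
    f <- S$f
  }
  acc <- acc / 80
  lr <- lif_linear_response(-56, sqrt(1 + prm$g_A^2), 0.010,
                            f = f[f > 0.4 & f < 400])
  sim_band <- sapply(seq_along(lr$f), function(i) {
    sel <- abs(f - lr$f[i]) <= max(0.5, 0.05 * lr$f[i])
    mean(acc[sel])
  })
  expect_lt(stats::median(abs(sim_band / lr$C0 - 1)), 0.10)

  # gain of the locked common component recovers A_D times the drive
  sp <- NULL
  stim <- sim$stimulus[[1]]
  Sss <- estimate_spectra(stim)
  for (tr in sim$deep$trains[[1]]) {
    Sys <- estimate_spectra(stim, tr)
    sp <- if (is.null(sp)) Sys$values else sp + Sys$values
  }
  G <- (sp / 80) / Sss$values
  drive <- sqrt(2 * 0.010) * prm$g_A * sqrt(circ$c_deep)
  th <- lr$A * drive
  band <- lr$f >= 1 & lr$f <= 100
  sim_g <- sapply(which(band), function(i) {
    sel <- abs(f - lr$f[i]) <= max(0.5, 0.1 * lr$f[i])
    mean(Mod(G[sel])^2)^0.5
  })
  expect_lt(stats::median(abs(sim_g / Mod(th[band]) - 1)), 0.10)
})

test_that("the serial feedback filter is low-pass with a real DC value", {
  circ <- ell_circuit("global")
  f <- c(0.1, 1, 10, 100)
  op <- operating_point(circ, f)
  Ff <- feedback_filter(circ, f, op)
  expect_lt(Mod(Ff$values[4]), Mod(Ff$values[2]))
  expect_lt(abs(Arg(Ff$values[1])), 0.05)
  expect_gt(Re(Ff$values[1]), 0)
  # infinite synaptic smoothing kills all finite-frequency transfer
  circ_slow <- ell_circuit("global", "BP", TRUE, ell_params(tau_s = 50))
  Fs <- feedback_filter(circ_slow, f, operating_point(circ_slow, f))
  expect_lt(Mod(Fs$values[3]) / Mod(Ff$values[3]), 0.02)
  # monotone non-increasing modulus above the synaptic corner
  fm <- c(40, 80, 160, 320)
  Fm <- feedback_filter(circ, fm, operating_point(circ, fm))
  expect_true(all(diff(Mod(Fm$values)) < 0))
})

test_that("stimulus gains compose the afferent and feedback stages correctly", {
  f <- c(0.5, 2, 10, 40, 100)
  pr <- ell_params()
  circL <- ell_circuit("local", "BP", TRUE, pr)
  circG <- ell_circuit("global", "BP", TRUE, pr)
  circGoff <- ell_circuit("global", "BP", FALSE, pr)
  GL <- stimulus_gain(circL, f)
  opG <- operating_point(circG, f)
  GG <- stimulus_gain(circG, f, opG)
  # local gain is the pure cellular response times the afferent drive
  a_L <- sqrt(2 * pr$tau_S) * pr$g_A * sqrt(circL$c_sup)
  opL <- operating_point(circL, f)
  expect_equal(GL$values, opL$sup$A * a_L, tolerance = 1e-10)
  # feedback-off against the local gain at the same operating point:
  # the shared cellular response cancels, leaving the flat sqrt(c) ratio
  Goff <- stimulus_gain(circGoff, f, opG)
  GL_at_opG <- stimulus_gain(circL, f, opG)
  expect_equal(Mod(Goff$values / GL_at_opG$values),
               rep(sqrt(circG$c_sup / circL$c_sup), length(f)),
               tolerance = 1e-6)
  # near-complete DC cancellation: global gain strongly attenuated at
  # low frequency but not at high frequency
  expect_lt(Mod(GG$values[1]) / Mod(GL$values[1]), 0.5)
  expect_gt(Mod(GG$values[5]) / Mod(GL$values[5]), 1.1)
})

test_that("predicted correlation vanishes without common input or gain", {
  # the stimulus-locked part vanishes with the input correlation or the
  # afferent strength; the shared feedback-noise term is switched off so
  # the Eq-style prediction is exactly zero
  pr0 <- ell_params(c_local = 0, p_local = 0.05)
  rho0 <- predict_rho(ell_circuit("local", "BP", TRUE, pr0),
                      c(0.01, 0.1), include_shared_noise = FALSE)
  expect_equal(rho0$rho, c(0, 0), tolerance = 1e-12)

  prg <- ell_params(g_A = 0)
  rhog <- predict_rho(ell_circuit("local", "BP", TRUE, prg), c(0.01, 0.1),
                      include_shared_noise = FALSE)
  expect_equal(rhog$rho, c(0, 0), tolerance = 1e-12)

  # with the pathway intact, its pooled spontaneous variability still
  # correlates the pair weakly even without any stimulus
  rho_shared <- predict_rho(ell_circuit("local", "BP", TRUE, prg),
                            c(0.01, 0.1))
  expect_true(all(rho_shared$rho > 0))

  rho <- predict_rho(ell_circuit("global"), c(0.002, 0.02, 0.2, 0.4))
  expect_true(all(rho$rho > -1 & rho$rho < 1))
})

test_that("mixed excitatory/inhibitory projections reduce to a net coupling", {
  expect_equal(effective_coupling(0, 1, 2), -2)
  expect_equal(effective_coupling(0.25, 2, 2), -1)
  expect_equal(effective_coupling(1, 3, 5), 3)
  expect_error(effective_coupling(1.2, 1, 1))
})
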