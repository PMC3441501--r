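test_that("simulations are seed-deterministic", {
  circ <- small_circuit("global")
  s1 <- simulate(circ, seed = 42, duration = 4, dt = 1e-4)
  s2 <- simulate(circ, seed = 42, duration = 4, dt = 1e-4)
  expect_identical(s1$superficial$trains[[1]][[1]]$times,
                   s2$superficial$trains[[1]][[1]]$times)
  expect_identical(s1$deep$trains[[1]][[5]]$times,
                   s2$deep$trains[[1]][[5]]$times)
  expect_identical(s1$locked, s2$locked)
  s3 <- simulate(circ, seed = 43, duration = 4, dt = 1e-4)
  expect_false(identical(s1$superficial$trains[[1]][[1]]$times,
                         s3$superficial$trains[[1]][[1]]$times))
})

test_that("subthreshold deterministic network stays silent", {
  circ <- ell_circuit("global", "BP", TRUE,
                      ell_params(N_D = 10L, N_E = 5L, sigma = 0, g_A = 0,
                                 J_DE = 0, J_ES = 0))
  sim <- simulate(circ, seed = 1, duration = 2, dt = 1e-4, burn_in = 0.1)
  expect_equal(population_rates(sim), c(deep = 0, egp = 0, superficial = 0))
})

test_that("noiseless suprathreshold neurons fire at the closed-form period", {
  # deep bias above threshold, no noise or stimulus: regular oscillator
  mu <- -53
  circ <- ell_circuit("global", "BP", TRUE,
                      ell_params(N_D = 3L, N_E = 1L, N_S = 1L, sigma = 0,
                                 g_A = 0, J_DE = 0, J_ES = 0, mu_D = mu))
  sim <- simulate(circ, seed = 2, duration = 5, dt = 2e-5)
  isi <- diff(sim$deep$trains[[1]][[1]]$times)
  period <- 0.010 * log((mu + 65) / (mu + 55))
  expect_lt(max(abs(isi - period)), 3 * 2e-5)
})

test_that("halving the integration step leaves population rates unchanged", {
  # a 100-neuron superficial population tightens the Monte-Carlo error on
  # the smallest population's rate without changing per-neuron dynamics
  circ <- ell_circuit("global", "BP", TRUE, ell_params(N_S = 100L))
  rates_at <- function(dt)
    rowMeans(sapply(1:4, function(sd)
      population_rates(simulate(circ, seed = sd, duration = 40,
                                dt = dt))))
  r1 <- rates_at(1e-4)
  r2 <- rates_at(5e-5)
  expect_lt(max(abs(r2 / r1 - 1)), 0.02)
  # superficial rates sit below deep rates in both scenarios
  expect_lt(r1[["superficial"]], r1[["deep"]])
  rl <- population_rates(simulate(scenario_circuit("local"), seed = 3,
                                  duration = 25, dt = 1e-4))
  expect_lt(rl[["superficial"]], rl[["deep"]])
})

test_that("the locked deep subset follows the scenario and the seed", {
  circL <- ell_circuit("local")
  simL <- simulate(circL, seed = 4, duration = 2, dt = 1e-4)
  expect_length(simL$locked, round(0.05 * 800))
  expect_true(all(simL$locked >= 1 & simL$locked <= 800))
  simL2 <- simulate(circL, seed = 4, duration = 2, dt = 1e-4)
  expect_identical(simL$locked, simL2$locked)
  simG <- simulate(ell_circuit("global"), seed = 4, duration = 2,
                   dt = 1e-4)
  expect_length(simG$locked, 800)
})

test_that("the returned stimulus is white with unit spectral density", {
  sim <- simulate(small_circuit("global"), seed = 6, duration = 30,
                  dt = 1e-4)
  S <- estimate_spectra(sim$stimulus[[1]])
  expect_equal(mean(Re(S$values[S$f > 5])), 1, tolerance = 0.05)
})

test_that("feedback drive is zero when blocked and reconstructible when on", {
  off <- simulate(small_circuit("global", feedback = FALSE), seed = 7,
                  duration = 2, dt = 1e-4)
  expect_true(all(feedback_current(off) == 0))

  on <- simulate(small_circuit("global"), seed = 7, duration = 3,
                 dt = 1e-4, feedback_full = TRUE)
  rec <- reconstruct_feedback(on)
  full <- on$feedback_full[[1]]
  # ignore the initial span where the burn-in synaptic state decays away
  skip <- round(0.2 / on$dt)
  expect_lt(max(abs(rec[-(1:skip)] - full[-(1:skip)])), 1e-8)
  # the binned trace is the bin average of the full-resolution trace
  k <- round(on$bin_width / on$dt)
  binned <- colMeans(matrix(full, nrow = k))
  expect_equal(as.numeric(feedback_current(on)), binned,
               tolerance = 1e-10)
})

test_that("EGp feedback locks to the stimulus under global but not local input", {
  coh_low <- function(scenario) {
    sim <- simulate(scenario_circuit(scenario), seed = 8, duration = 40,
                    dt = 1e-4)
    fb <- feedback_current(sim)
    stim <- sim$stimulus[[1]]
    S_fs <- estimate_spectra(stim, fb)
    S_ff <- estimate_spectra(fb)
    S_ss <- estimate_spectra(stim)
    band <- S_fs$f > 0.5 & S_fs$f < 20
    mean(Mod(S_fs$values[band])^2 /
           (Re(S_ff$values[band]) * Re(S_ss$values[band])))
  }
  expect_gt(coh_low("global"), 3 * coh_low("local"))
})

test_that("deep population synchrony tracks the stimulated fraction", {
  simL <- simulate(scenario_circuit("local"), seed = 9, duration = 20,
                   dt = 1e-4)
  simG <- simulate(scenario_circuit("global"), seed = 9, duration = 20,
                   dt = 1e-4)
  rhoL <- deep_population_summary(simL, n_pairs = 40L)
  rhoG <- deep_population_summary(simG, n_pairs = 40L)
  expect_lt(rhoL, rhoG)
  expect_gt(rhoG, 0.05)

  # without afferent drive the deep population is uncorrelated
  sim0 <- simulate(ell_circuit("global", "BP", TRUE,
                               ell_params(N_D = 60L, N_E = 5L, g_A = 0)),
                   seed = 10, duration = 20, dt = 1e-4)
  expect_lt(abs(deep_population_summary(sim0, n_pairs = 30L)), 0.02)
})
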