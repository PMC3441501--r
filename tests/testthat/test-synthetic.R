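test_that("thinned Poisson pairs hit the designed count correlation", {
  p0 <- correlated_poisson_pair(20, 0, 100, seed = 1)
  c0 <- suppressWarnings(count_correlation(
    spike_counts(p0$a, 0.1, 0.01), spike_counts(p0$b, 0.1, 0.01)))
  expect_lt(abs(c0), 0.05)

  p1 <- correlated_poisson_pair(20, 1, 50, seed = 2)
  expect_identical(p1$a$times, p1$b$times)
  expect_equal(suppressWarnings(count_correlation(
    spike_counts(p1$a, 0.05, 0.05), spike_counts(p1$b, 0.05, 0.05))), 1)

  p3 <- correlated_poisson_pair(20, 0.3, 200, seed = 3)
  rho <- suppressWarnings(count_correlation(
    spike_counts(p3$a, 0.2, 0.02), spike_counts(p3$b, 0.2, 0.02)))
  # thinning construction: expected correlation is exactly c_share
  expect_lt(abs(rho - 0.3), 0.04)

  expect_error(correlated_poisson_pair(-5, 0.3, 10), "r > 0")
})

test_that("Cox ensembles are deterministic and return their ground truth", {
  spec <- cox_pair_spec(r0 = 40, tau_k = 0.02, g_common = 1.6,
                        duration = 20, n_trials = 2L, seed = 11)
  ce1 <- cox_ensemble(spec)
  ce2 <- cox_ensemble(spec)
  expect_identical(ce1$ensemble$trains[[1]][[1]]$times,
                   ce2$ensemble$trains[[1]][[1]]$times)
  expect_identical(ce1$stimulus$samples, ce2$stimulus$samples)
  expect_s3_class(ce1$truth$gain, "gain_fun")
  expect_lt(ce1$clip_fraction, 1e-3)

  # excessive modulation depth violates the clipping budget
  expect_error(cox_ensemble(cox_pair_spec(r0 = 10, g_common = 20,
                                          duration = 5, seed = 1)),
               "clipping")
})

test_that("Cox pair statistics follow the closed-form ground truth", {
  # same filter, no private modulation: within-trial equals across-trial
  spec <- cox_pair_spec(r0 = 40, tau_k = 0.02, g_common = 2.5,
                        g_private = 0, duration = 150, n_trials = 2L,
                        seed = 5)
  ce <- cox_ensemble(spec)
  Tg <- c(0.005, 0.05, 0.2)
  truth <- cox_ground_truth(spec, Tg)
  within <- correlation_curve(ce$ensemble, 1, 2, Tg,
                              kind = "within_trial", stride = 2e-3)
  across <- correlation_curve(ce$ensemble, 1, 2, Tg,
                              kind = "across_trial", stride = 2e-3)
  expect_equal(within$rho, truth$rho, tolerance = 0.15)
  expect_equal(across$rho, truth$rho, tolerance = 0.15)
  expect_lt(max(abs(within$rho - across$rho)), 0.06)

  # no common drive: gain and across-trial correlation go to zero
  spec0 <- cox_pair_spec(r0 = 40, tau_k = 0.02, g_common = 0,
                         g_private = 2, duration = 60, n_trials = 2L,
                         seed = 6)
  ce0 <- cox_ensemble(spec0)
  G0 <- estimate_gain(ce0$ensemble$trains[[1]][[1]], ce0$stimulus)
  # complex band mean beats the per-bin noise floor down by sqrt(#bins)
  expect_lt(Mod(mean(G0$values[G0$f > 1 & G0$f < 100])), 0.3)
  expect_lt(abs(across_trial_correlation(ce0$ensemble, 1, 2, 0.1)), 0.05)
})

test_that("trial-variable common input raises within- above across-trial rho", {
  spec <- cox_pair_spec(r0 = 40, tau_k = 0.02, g_common = 1.4,
                        g_trial = 1.4, duration = 120, n_trials = 3L,
                        seed = 7)
  ce <- cox_ensemble(spec)
  Tg <- c(0.05, 0.2)
  truth <- cox_ground_truth(spec, Tg)
  within <- correlation_curve(ce$ensemble, 1, 2, Tg,
                              kind = "within_trial", stride = 5e-3)
  across <- correlation_curve(ce$ensemble, 1, 2, Tg,
                              kind = "across_trial", stride = 5e-3)
  # the trial-variable common modulation doubles the within-trial
  # covariance but leaves the across-trial (signal) covariance untouched
  expect_true(all(within$rho > across$rho))
  expect_equal(within$rho, truth$rho_within, tolerance = 0.15)
  expect_equal(across$rho, truth$rho, tolerance = 0.2)
})
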