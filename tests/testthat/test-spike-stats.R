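test_that("cross-covariance matches the direct-summation definition", {
  a <- toy_train(c(1, 3, 5), 10)
  b <- toy_train(c(2, 4, 6), 10)
  cc <- cross_covariance(a, b, max_lag = 4e-3)
  oracle <- brute_cross_cov(a, b, 4e-3)
  expect_equal(cc$lags, oracle$lags)
  expect_equal(cc$values, oracle$values, tolerance = 1e-10)

  # time-reversal symmetry c_ab(tau) = c_ba(-tau)
  cc_rev <- cross_covariance(b, a, max_lag = 4e-3)
  expect_equal(cc$values, rev(cc_rev$values), tolerance = 1e-10)
})

test_that("auto-covariance at zero lag carries the binned point-process mass", {
  tr <- poisson_train(30, 20, seed = 2)
  ac <- cross_covariance(tr, tr, max_lag = 5e-3)
  r <- firing_rate(tr)
  dt <- tr$bin_width
  i0 <- which(ac$lags == 0)
  # empirical bin variance: exactly p(1-p)/dt^2 with p the bin occupancy
  p_occ <- mean(bin_spikes(tr))
  expect_equal(ac$values[i0], p_occ * (1 - p_occ) / dt^2,
               tolerance = 1e-9)
  # delta-mass approximation r/dt - r^2 for sparse trains
  expect_equal(ac$values[i0], r / dt - r^2, tolerance = 0.02)
})

test_that("independent trains have near-zero cross-covariance", {
  a <- poisson_train(5, 100, seed = 21)
  b <- poisson_train(5, 100, seed = 22)
  cc <- cross_covariance(a, b, max_lag = 0.05)
  # analytic estimator scale: var(c_hat) ~ r_a r_b / (T dt)
  se <- sqrt(5 * 5 / (100 * a$bin_width))
  expect_lt(max(abs(cc$values)), 4 * se)
})

test_that("across-trial covariance equals the ordered-pair average", {
  set.seed(9)
  trials <- lapply(1:3, function(k)
    list(poisson_train(20, 4, seed = 30 + k),
         poisson_train(25, 4, seed = 60 + k)))
  ens <- trial_ensemble(trials)
  got <- across_trial_covariance(ens, 1, 2, max_lag = 10e-3)

  # oracle: explicit loop over the 6 ordered trial pairs, each by the
  # direct-summation covariance of mean-subtracted binned trains
  dt <- ens$bin_width
  m <- round(10e-3 / dt)
  oracle <- 0
  npairs <- 0
  for (k in 1:3) for (l in 1:3) {
    if (k == l) next
    ya <- bin_spikes(trials[[k]][[1]]) / dt
    yb <- bin_spikes(trials[[l]][[2]]) / dt
    ya <- ya - mean(ya); yb <- yb - mean(yb)
    n <- length(ya)
    vals <- sapply(-m:m, function(lag) {
      idx <- seq_len(n)
      j <- idx + lag
      ok <- j >= 1 & j <= n
      sum(ya[idx[ok]] * yb[j[ok]]) / n
    })
    oracle <- oracle + vals
    npairs <- npairs + 1
  }
  expect_equal(got$values, oracle / npairs, tolerance = 1e-10)
})

test_that("across-trial statistics isolate the stimulus-locked component", {
  # trains identical across trials (fully stimulus-determined):
  # across-trial equals within-trial covariance
  a <- poisson_train(20, 10, seed = 41)
  b <- poisson_train(22, 10, seed = 42)
  ens <- trial_ensemble(list(list(a, b), list(a, b), list(a, b)))
  at <- across_trial_covariance(ens, 1, 2, max_lag = 20e-3)
  wt <- cross_covariance(a, b, max_lag = 20e-3)
  # within-trial subtracts the rate product; across subtracts per-trial
  # means: identical up to the O(max_lag / N) edge term
  expect_equal(at$values, wt$values, tolerance = 0.01)
  expect_equal(across_trial_correlation(ens, 1, 2, 0.1, stride = 0.01),
               suppressWarnings(count_correlation(
                 spike_counts(a, 0.1, 0.01), spike_counts(b, 0.1, 0.01))),
               tolerance = 1e-9)

  # trains independent of the stimulus (fresh noise each trial): ~ 0
  trials <- lapply(1:3, function(k)
    list(poisson_train(20, 20, seed = 100 + k),
         poisson_train(20, 20, seed = 200 + k)))
  ens2 <- trial_ensemble(trials)
  at2 <- across_trial_covariance(ens2, 1, 2, max_lag = 20e-3)
  se <- sqrt(20 * 20 / (20 * ens2$bin_width)) / sqrt(6)
  expect_lt(max(abs(at2$values)), 5 * se)
  expect_lt(abs(across_trial_correlation(ens2, 1, 2, 0.1)), 0.1)

  expect_error(across_trial_covariance(
    trial_ensemble(list(list(a, b))), 1, 2, 0.02), "two trials")
})

test_that("count covariance from the covariance function: analytic cases", {
  dt <- 5e-4
  lags <- seq(-0.05, 0.05, by = dt)
  zero <- structure(list(lags = lags, values = rep(0, length(lags)),
                         bin_width = dt, kind = "within_trial"),
                    class = "cov_fun")
  expect_equal(count_cov_from_covfun(zero, 0.02), 0)

  # single lag-zero mass v (discrete delta): integral = T * v * dt
  v <- 120
  delta <- zero
  delta$values[lags == 0] <- v
  expect_equal(count_cov_from_covfun(delta, 0.02), 0.02 * v * dt)

  expect_error(count_cov_from_covfun(zero, 1), "lag range")
})

test_that("count statistics agree across the three computation routes", {
  # direct count covariance (counts), triangular-kernel integral of the
  # covariance function, and sinc-kernel integral of the cross-spectrum
  # must agree on the same data
  pair <- correlated_poisson_pair(25, 0.3, 120, seed = 8)
  T <- 0.05
  direct <- stats::cov(spike_counts(pair$a, T, stride = 5e-3)$counts,
                       spike_counts(pair$b, T, stride = 5e-3)$counts)
  from_cov <- count_cov_from_covfun(
    cross_covariance(pair$a, pair$b, max_lag = 0.1), T)
  S <- estimate_spectra(pair$a, pair$b)
  from_spec <- count_stats_from_spectra(S, T)
  expect_equal(from_cov, direct, tolerance = 0.1)
  expect_equal(from_spec, direct, tolerance = 0.1)

  # and the variance route
  v_direct <- stats::var(spike_counts(pair$a, T, stride = 5e-3)$counts)
  v_cov <- count_cov_from_covfun(
    cross_covariance(pair$a, pair$a, max_lag = 0.1), T)
  v_spec <- count_stats_from_spectra(estimate_spectra(pair$a), T)
  expect_equal(v_cov, v_direct, tolerance = 0.1)
  expect_equal(v_spec, v_direct, tolerance = 0.1)
})

test_that("correlation curves stay in [-1, 1] across window sizes", {
  pair <- correlated_poisson_pair(30, 0.4, 30, seed = 15)
  ens <- trial_ensemble(list(list(pair$a, pair$b)))
  cc <- correlation_curve(ens, 1, 2, c(0.002, 0.01, 0.05, 0.2),
                          stride = 2e-3)
  expect_true(all(cc$rho >= -1 & cc$rho <= 1))
  expect_true(all(diff(order(c(0.002, 0.01, 0.05, 0.2))) > 0))
})
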