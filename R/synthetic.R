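#' Correlated Poisson spike-train pair by thinning
#'
#' Two homogeneous Poisson trains of rate `r` that share a fraction
#' `c_share` of their events exactly (thinning construction: a common
#' mother train of rate `c_share * r` is merged with independent private
#' trains of rate `(1 - c_share) * r`). The spike-count correlation over
#' any window equals `c_share` up to `O(r * bin_width)` corrections, which
#' makes the pair a clean oracle for count-correlation estimators.
#'
#' @param r rate in Hz, `> 0`.
#' @param c_share shared-event fraction in `[0, 1]`.
#' @param duration duration in seconds.
#' @param seed integer seed.
#' @param bin_width bin width in seconds; events are generated on the bin
#'   grid (at most one per bin).
#' @return List with `a`, `b` ([spike_train()] objects) and the ground
#'   truth `rho_expected = c_share`.
#' @export
correlated_poisson_pair <- function(r, c_share, duration, seed = 1L,
                                    bin_width = 5e-4) {
  stopifnot(r > 0, c_share >= 0, c_share <= 1, duration > 0)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  n <- floor(duration / bin_width)
  pc <- c_share * r * bin_width
  pp <- (1 - c_share) * r * bin_width
  stopifnot(pc <= 1, pp <= 1)
  common <- stats::runif(n) < pc
  mk <- function() {
    bins <- common | (stats::runif(n) < pp)
    spike_train((which(bins) - 0.5) * bin_width, duration, bin_width)
  }
  list(a = mk(), b = mk(), rho_expected = c_share)
}

#' Specification of a doubly stochastic (Cox) pair ensemble
#'
#' Two conditionally independent inhomogeneous Poisson neurons whose rates
#' are `r0 + g_common (k * s)(t) + g_trial (k * eta_k)(t) +
#' g_private (k * xi)(t)`, with `k` an exponential kernel of time constant
#' `tau_k` (unit area), `s` a frozen unit-spectral-density white stimulus
#' shared by both neurons and all trials, `eta_k` a trial-variable common
#' noise (shared by the pair within a trial, fresh each trial), and `xi`
#' private white noise, fresh per neuron and trial. The `g_trial` component
#' correlates the pair within a trial but not across trials, so it
#' separates the within-trial from the across-trial (signal) correlation.
#' Every second-order statistic of this generator has a closed form,
#' evaluated by [cox_ground_truth()] through time-domain algebra that is
#' independent of the spectral estimators it validates.
#'
#' @param r0 base rate (Hz).
#' @param tau_k kernel time constant (s).
#' @param g_common,g_trial,g_private modulation strengths (Hz per unit
#'   filtered input) of the frozen-stimulus, trial-variable common, and
#'   private components.
#' @param duration trial duration (s).
#' @param n_trials number of frozen-stimulus trials.
#' @param bin_width bin width (s).
#' @param seed integer seed.
#' @param max_clip tolerated fraction of rate-clipped bins.
#' @return A list of class `cox_pair_spec`.
#' @export
cox_pair_spec <- function(r0 = 30, tau_k = 0.02, g_common = 2,
                          g_trial = 0, g_private = 0, duration = 100,
                          n_trials = 1L, bin_width = 5e-4, seed = 1L,
                          max_clip = 1e-3) {
  stopifnot(r0 > 0, tau_k > 0, duration > 0, n_trials >= 1)
  structure(list(r0 = r0, tau_k = tau_k, g_common = g_common,
                 g_trial = g_trial,
                 g_private = g_private, duration = duration,
                 n_trials = as.integer(n_trials), bin_width = bin_width,
                 seed = seed, max_clip = max_clip),
            class = "cox_pair_spec")
}

#' Closed-form statistics of the Cox pair generator
#'
#' For the exponential kernel, the filtered unit-density white stimulus has
#' covariance `exp(-|u|/tau_k) / (2 tau_k)`, so the across-trial
#' (signal) count covariance over a window `T` is
#' `g_common^2 (T - tau_k (1 - exp(-T/tau_k)))`, the count variance adds
#' the Poisson term `r0 T` and the private modulation, and the gain is
#' `G(f) = g_common / (1 + 2 pi i f tau_k)`.
#'
#' @param spec a [cox_pair_spec()].
#' @param T_grid window lengths (s).
#' @param f frequency grid (Hz) for the gain.
#' @return List with `rho` (predicted across-trial correlation at
#'   `T_grid`), `rho_within` (within-trial correlation, which adds the
#'   trial-variable common term), `count_cov`, `count_var`, and `gain`
#'   (a `gain_fun`).
#' @export
cox_ground_truth <- function(spec, T_grid = c(0.005, 0.05, 0.2),
                             f = lif_frequency_grid()) {
  stopifnot(inherits(spec, "cox_pair_spec"))
  shape <- function(T) T - spec$tau_k * (1 - exp(-T / spec$tau_k))
  count_cov <- spec$g_common^2 * shape(T_grid)
  cov_within <- (spec$g_common^2 + spec$g_trial^2) * shape(T_grid)
  count_var <- spec$r0 * T_grid +
    (spec$g_common^2 + spec$g_trial^2 + spec$g_private^2) * shape(T_grid)
  gain <- structure(list(f = f,
                         values = spec$g_common /
                           (1 + 2i * pi * f * spec$tau_k),
                         provenance = "theory"),
                    class = "gain_fun")
  list(rho = count_cov / count_var, rho_within = cov_within / count_var,
       count_cov = count_cov, count_var = count_var, gain = gain,
       T_grid = T_grid)
}

#' Generate a Cox-process trial ensemble with known ground truth
#'
#' @param spec a [cox_pair_spec()].
#' @return A list of class `cox_ensemble`: `ensemble` (a
#'   [trial_ensemble()] of the two neurons), `stimulus` (the frozen trace
#'   at bin resolution, unit spectral density), `truth`
#'   ([cox_ground_truth()] at default grids), and `clip_fraction`.
#' @export
cox_ensemble <- function(spec) {
  stopifnot(inherits(spec, "cox_pair_spec"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)
  dt <- spec$bin_width
  n <- floor(spec$duration / dt)
  decay <- exp(-dt / spec$tau_k)
  filt <- function(x)  # discrete exponential kernel, unit area
    as.numeric(stats::filter(x * dt / spec$tau_k, decay,
                             method = "recursive"))
  s <- stats::rnorm(n) / sqrt(dt)        # unit spectral density
  zs <- filt(s)
  clip <- 0L
  trials <- vector("list", spec$n_trials)
  for (k in seq_len(spec$n_trials)) {
    trains <- vector("list", 2L)
    zt <- if (spec$g_trial > 0) filt(stats::rnorm(n) / sqrt(dt)) else 0
    for (i in 1:2) {
      zp <- if (spec$g_private > 0)
        filt(stats::rnorm(n) / sqrt(dt)) else 0
      rate <- spec$r0 + spec$g_common * zs + spec$g_trial * zt +
        spec$g_private * zp
      p <- rate * dt
      clip <- clip + sum(p < 0 | p > 1)
      p <- pmin(pmax(p, 0), 1)
      bins <- stats::runif(n) < p
      trains[[i]] <- spike_train((which(bins) - 0.5) * dt, spec$duration,
                                 dt)
    }
    trials[[k]] <- trains
  }
  clip_fraction <- clip / (2 * spec$n_trials * n)
  if (clip_fraction > spec$max_clip)
    stop(sprintf(paste0("rate clipping fraction %.2g exceeds the budget ",
                        "%.2g; reduce the modulation depth"),
                 clip_fraction, spec$max_clip))
  stim <- structure(list(samples = s, dt_sample = dt, kind = "white",
                         frozen_segment_s = spec$duration, n_repeats = 1L,
                         seed = spec$seed),
                    class = "stimulus")
  structure(list(ensemble = trial_ensemble(trials), stimulus = stim,
                 truth = cox_ground_truth(spec), spec = spec,
                 clip_fraction = clip_fraction),
            class = "cox_ensemble")
}

#' @export
print.cox_ensemble <- function(x, ...) {
  cat(sprintf(
    "<cox_ensemble> r0 = %g Hz, tau_k = %g ms, %d trial(s) x %g s (clip %.2g)\n",
    x$spec$r0, 1e3 * x$spec$tau_k, x$spec$n_trials, x$spec$duration,
    x$clip_fraction))
  invisible(x)
}
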