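#' Simulate the ELL-EGp spiking network
#'
#' Euler-Maruyama integration of the three-population leaky
#' integrate-and-fire network at step `dt` (default 0.05 ms). The common
#' stimulus is temporally white, frozen across trials (`nsim` trials rerun
#' the identical stimulus with fresh private noise), and is returned
#' bin-averaged at the spike bin width with unit spectral density, so
#' [estimate_gain()] applied to the result is directly comparable with the
#' theoretical [stimulus_gain()]. Initial voltages are uniform on
#' `[V_r, V_th]` and a burn-in (default 1 s) is discarded.
#'
#' @param object an [ell_circuit()].
#' @param nsim number of frozen-stimulus trials.
#' @param seed integer seed; fully determines the realisation (stimulus,
#'   locked-subset membership, and private noise).
#' @param duration recorded duration per trial in seconds.
#' @param dt integration step in seconds (must be `<= 1e-4`).
#' @param burn_in discarded initial span in seconds.
#' @param bin_width spike-train bin width for the returned ensembles.
#' @param feedback_full also return the feedback drive at full `dt`
#'   resolution (memory-heavy; for diagnostics on short runs).
#' @param ... unused.
#' @return An object of class `ell_sim`: trial ensembles `deep`, `egp`,
#'   `superficial`; `stimulus` (a [make_stimulus()]-compatible object per
#'   trial, identical across trials); `feedback` (binned drive in mV/s per
#'   trial); `locked` (indices of stimulus-locked deep neurons); and the
#'   run configuration.
#' @export
simulate.ell_circuit <- function(object, nsim = 1, seed = 1L,
                                 duration = 120, dt = 5e-5, burn_in = 1,
                                 bin_width = 5e-4, feedback_full = FALSE,
                                 ...) {
  stopifnot(inherits(object, "ell_circuit"), duration > 0, burn_in >= 0,
            nsim >= 1)
  if (dt > 1e-4) stop("integration step dt must be at most 0.1 ms")
  p <- object$params
  par <- list(N_D = p$N_D, N_E = p$N_E, N_S = p$N_S,
              tau_D = p$tau_D, tau_E = p$tau_E, tau_S = p$tau_S,
              mu_D = p$mu_D, mu_E = p$mu_E, mu_S = p$mu_S,
              V_th = p$V_th, V_r = p$V_r, sigma = p$sigma, g_A = p$g_A,
              J_DE = p$J_DE, J_ES = p$J_ES, tau_s = p$tau_s,
              c_deep = object$c_deep, c_sup = object$c_sup,
              p_locked = object$p_locked,
              feedback_on = object$feedback)
  raw <- sim_ell_cpp(par, duration, dt, burn_in, as.integer(nsim),
                     as.numeric(seed), bin_width, feedback_full)
  dur <- raw$duration
  wrap_pop <- function(pop) {
    trial_ensemble(lapply(pop, function(trial)
      lapply(trial, spike_train, duration = dur, bin_width = bin_width)))
  }
  stim <- lapply(raw$stimulus, function(s)
    structure(list(samples = s, dt_sample = raw$bin_width, kind = "white",
                   frozen_segment_s = dur, n_repeats = 1L, seed = seed),
              class = "stimulus"))
  structure(list(deep = wrap_pop(raw$deep), egp = wrap_pop(raw$egp),
                 superficial = wrap_pop(raw$superficial),
                 stimulus = stim, feedback = raw$feedback,
                 feedback_full = if (feedback_full) raw$feedback_full,
                 locked = sort(raw$locked + 1L),
                 circuit = object, seed = seed, dt = dt,
                 duration = dur, burn_in = burn_in,
                 bin_width = raw$bin_width, n_trials = as.integer(nsim)),
            class = "ell_sim")
}

#' @export
print.ell_sim <- function(x, ...) {
  cat(sprintf("<ell_sim> %s/%s/feedback %s: %d trial(s) x %.1f s (dt %.3g ms)\n",
              x$circuit$scenario, x$circuit$cell_class,
              if (x$circuit$feedback) "on" else "off",
              x$n_trials, x$duration, 1e3 * x$dt))
  r <- population_rates(x)
  cat(sprintf("  mean rates: deep %.1f Hz, EGp %.1f Hz, superficial %.1f Hz\n",
              r["deep"], r["egp"], r["superficial"]))
  invisible(x)
}

#' Mean population firing rates of a simulation
#'
#' @param sim an `ell_sim`.
#' @return Named vector of rates (Hz) averaged over neurons and trials.
#' @export
population_rates <- function(sim) {
  stopifnot(inherits(sim, "ell_sim"))
  one <- function(ens)
    mean(vapply(unlist(ens$trains, recursive = FALSE), firing_rate, 0))
  c(deep = one(sim$deep), egp = one(sim$egp),
    superficial = one(sim$superficial))
}

#' Feedback drive delivered to the superficial pair
#'
#' Returns the synaptic drive term `(J_ES / N_E) sum_j (alpha * y_j)(t)`
#' (mV/s) that the simulation delivered to each superficial neuron,
#' bin-averaged at the spike bin width, for one trial. Identically zero when
#' the pathway is blocked.
#'
#' @param sim an `ell_sim`.
#' @param trial trial index.
#' @return Numeric vector with a `dt` attribute (the bin width).
#' @export
feedback_current <- function(sim, trial = 1L) {
  stopifnot(inherits(sim, "ell_sim"))
  out <- sim$feedback[[trial]]
  attr(out, "dt") <- sim$bin_width
  out
}

#' Reconstruct the feedback drive from the stored EGp spike times
#'
#' Replays the exponential synaptic kernel `exp(-t/tau_s)/tau_s` over the
#' recorded EGp spikes at the integration step, verifying that the stored
#' feedback trace is a deterministic function of the spike output.
#'
#' @param sim an `ell_sim` run with `feedback_full = TRUE`.
#' @param trial trial index.
#' @return Numeric vector at `dt` resolution (mV/s), aligned with
#'   `sim$feedback_full[[trial]]`.
#' @export
reconstruct_feedback <- function(sim, trial = 1L) {
  stopifnot(inherits(sim, "ell_sim"))
  if (is.null(sim$feedback_full))
    stop("simulation was not run with feedback_full = TRUE")
  p <- sim$circuit$params
  dt <- sim$dt
  n <- round(sim$duration / dt)
  counts <- integer(n)
  for (tr in sim$egp$trains[[trial]]) {
    # spike times are exact multiples of dt; round against FP jitter
    idx <- as.integer(round(tr$times / dt)) + 1L
    idx <- idx[idx >= 1L & idx <= n]
    tab <- tabulate(idx, nbins = n)
    counts <- counts + tab
  }
  decay <- exp(-dt / p$tau_s)
  syn <- numeric(n)
  acc <- 0
  J <- if (sim$circuit$feedback) p$J_ES else 0
  for (i in seq_len(n)) {
    acc <- acc * decay + counts[i] / p$tau_s
    syn[i] <- acc
  }
  J / p$N_E * syn
}

#' Mean pairwise count correlation across the deep population
#'
#' Average within-trial spike-count correlation (window `T`, default
#' 100 ms) over a random subsample of deep neuron pairs. Under local
#' stimulation only a small locked fraction is stimulus-correlated, so the
#' population mean is low; under global stimulation the whole deep
#' population is stimulus-locked and the mean rises.
#'
#' @param sim an `ell_sim`.
#' @param window_T counting window (s).
#' @param n_pairs number of random pairs to average.
#' @param seed seed for the pair subsample.
#' @param stride count-window stride (s); a coarse default keeps this cheap.
#' @return Mean pairwise correlation (zero-variance pairs dropped).
#' @export
deep_population_summary <- function(sim, window_T = 0.1, n_pairs = 50L,
                                    seed = 1L, stride = window_T / 4) {
  stopifnot(inherits(sim, "ell_sim"))
  nD <- sim$deep$n_neurons
  if (nD < 2) stop("need at least two deep neurons")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  pairs <- unique(t(replicate(n_pairs, sort(sample.int(nD, 2L)))))
  trains <- sim$deep$trains[[1]]
  counts <- lapply(seq_len(nD), function(i) NULL)
  get_counts <- function(i) {
    if (is.null(counts[[i]]))
      counts[[i]] <<- spike_counts(trains[[i]], window_T, stride)
    counts[[i]]
  }
  rho <- apply(pairs, 1, function(ij) {
    suppressWarnings(count_correlation(get_counts(ij[1]), get_counts(ij[2])))
  })
  mean(rho[is.finite(rho)])
}
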