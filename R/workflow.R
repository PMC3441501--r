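#' Run the model scenario suite
#'
#' Simulates the circuit under a set of scenarios over several seeds and
#' collects, per run: population rates, the within-trial spike-count
#' correlation of the superficial pair at each window length, and the
#' cross-/power-spectra needed for stimulus-gain estimation. This is the
#' engine behind the reproduction of the correlation-shaping, feedback
#' block, and nBP results.
#'
#' @param scenarios character vector from `"local"`, `"global"`,
#'   `"global-off"` (feedback blocked), `"nbp-local"`, `"nbp-global"`.
#' @param seeds integer vector of simulation seeds.
#' @param duration seconds per run.
#' @param T_grid counting windows (s) for the correlation curves.
#' @param params an [ell_params()].
#' @param dt integration step (s).
#' @param stride count-window stride (s); the default (5 ms) keeps the
#'   count series cheap while still heavily overlapped.
#' @param keep_spectra collect Welch spectra for gain estimation.
#' @return A list of class `scenario_suite`: `results` (one row per
#'   scenario/seed/window with `rho`), `rates`, `spectra` (per scenario:
#'   averaged `S_ys`, `S_ss`), and the configuration.
#' @export
run_scenario_suite <- function(scenarios = c("local", "global"),
                               seeds = 1:10, duration = 60,
                               T_grid = c(0.005, 0.2),
                               params = ell_params(), dt = 5e-5,
                               stride = 5e-3, keep_spectra = TRUE) {
  known <- c("local", "global", "global-off", "nbp-local", "nbp-global")
  stopifnot(all(scenarios %in% known))
  res <- list()
  rates <- list()
  spectra <- list()
  for (sc in scenarios) {
    circ <- scenario_circuit(sc, params)
    acc_ys <- NULL
    acc_ss <- NULL
    fgrid <- NULL
    for (sd in seeds) {
      sim <- simulate(circ, nsim = 1, seed = sd, duration = duration,
                      dt = dt)
      r <- population_rates(sim)
      rates[[length(rates) + 1L]] <-
        data.frame(scenario = sc, seed = sd, deep = r[["deep"]],
                   egp = r[["egp"]], superficial = r[["superficial"]])
      cc <- correlation_curve(sim$superficial, 1L, 2L, T_grid,
                              kind = "within_trial", stride = stride)
      res[[length(res) + 1L]] <-
        data.frame(scenario = sc, seed = sd, T = T_grid, rho = cc$rho)
      if (keep_spectra) {
        sp <- sim_gain_spectra(sim)
        fgrid <- sp$f
        acc_ys <- if (is.null(acc_ys)) sp$S_ys else acc_ys + sp$S_ys
        acc_ss <- if (is.null(acc_ss)) sp$S_ss else acc_ss + sp$S_ss
      }
    }
    if (keep_spectra)
      spectra[[sc]] <- list(f = fgrid, S_ys = acc_ys / length(seeds),
                            S_ss = acc_ss / length(seeds))
  }
  structure(list(results = do.call(rbind, res),
                 rates = do.call(rbind, rates), spectra = spectra,
                 scenarios = scenarios, seeds = seeds,
                 duration = duration, T_grid = T_grid, params = params,
                 dt = dt, stride = stride),
            class = "scenario_suite")
}

#' Resolve a scenario label into a circuit
#'
#' @param scenario one of `"local"`, `"global"`, `"global-off"`,
#'   `"nbp-local"`, `"nbp-global"`.
#' @param params an [ell_params()].
#' @return An [ell_circuit()].
#' @export
scenario_circuit <- function(scenario, params = ell_params()) {
  switch(scenario,
         "local" = ell_circuit("local", "BP", TRUE, params),
         "global" = ell_circuit("global", "BP", TRUE, params),
         "global-off" = ell_circuit("global", "BP", FALSE, params),
         "nbp-local" = ell_circuit("local", "nBP", TRUE, params),
         "nbp-global" = ell_circuit("global", "nBP", TRUE, params),
         stop("unknown scenario: ", scenario))
}

# Welch spectra of a simulated superficial pair against its stimulus,
# averaged over the two neurons and all trials
sim_gain_spectra <- function(sim) {
  stopifnot(inherits(sim, "ell_sim"))
  acc_ys <- NULL
  acc_ss <- NULL
  f <- NULL
  n <- 0L
  for (k in seq_len(sim$n_trials)) {
    stim <- sim$stimulus[[k]]
    S_ss <- estimate_spectra(stim)
    for (i in seq_len(sim$superficial$n_neurons)) {
      S_ys <- estimate_spectra(stim, sim$superficial$trains[[k]][[i]])
      f <- S_ys$f
      acc_ys <- if (is.null(acc_ys)) S_ys$values else acc_ys + S_ys$values
      acc_ss <- if (is.null(acc_ss)) Re(S_ss$values)
                else acc_ss + Re(S_ss$values)
      n <- n + 1L
    }
  }
  list(f = f, S_ys = acc_ys / n, S_ss = acc_ss / n)
}

#' Band-averaged gain magnitude from suite spectra
#'
#' @param sp one element of `run_scenario_suite()$spectra` (fields `f`,
#'   `S_ys`, `S_ss`).
#' @param bands matrix with two columns (band edges in Hz) or a vector of
#'   edges.
#' @return Data frame with band centres and band-averaged `|G|`.
#' @export
gain_bands <- function(sp, bands = c(1, 3, 10, 30, 100)) {
  if (is.vector(bands)) bands <- cbind(bands[-length(bands)], bands[-1])
  G <- sp$S_ys / sp$S_ss
  out <- apply(bands, 1, function(b) {
    sel <- sp$f >= b[1] & sp$f < b[2]
    c(f_lo = b[1], f_hi = b[2], f_mid = exp(mean(log(sp$f[sel]))),
      gain = mean(Mod(G[sel])))
  })
  as.data.frame(t(out))
}

#' Summary report of the scenario suite against the model benchmarks
#'
#' Evaluates the suite results against the model's benchmark behaviour:
#' target rates (deep 36 Hz, superficial 12 Hz), the correlation-shaping
#' contrast between local and global stimulation at short and long
#' windows, the feedback-block effect, and the nBP variant, with
#' Monte-Carlo standard errors over seeds.
#'
#' @param suite a `scenario_suite` from [run_scenario_suite()].
#' @param T_short,T_long the window lengths (s) used for the contrasts.
#' @return A `data.frame` with columns `check`, `value`, `se`, `target`,
#'   `pass`.
#' @export
acceptance_report <- function(suite, T_short = 0.005, T_long = 0.2) {
  stopifnot(inherits(suite, "scenario_suite"))
  if (!nrow(suite$results)) stop("empty suite: nothing to report")
  rows <- list()
  add <- function(check, value, se, target, pass)
    rows[[length(rows) + 1L]] <<-
      data.frame(check = check, value = value, se = se, target = target,
                 pass = pass)
  rho_at <- function(sc, T) {
    x <- suite$results
    x$rho[x$scenario == sc & abs(x$T - T) < 1e-9]
  }
  mse <- function(x) stats::sd(x) / sqrt(length(x))
  if ("global" %in% suite$scenarios) {
    rt <- suite$rates[suite$rates$scenario == "global", ]
    add("deep rate (global), Hz", mean(rt$deep), mse(rt$deep), 36,
        abs(mean(rt$deep) - 36) < 3.6)
    add("superficial rate (global), Hz", mean(rt$superficial),
        mse(rt$superficial), 12, abs(mean(rt$superficial) - 12) < 1.2)
  }
  both <- function(a, b, T) {
    d <- rho_at(a, T) - rho_at(b, T)
    c(mean(d), mse(d))
  }
  if (all(c("local", "global") %in% suite$scenarios)) {
    d5 <- both("global", "local", T_short)
    add(sprintf("rho_global - rho_local at T = %g ms", 1e3 * T_short),
        d5[1], d5[2], NA, d5[1] > 2 * d5[2])
    dL <- both("global", "local", T_long)
    add(sprintf("rho_global - rho_local at T = %g ms", 1e3 * T_long),
        dL[1], dL[2], NA, dL[1] < -2 * dL[2])
  }
  if (all(c("global", "global-off") %in% suite$scenarios)) {
    db <- both("global-off", "global", T_long)
    add(sprintf("feedback block: delta rho at T = %g ms", 1e3 * T_long),
        db[1], db[2], NA, db[1] > 2 * db[2])
    ds <- both("global-off", "global", T_short)
    add(sprintf("feedback block: delta rho at T = %g ms", 1e3 * T_short),
        ds[1], ds[2], NA, abs(ds[1]) < max(1 * ds[2], 0.02))
  }
  if (all(c("nbp-local", "nbp-global") %in% suite$scenarios)) {
    dn5 <- both("nbp-global", "nbp-local", T_short)
    add(sprintf("nBP: rho_global - rho_local at T = %g ms", 1e3 * T_short),
        dn5[1], dn5[2], NA, abs(dn5[1]) < 2 * dn5[2] + 1e-3)
    dnL <- both("nbp-global", "nbp-local", T_long)
    add(sprintf("nBP: rho_global - rho_local at T = %g ms", 1e3 * T_long),
        dnL[1], dnL[2], NA, dnL[1] < -2 * dnL[2])
  }
  do.call(rbind, rows)
}
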