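#' Network parameters for the ELL-EGp circuit
#'
#' Constants of the three-population leaky integrate-and-fire model of the
#' open-loop feedback pathway: a deep ELL pyramidal population (N_D = 800)
#' that projects to EGp granule cells (N_E = 200), which inhibit a pair of
#' superficial ELL pyramidal neurons (N_S = 2). Voltages in mV, times in
#' seconds, rates in Hz.
#'
#' The synaptic strengths `J_DE` (deep to EGp, excitatory) and `J_ES` (EGp to
#' superficial, net inhibitory, `<= 0`), and the afferent strength `g_A`
#' (voltage-std of the electroreceptor input carrying the stimulus), are
#' fixed by the packaged calibration ([calibrate_circuit()]): deep rate
#' 36 Hz, superficial rate 12 Hz (local/global average), and near-complete
#' cancellation of the low-frequency global stimulus drive by the feedback
#' (`F(0)/a_ff = 0.95`). The shipped defaults are the calibrated values.
#'
#' @param ... named overrides of any default parameter.
#' @return A named list of class `ell_params`.
#' @export
ell_params <- function(...) {
  p <- list(
    N_D = 800L, N_E = 200L, N_S = 2L,
    tau_D = 0.010, tau_E = 0.010, tau_S = 0.015,
    mu_D = -56, mu_E = -60, mu_S = -56,
    V_th = -55, V_r = -65,
    sigma = 1,
    tau_s = 0.005,
    c_local = 0.1, c_global = 0.2,
    p_local = 0.05, p_global = 1.0,
    # calibrated (see calibrate_circuit / the methods vignette)
    g_A = 1.946858,
    J_DE = 11.015591,
    J_ES = -6.100130
  )
  ov <- list(...)
  if (length(ov)) {
    bad <- setdiff(names(ov), names(p))
    if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    p[names(ov)] <- ov
  }
  stopifnot(p$V_r < p$V_th, p$tau_D > 0, p$tau_E > 0, p$tau_S > 0,
            p$N_D >= 1, p$N_E >= 1, p$N_S >= 1, p$J_ES <= 0,
            p$sigma >= 0, p$g_A >= 0)
  class(p) <- "ell_params"
  p
}

#' ELL-EGp circuit model object
#'
#' Binds the network parameters to a stimulation scenario, giving the object
#' that [simulate()][simulate.ell_circuit], [predict()][predict.ell_circuit]
#' and [snr_table()] operate on.
#'
#' Scenarios: under `"local"` stimulation a fraction `p = 0.05` of deep
#' neurons is stimulus-locked and the afferent input correlation of the
#' superficial pair is `c = 0.1`; under `"global"` stimulation all deep
#' neurons are locked (`p = 1`) and `c = 0.2` (receptive-field saturation).
#' For the `"nBP"` cell class the classical receptive field is small enough
#' that local stimuli already saturate it, so `c = 0.2` in both scenarios
#' (the deep population drive is unchanged). `feedback = FALSE` sets
#' `J_ES = 0` (pathway block).
#'
#' @param scenario `"local"` or `"global"` spatial extent of the stimulus.
#' @param cell_class `"BP"` (basilar) or `"nBP"` (non-basilar) superficial
#'   pyramidal neurons.
#' @param feedback logical; is the EGp feedback pathway intact?
#' @param params an [ell_params()] object.
#' @return An object of class `ell_circuit`.
#' @export
ell_circuit <- function(scenario = c("global", "local"),
                        cell_class = c("BP", "nBP"),
                        feedback = TRUE, params = ell_params()) {
  scenario <- match.arg(scenario)
  cell_class <- match.arg(cell_class)
  stopifnot(inherits(params, "ell_params"), is.logical(feedback))
  # deep (driver) population: always BP receptive fields
  c_deep <- if (scenario == "local") params$c_local else params$c_global
  # superficial pair: nBP receptive fields saturate already for local input
  c_sup <- if (cell_class == "nBP") params$c_global else c_deep
  p_locked <- if (scenario == "local") params$p_local else params$p_global
  structure(list(params = params, scenario = scenario,
                 cell_class = cell_class, feedback = feedback,
                 c_deep = c_deep, c_sup = c_sup, p_locked = p_locked,
                 Lambda = if (scenario == "global") 1 else 0),
            class = "ell_circuit")
}

#' @export
print.ell_circuit <- function(x, ...) {
  cat(sprintf(
    "<ell_circuit> %s stimulation, %s cells, feedback %s\n",
    x$scenario, x$cell_class, if (x$feedback) "on" else "off"))
  cat(sprintf("  c_deep = %.2f, c_sup = %.2f, locked fraction p = %.2f\n",
              x$c_deep, x$c_sup, x$p_locked))
  cat(sprintf("  g_A = %.3f mV, J_DE = %.2f mV, J_ES = %.2f mV\n",
              x$params$g_A, x$params$J_DE, x$params$J_ES))
  invisible(x)
}

#' @export
coef.ell_circuit <- function(object, ...) {
  p <- object$params
  c(N_D = p$N_D, N_E = p$N_E, N_S = p$N_S,
    tau_D = p$tau_D, tau_E = p$tau_E, tau_S = p$tau_S,
    mu_D = p$mu_D, mu_E = p$mu_E, mu_S = p$mu_S,
    V_th = p$V_th, V_r = p$V_r, sigma = p$sigma, tau_s = p$tau_s,
    g_A = p$g_A, J_DE = p$J_DE, J_ES = p$J_ES,
    c_deep = object$c_deep, c_sup = object$c_sup,
    p_locked = object$p_locked,
    Lambda = object$Lambda)
}

#' @export
summary.ell_circuit <- function(object, ...) {
  op <- operating_point(object)
  out <- list(circuit = object, op = op)
  class(out) <- "summary.ell_circuit"
  out
}

#' @export
print.summary.ell_circuit <- function(x, ...) {
  print(x$circuit)
  cat(sprintf("  theory rates: deep %.1f Hz, EGp %.1f Hz, superficial %.1f Hz\n",
              x$op$deep$r0, x$op$egp$r0, x$op$sup$r0))
  cat(sprintf("  superficial operating point: mu_eff = %.2f mV, sigma_eff = %.2f mV\n",
              x$op$sup$params$mu, x$op$sup$params$sigma))
  invisible(x)
}

#' @export
plot.ell_circuit <- function(x, type = c("gain", "rho"), ...) {
  type <- match.arg(type)
  if (type == "gain") {
    g <- predict(x, type = "gain")
    plot(g, main = sprintf("stimulus gain (%s, %s)", x$scenario,
                           x$cell_class), ...)
  } else {
    r <- predict(x, type = "rho")
    plot(r, main = sprintf("predicted rho(T) (%s, %s)", x$scenario,
                           x$cell_class), ...)
  }
  invisible(x)
}
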