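#' Linearisation operating point of the circuit
#'
#' Computes, population by population, the effective bias and noise level
#' around which the linear-response theory expands, together with the
#' stationary rates. The deep population feels the intrinsic noise `sigma`
#' plus the afferent input `g_A` (locked and unlocked deep neurons carry the
#' same total input variance, hence the same rate and susceptibility). EGp
#' granule cells are depolarised by the pooled deep spikes
#' (`mu_E + tau_E J_DE r_D`), with voltage fluctuations from intrinsic
#' noise, the pooled shot noise of the deep spiking, and the shared
#' stimulus-locked modulation of the pooled deep rate (membrane-filtered,
#' effective-diffusion approximation). Superficial neurons feel the
#' afferent input, the mean of the inhibitory feedback `tau_S J_ES r_E`
#' (zero when the pathway is blocked), and the feedback's fluctuations
#' around that mean: the 1/N_E-pooled spontaneous EGp variability and the
#' stimulus-locked feedback component, both filtered through the synaptic
#' kernel and the membrane.
#'
#' @param circuit an [ell_circuit()].
#' @param f frequency grid (Hz) for the cellular response functions.
#' @param deep_wide optional precomputed deep-population
#'   [lif_linear_response()] on a wide grid (calibration reuses it).
#' @return List with components `deep`, `egp`, `sup`, each a
#'   [lif_linear_response()] result.
#' @export
operating_point <- function(circuit, f = lif_frequency_grid(),
                            deep_wide = NULL) {
  stopifnot(inherits(circuit, "ell_circuit"))
  p <- circuit$params
  sig_aff <- sqrt(p$sigma^2 + p$g_A^2)
  if (is.null(deep_wide))
    deep_wide <- lif_linear_response(p$mu_D, sig_aff, p$tau_D, p$V_th,
                                     p$V_r, lif_frequency_grid(0.1, 800, 160))
  deep <- interp_response(deep_wide, f)
  ep <- egp_point(p, circuit$p_locked, circuit$c_deep, deep_wide)
  egp_wide <- lif_linear_response(ep$mu_E, ep$sig_E, p$tau_E, p$V_th,
                                  p$V_r, deep_wide$f)
  egp <- interp_response(egp_wide, f)
  J_ES <- if (circuit$feedback) p$J_ES else 0
  mu_S <- p$mu_S + p$tau_S * J_ES * egp_wide$r0
  fbv <- feedback_variance(p, circuit$p_locked, circuit$c_deep, deep_wide,
                           egp_wide)
  sig_S <- sqrt(p$sigma^2 + p$g_A^2 +
                  J_ES^2 * (fbv$I_priv + fbv$I_stim))
  sup <- lif_linear_response(mu_S, sig_S, p$tau_S, p$V_th, p$V_r, f)
  list(deep = deep, egp = egp, sup = sup)
}

# superficial voltage variance contributed by feedback fluctuations, per
# unit J_ES^2: private (pooled spontaneous EGp variability) and shared
# (stimulus-locked chain), both filtered by the synaptic kernel and the
# superficial membrane
feedback_variance <- function(p, p_locked, c_deep, deep_wide, egp_wide) {
  fw <- deep_wide$f
  syn2 <- 1 / (1 + (2 * pi * fw * p$tau_s)^2)
  mem2 <- 1 / (1 + (2 * pi * fw * p$tau_S)^2)
  I_priv <- p$tau_S^2 / p$N_E *
    2 * pracma::trapz(fw, egp_wide$C0 * syn2 * mem2)
  chain <- p$tau_S * sqrt(syn2) * Mod(egp_wide$A) *
    p$tau_E * p$J_DE * p_locked * Mod(deep_wide$A) *
    sqrt(2 * p$tau_D) * p$g_A * sqrt(c_deep)
  I_stim <- 2 * pracma::trapz(fw, chain^2 * mem2)
  list(I_priv = I_priv, I_stim = I_stim)
}

#' Serial feedback filter of the open-loop pathway
#'
#' Transfer from the common stimulus to the feedback drive received by a
#' superficial neuron, composed serially along
#' deep ELL -> EGp -> superficial ELL: the stimulus drives each locked deep
#' neuron (voltage drive `sqrt(2 tau_D) g_A sqrt(c)` per unit stimulus), its
#' rate modulation passes through the deep susceptibility `A_D(f)`, the
#' pooled deep spikes drive EGp (`tau_E J_DE`, diluted by the locked
#' fraction `p`), EGp rate modulations pass through `A_E(f)` and the
#' Lorentzian synaptic filter `1 / (1 + 2 pi i f tau_s)`, and finally reach
#' the superficial membrane with weight `tau_S |J_ES|`. Returned with a
#' positive sign convention at `f = 0` so that the global stimulus gain is
#' `A_S(f) (a_ff - F(f))` with `a_ff` the feedforward afferent drive.
#'
#' @param circuit an [ell_circuit()].
#' @param f frequency grid (Hz).
#' @param op optional precomputed [operating_point()] on the same grid.
#' @param deep_stage `"p_sqrt_c"` (default: the locked fraction dilutes the
#'   pooled deep modulation) or `"sqrt_c"` (no dilution); the two variants
#'   of the deep-stage prefactor.
#' @return Object of class `feedback_filter` with `f` and complex `values`
#'   (mV of superficial drive per unit stimulus).
#' @export
feedback_filter <- function(circuit, f = lif_frequency_grid(), op = NULL,
                            deep_stage = c("p_sqrt_c", "sqrt_c")) {
  stopifnot(inherits(circuit, "ell_circuit"))
  deep_stage <- match.arg(deep_stage)
  p <- circuit$params
  if (is.null(op)) op <- operating_point(circuit, f)
  syn <- 1 / (1 + 2i * pi * f * p$tau_s)
  p_eff <- if (deep_stage == "p_sqrt_c") circuit$p_locked else 1
  vals <- p$tau_S * abs(p$J_ES) * syn * op$egp$A *
    p$tau_E * p$J_DE * p_eff * op$deep$A *
    sqrt(2 * p$tau_D) * p$g_A * sqrt(circuit$c_deep)
  structure(list(f = f, values = vals, tau_s = p$tau_s,
                 deep_stage = deep_stage),
            class = "feedback_filter")
}

#' @export
print.feedback_filter <- function(x, ...) {
  cat(sprintf("<feedback_filter> F(0+) = %.3g mV/unit, |F| at %.0f Hz = %.3g\n",
              Mod(x$values[1]), max(x$f), Mod(x$values[length(x$f)])))
  invisible(x)
}

#' @export
plot.feedback_filter <- function(x, ...) {
  graphics::plot(x$f, Mod(x$values), log = "x", type = "l",
                 xlab = "frequency (Hz)", ylab = "|F(f)| (mV per unit)", ...)
  invisible(x)
}

#' Theoretical stimulus gain of a superficial pyramidal neuron
#'
#' Linear-response prediction for the transfer from the common stimulus to
#' the firing rate of a superficial neuron,
#' `G(f) = A_S(f) (a_ff - Lambda F(f))`, with
#' `a_ff = sqrt(2 tau_S) g_A sqrt(c)` the feedforward afferent drive per
#' unit stimulus, `Lambda = 1` under global stimulation (EGp feedback
#' recruited), `Lambda = 0` under local stimulation, and `F` the serial
#' feedback filter (dropped when the pathway is blocked). Directly
#' comparable with [estimate_gain()] applied to a simulation.
#'
#' @inheritParams feedback_filter
#' @return A `gain_fun` with `provenance = "theory"`.
#' @export
stimulus_gain <- function(circuit, f = lif_frequency_grid(), op = NULL,
                          deep_stage = c("p_sqrt_c", "sqrt_c")) {
  stopifnot(inherits(circuit, "ell_circuit"))
  deep_stage <- match.arg(deep_stage)
  p <- circuit$params
  if (is.null(op)) op <- operating_point(circuit, f)
  a_ff <- sqrt(2 * p$tau_S) * p$g_A * sqrt(circuit$c_sup)
  drive <- rep(a_ff + 0i, length(f))
  if (circuit$Lambda == 1 && circuit$feedback) {
    Ff <- feedback_filter(circuit, f, op, deep_stage)
    drive <- drive - Ff$values
  }
  structure(list(f = f, values = op$sup$A * drive, provenance = "theory",
                 scenario = circuit$scenario, cell_class = circuit$cell_class,
                 feedback = circuit$feedback),
            class = "gain_fun")
}

#' Predicted spike-count correlation versus window size
#'
#' Linear-response prediction for the correlation between the two
#' superficial neurons' spike counts over windows `T`: the stimulus-induced
#' cross-spectrum `|G(f)|^2 S_ss(f)` (the signal is white with unit spectral
#' density) and the single-train spectrum `C0(f) + |G(f)|^2 S_ss(f)` are
#' integrated against the squared sinc window kernel,
#' `rho(T) = int |G|^2 K_T df / int (C0 + |G|^2) K_T df`. The pair is
#' homogeneous, so one gain and one spectrum suffice. With
#' `denominator = "spontaneous"` the stimulus-driven variance term is
#' dropped from the denominator.
#'
#' Beyond the stimulus-locked term, the feedback pathway delivers a second,
#' weaker common input to the pair: the pooled spontaneous variability of
#' the EGp population (and of the deep population, relayed through EGp),
#' which is identical for both superficial neurons and is not cancelled by
#' anything. Its cross-spectrum,
#' `|A_S|^2 (tau_S J_ES)^2 |syn|^2 (C0_E / N_E + (tau_E J_DE A_E)^2 r_D / N_D)`,
#' is included in the numerator and denominator when
#' `include_shared_noise = TRUE` (the default); it matters only when the
#' stimulus-locked part is strongly cancelled.
#'
#' @inheritParams feedback_filter
#' @param T_grid counting-window lengths in seconds.
#' @param denominator `"total"` (default) or `"spontaneous"`.
#' @param include_shared_noise include the un-cancellable shared feedback
#'   noise term.
#' @param f_max upper integration frequency (Hz); above it the spike
#'   spectrum is treated as flat at `r0` (exact analytic tail for the
#'   window kernel).
#' @param df linear integration step in Hz.
#' @return A `correlation_curve` with `kind = "predicted"`.
#' @export
predict_rho <- function(circuit, T_grid = c(0.005, 0.02, 0.05, 0.1, 0.2),
                        op = NULL, denominator = c("total", "spontaneous"),
                        deep_stage = c("p_sqrt_c", "sqrt_c"),
                        include_shared_noise = TRUE,
                        f_max = 800, df = 0.1) {
  stopifnot(inherits(circuit, "ell_circuit"))
  denominator <- match.arg(denominator)
  deep_stage <- match.arg(deep_stage)
  fg <- seq(df, f_max, by = df)
  if (is.null(op))
    op <- operating_point(circuit, lif_frequency_grid(df, f_max, 240))
  op <- lapply(op, interp_response, f_new = fg)
  G <- stimulus_gain(circuit, fg, op, deep_stage)
  G2 <- Mod(G$values)^2
  p <- circuit$params
  if (include_shared_noise && circuit$feedback) {
    syn2 <- 1 / (1 + (2 * pi * fg * p$tau_s)^2)
    S_fb <- (p$tau_S * p$J_ES)^2 * syn2 *
      (op$egp$C0 / p$N_E +
         (p$tau_E * p$J_DE * Mod(op$egp$A))^2 * op$deep$r0 / p$N_D)
    G2 <- G2 + Mod(op$sup$A)^2 * S_fb
  }
  C0 <- op$sup$C0
  r0 <- op$sup$r0
  rho <- vapply(T_grid, function(T) {
    K <- sinc_kernel(fg, T)
    num <- 2 * pracma::trapz(fg, G2 * K)
    den <- r0 * T + 2 * pracma::trapz(fg, (C0 - r0) * K) +
      if (denominator == "total") num else 0
    num / den
  }, 0)
  structure(list(windows_T = T_grid, rho = rho, kind = "predicted",
                 scenario = circuit$scenario,
                 cell_class = circuit$cell_class,
                 feedback = circuit$feedback),
            class = "correlation_curve")
}

#' Theory predictions from a circuit model
#'
#' Dispatches to the linear-response layer: `"gain"` for the stimulus gain
#' `G(f)`, `"rho"` for the predicted count-correlation curve `rho(T)`,
#' `"filter"` for the serial feedback filter `F(f)`, `"cellular"` for the
#' operating-point response functions, and `"snr"` for the
#' signal-versus-distractor table.
#'
#' @param object an [ell_circuit()].
#' @param type which prediction to return.
#' @param f frequency grid (Hz) where applicable.
#' @param T_grid window-length grid (s) for `type = "rho"`.
#' @param ... passed to the underlying function.
#' @return See the corresponding function.
#' @export
predict.ell_circuit <- function(object,
                                type = c("gain", "rho", "filter",
                                         "cellular", "snr"),
                                f = lif_frequency_grid(),
                                T_grid = c(0.005, 0.02, 0.05, 0.1, 0.2),
                                ...) {
  type <- match.arg(type)
  switch(type,
         gain = stimulus_gain(object, f, ...),
         rho = predict_rho(object, T_grid, ...),
         filter = feedback_filter(object, f, ...),
         cellular = operating_point(object, f),
         snr = snr_table(object, ...))
}

# EGp operating point: mean depolarisation by the pooled deep spikes, and
# voltage fluctuations from intrinsic noise, pooled shot noise of the
# (conditionally independent) deep spiking, and the stimulus-locked
# modulation of the pooled deep rate, which all EGp cells share
egp_point <- function(p, p_locked, c_deep, deep_wide) {
  mu_E <- p$mu_E + p$tau_E * p$J_DE * deep_wide$r0
  var_shot <- p$J_DE^2 * deep_wide$r0 * p$tau_E / (2 * p$N_D)
  # voltage variance of the shared drive after membrane filtering
  # (effective-diffusion approximation for the coloured common input)
  H <- p$tau_E * p$J_DE * p_locked * deep_wide$A *
    sqrt(2 * p$tau_D) * p$g_A * sqrt(c_deep)
  var_stim <- 2 * pracma::trapz(deep_wide$f,
                                Mod(H)^2 /
                                  (1 + (2 * pi * deep_wide$f * p$tau_E)^2))
  sig_E <- sqrt(p$sigma^2 + var_shot + var_stim)
  list(mu_E = mu_E, sig_E = sig_E,
       r_E = lif_rate(mu_E, sig_E, p$tau_E, p$V_th, p$V_r))
}

# spline interpolation of a lif_linear_response result onto a new frequency
# grid (A and C0 are smooth in log f; endpoints clamped)
interp_response <- function(cr, f_new) {
  pos <- cr$f > 0
  lf <- log(cr$f[pos])
  lfn <- log(pmax(f_new, min(cr$f[pos])))
  lfn <- pmin(lfn, max(lf))
  A <- complex(real = stats::spline(lf, Re(cr$A[pos]), xout = lfn)$y,
               imaginary = stats::spline(lf, Im(cr$A[pos]), xout = lfn)$y)
  C0 <- pmax(stats::spline(lf, cr$C0[pos], xout = lfn)$y, 0)
  list(f = f_new, r0 = cr$r0, A = A, C0 = C0, params = cr$params)
}

#' Effective synaptic strength of a mixed excitatory/inhibitory projection
#'
#' When the EGp to superficial projection contains a fraction `frac_exc` of
#' excitatory synapses of strength `g_E` and inhibitory synapses of strength
#' `g_I`, the net coupling entering the feedback filter is
#' `frac_exc * g_E - (1 - frac_exc) * g_I`.
#'
#' @param frac_exc fraction of excitatory synapses in `[0, 1]`.
#' @param g_E,g_I non-negative synaptic strengths (mV).
#' @return Signed effective coupling (mV).
#' @export
effective_coupling <- function(frac_exc, g_E, g_I) {
  stopifnot(frac_exc >= 0, frac_exc <= 1, g_E >= 0, g_I >= 0)
  frac_exc * g_E - (1 - frac_exc) * g_I
}
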