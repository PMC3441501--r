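#' Stationary firing rate of a leaky integrate-and-fire neuron
#'
#' White-noise-driven LIF with membrane equation
#' `tau dV/dt = mu - V + sqrt(2 tau) sigma xi(t)` (so `sigma` is the
#' stationary voltage standard deviation in the absence of threshold),
#' threshold `V_th`, reset `V_r`. The rate is the inverse mean first-passage
#' time (Siegert integral); `sigma = 0` falls back to the deterministic
#' oscillator rate `1 / (tau log((mu - V_r)/(mu - V_th)))`.
#'
#' @param mu effective bias (mV).
#' @param sigma voltage noise standard deviation (mV), `>= 0`.
#' @param tau membrane time constant (s).
#' @param V_th,V_r threshold and reset voltages (mV).
#' @return Firing rate in Hz.
#' @export
lif_rate <- function(mu, sigma, tau, V_th = -55, V_r = -65) {
  stopifnot(is.finite(mu), is.finite(sigma), sigma >= 0, tau > 0,
            V_r < V_th)
  if (sigma == 0) {
    if (mu <= V_th) return(0)
    return(1 / (tau * log((mu - V_r) / (mu - V_th))))
  }
  s <- sqrt(2) * sigma  # Siegert-convention noise scale
  lo <- (V_r - mu) / s
  hi <- (V_th - mu) / s
  if (hi > 7) return(0)  # > 7 noise sd below threshold: rate < 1e-10 Hz
  val <- stats::integrate(function(u) pracma::erfcx(-u), lo, hi,
                          rel.tol = 1e-10, abs.tol = 0)$value
  1 / (tau * sqrt(pi) * val)
}

#' Linear response of the white-noise LIF by threshold integration
#'
#' Solves the Fokker-Planck equation of the LIF on a voltage grid by
#' backward (threshold-to-lower-bound) integration, yielding the stationary
#' rate `r0`, the cellular response function `A(f)` (rate modulation per mV
#' of bias modulation, complex), and the spontaneous spike-train power
#' spectrum `C0(f)` obtained from the first-passage-time density through the
#' renewal relation `C0 = r0 (1 - |ft|^2) / |1 - ft|^2`. The `f = 0` value
#' of `A` is computed analytically as the derivative of the stationary rate
#' with respect to `mu` (fluctuation-response relation); `C0(0)` is not
#' evaluated (use a small positive frequency).
#'
#' @inheritParams lif_rate
#' @param f vector of frequencies in Hz (may include 0).
#' @param n_grid number of voltage grid steps (default chosen to resolve
#'   both the noise scale and the fastest requested oscillation).
#' @return List with `f`, `r0` (Hz), `A` (complex, Hz/mV), `C0` (Hz),
#'   `f_tilde` (complex FPT density transform), and the parameters.
#' @export
lif_linear_response <- function(mu, sigma, tau, V_th = -55, V_r = -65,
                                f = lif_frequency_grid(), n_grid = NULL) {
  stopifnot(sigma > 0, tau > 0, V_r < V_th)
  D <- sigma^2 / tau
  V_lb <- min(V_r, mu) - 6 * sigma
  # snap the grid so that V_r is a grid point
  m_up <- max(64L, ceiling((V_th - V_r) / (sigma / 40)))
  h <- (V_th - V_r) / m_up
  m_dn <- ceiling((V_r - V_lb) / h)
  if (!is.null(n_grid)) {
    h <- (V_th - V_r) / max(16L, round(n_grid * (V_th - V_r) /
                                         (V_th - V_r + V_r - V_lb)))
    m_up <- round((V_th - V_r) / h)
    h <- (V_th - V_r) / m_up
    m_dn <- ceiling((V_r - V_lb) / h)
  }
  V_lb <- V_r - m_dn * h
  n <- m_up + m_dn
  Vgrid <- V_th - h * (0:n)          # descending
  i_reset <- m_up + 1L               # index of V_r in Vgrid

  # stationary solution at half-step resolution (for RK4 substeps)
  Vh <- V_th - (h / 2) * (0:(2 * n))
  p0h <- numeric(2 * n + 1)
  j0h <- ifelse(Vh > V_r - 1e-12, 1, 0)
  a_h <- (mu - Vh) / sigma^2
  b <- tau / sigma^2
  for (k in seq_len(2 * n)) {        # RK4 on p0 with step -h/2
    hs <- -h / 2
    Vk <- Vh[k]
    pk <- p0h[k]
    jfun <- function(V) if (V > V_r - 1e-12) 1 else 0
    f1 <- (mu - Vk) / sigma^2 * pk - b * jfun(Vk)
    Vm <- Vk + hs / 2
    f2 <- (mu - Vm) / sigma^2 * (pk + hs / 2 * f1) - b * jfun(Vm)
    f3 <- (mu - Vm) / sigma^2 * (pk + hs / 2 * f2) - b * jfun(Vm)
    Ve <- Vk + hs
    f4 <- (mu - Ve) / sigma^2 * (pk + hs * f3) - b * jfun(Ve)
    p0h[k + 1] <- pk + hs / 6 * (f1 + 2 * f2 + 2 * f3 + f4)
  }
  p0h <- pmax(p0h, 0)
  p0 <- p0h[seq(1, 2 * n + 1, by = 2)]
  r0 <- 1 / pracma::trapz(rev(Vgrid), rev(p0))
  P0h <- r0 * p0h                    # normalised density on half grid

  pos <- f > 0
  fpos <- f[pos]
  omega <- 2 * pi * fpos
  nf <- length(omega)
  A <- complex(length(f))
  f_tilde <- complex(length(f))

  if (nf) {
    # vectorised RK4 over frequencies for the (p, j) pair, integrating from
    # V_th down; three solutions:
    #   A: free, (p, j)(V_th) = (0, 1), no reset jump      [FPT homogeneous]
    #   B: starts at V_r with (0, -1)                      [FPT source]
    #   P: particular with drive P0(V)/sigma^2, (0, 0)     [bias modulation]
    iw <- 1i * omega
    deriv <- function(V, p, j, drv) {
      list(dp = (mu - V) / sigma^2 * p - b * j + drv,
           dj = -iw * p)
    }
    step_rk4 <- function(k, p, j, drv3) {
      # one step from grid point k to k+1 (V decreasing by h);
      # drv3 = drive at (V_k, V_k - h/2, V_k - h), zeros if no drive
      hs <- -h
      Vk <- Vgrid[k]
      d1 <- deriv(Vk, p, j, drv3[1])
      d2 <- deriv(Vk - h / 2, p + hs / 2 * d1$dp, j + hs / 2 * d1$dj, drv3[2])
      d3 <- deriv(Vk - h / 2, p + hs / 2 * d2$dp, j + hs / 2 * d2$dj, drv3[2])
      d4 <- deriv(Vk - h, p + hs * d3$dp, j + hs * d3$dj, drv3[3])
      list(p = p + hs / 6 * (d1$dp + 2 * d2$dp + 2 * d3$dp + d4$dp),
           j = j + hs / 6 * (d1$dj + 2 * d2$dj + 2 * d3$dj + d4$dj))
    }
    zero3 <- c(0, 0, 0)
    pA <- complex(nf); jA <- rep(1 + 0i, nf)
    pP <- complex(nf); jP <- complex(nf)
    for (k in seq_len(n)) {
      sA <- step_rk4(k, pA, jA, zero3)
      pA <- sA$p; jA <- sA$j
      drv <- P0h[c(2 * k - 1, 2 * k, 2 * k + 1)] / sigma^2
      sP <- step_rk4(k, pP, jP, drv)
      pP <- sP$p; jP <- sP$j
    }
    pB <- complex(nf); jB <- rep(-1 + 0i, nf)
    if (i_reset <= n) {
      for (k in i_reset:n) {
        sB <- step_rk4(k, pB, jB, zero3)
        pB <- sB$p; jB <- sB$j
      }
    }
    ft <- -jB / jA
    Apos <- -jP / (jA + jB)
    A[pos] <- Apos
    f_tilde[pos] <- ft
  }
  if (any(!pos)) {
    dr <- 1e-3
    A[!pos] <- (lif_rate(mu + dr, sigma, tau, V_th, V_r) -
                  lif_rate(mu - dr, sigma, tau, V_th, V_r)) / (2 * dr)
    f_tilde[!pos] <- 1
  }
  C0 <- rep(NA_real_, length(f))
  C0[pos] <- r0 * (1 - Mod(f_tilde[pos])^2) / Mod(1 - f_tilde[pos])^2
  C0 <- pmax(C0, 0)
  list(f = f, r0 = r0, A = A, C0 = C0, f_tilde = f_tilde,
       params = list(mu = mu, sigma = sigma, tau = tau, V_th = V_th,
                     V_r = V_r))
}

#' Default logarithmic frequency grid for theory curves
#'
#' @param f_min,f_max range in Hz.
#' @param n number of points.
#' @return Numeric vector of frequencies.
#' @export
lif_frequency_grid <- function(f_min = 0.1, f_max = 500, n = 200) {
  exp(seq(log(f_min), log(f_max), length.out = n))
}

#' Cellular response function A(f) of the LIF
#'
#' Susceptibility of the firing rate to a weak sinusoidal bias (current)
#' modulation, independent of any network feedback. See
#' [lif_linear_response()] for the numerical scheme.
#'
#' @inheritParams lif_linear_response
#' @return Object of class `cellular_response` with `f`, `A` (complex,
#'   Hz/mV), `r0`, and `C0`.
#' @export
lif_susceptibility <- function(mu, sigma, tau, V_th = -55, V_r = -65,
                               f = lif_frequency_grid()) {
  res <- lif_linear_response(mu, sigma, tau, V_th, V_r, f)
  structure(res, class = "cellular_response")
}

#' Spontaneous spike-train power spectrum C0(f) of the LIF
#'
#' Renewal-theory spectrum computed from the first-passage-time density;
#' approaches the stationary rate `r0` at high frequency.
#'
#' @inheritParams lif_linear_response
#' @return Object of class `cellular_response` (same fields as
#'   [lif_susceptibility()]).
#' @export
lif_power_spectrum <- function(mu, sigma, tau, V_th = -55, V_r = -65,
                               f = lif_frequency_grid()) {
  res <- lif_linear_response(mu, sigma, tau, V_th, V_r, f)
  structure(res, class = "cellular_response")
}

#' @export
print.cellular_response <- function(x, ...) {
  cat(sprintf(
    "<cellular_response> r0 = %.2f Hz; A(0+) = %.3g Hz/mV; %d freqs\n",
    x$r0, Mod(x$A[1]), length(x$f)))
  invisible(x)
}

#' @export
plot.cellular_response <- function(x, which = c("A", "C0"), ...) {
  which <- match.arg(which)
  ok <- x$f > 0
  if (which == "A") {
    graphics::plot(x$f[ok], Mod(x$A[ok]), log = "x", type = "l",
                   xlab = "frequency (Hz)", ylab = "|A(f)| (Hz/mV)", ...)
  } else {
    graphics::plot(x$f[ok], x$C0[ok], log = "x", type = "l",
                   xlab = "frequency (Hz)", ylab = "C0(f) (Hz)", ...)
  }
  invisible(x)
}
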