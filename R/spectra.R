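#' Cross- and power-spectral density estimation
#'
#' Averaged modified periodograms (Welch's method) with a Hann taper, 50%
#' segment overlap, and a power-of-two segment length nearest 4 s, which
#' resolves about 0.25 Hz while still averaging tens of segments on a 60 s
#' recording. Spike trains enter as binarised rate signals `n_b / dt` with
#' the global mean removed, so for a homogeneous Poisson train the power
#' spectrum is flat at the firing rate. The Fourier convention is ordinary
#' frequency in Hz with kernel `exp(-2 pi i f tau)`; the returned values are
#' the two-sided density evaluated on the non-negative frequency grid
#' (`C(-f) = Conj(C(f))` is implied).
#'
#' @param a,b a [spike_train()], a [make_stimulus()] object, or a numeric
#'   vector with an `dt` attribute (sample interval in s). `b` defaults to
#'   `a`, giving the power spectrum.
#' @param seg_len segment length in samples; default nearest power of two
#'   to 4 s.
#' @param overlap fractional segment overlap (default 0.5).
#' @return An object of class `spectral_density` with fields `f` (Hz),
#'   `values` (complex), and the estimator metadata.
#' @export
estimate_spectra <- function(a, b = a, seg_len = NULL, overlap = 0.5) {
  sa <- as_signal(a)
  sb <- if (identical(a, b)) sa else as_signal(b)
  if (abs(sa$dt - sb$dt) > 1e-12)
    stop("signals have mismatched sampling intervals")
  n <- min(length(sa$x), length(sb$x))
  if (n < 8) stop("signal too short for spectral estimation")
  if (is.null(seg_len)) seg_len <- 2^round(log2(4 / sa$dt))
  seg_len <- min(seg_len, 2^floor(log2(n)))
  step <- max(1L, round(seg_len * (1 - overlap)))
  starts <- seq.int(1L, n - seg_len + 1L, by = step)
  if (length(starts) < 2L)
    warning("fewer than 2 averaging segments; spectral estimate is noisy")
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(seg_len) / (seg_len + 1))  # Hann
  W <- sum(w^2)
  xa <- sa$x - mean(sa$x)
  xb <- sb$x - mean(sb$x)
  nf <- seg_len %/% 2 + 1L
  acc <- complex(nf)
  for (s0 in starts) {
    idx <- s0:(s0 + seg_len - 1L)
    A <- stats::fft(w * xa[idx])[1:nf]
    B <- stats::fft(w * xb[idx])[1:nf]
    acc <- acc + Conj(A) * B
  }
  vals <- acc * sa$dt / (W * length(starts))
  same <- identical(a, b)
  if (same) vals <- complex(real = pmax(Re(vals), 0), imaginary = 0)
  structure(list(f = (0:(nf - 1L)) / (seg_len * sa$dt), values = vals,
                 dt = sa$dt, seg_len = seg_len, n_seg = length(starts),
                 overlap = overlap, taper = "hann",
                 kind = if (same) "power" else "cross"),
            class = "spectral_density")
}

as_signal <- function(x) {
  if (inherits(x, "spike_train")) {
    list(x = bin_spikes(x) / x$bin_width, dt = x$bin_width)
  } else if (inherits(x, "stimulus")) {
    list(x = x$samples, dt = x$dt_sample)
  } else if (is.numeric(x) && !is.null(attr(x, "dt"))) {
    list(x = as.numeric(x), dt = attr(x, "dt"))
  } else {
    stop("expected a spike_train, a stimulus, or a numeric vector with a ",
         "'dt' attribute")
  }
}

#' @export
print.spectral_density <- function(x, ...) {
  cat(sprintf(
    "<spectral_density> %s, %d freqs up to %.1f Hz (df = %.3g Hz), %d segments\n",
    x$kind, length(x$f), max(x$f), x$f[2], x$n_seg))
  invisible(x)
}

#' @export
plot.spectral_density <- function(x, ...) {
  graphics::plot(x$f[-1], Re(x$values[-1]), type = "l", log = "x",
                 xlab = "frequency (Hz)", ylab = "spectral density", ...)
  invisible(x)
}

# squared sinc-type window kernel (sin(pi f T) / (pi f))^2, = T^2 at f = 0
sinc_kernel <- function(f, T) {
  k <- ifelse(f == 0, T^2, (sin(pi * f * T) / (pi * f))^2)
  k
}

#' Spike-count covariance from a spectral density
#'
#' Wiener-Khinchin route to count statistics: the count covariance over a
#' window `T` equals `int C(f) (sin(pi f T) / (pi f))^2 df` over the whole
#' frequency axis. For large `T` only the zero-frequency part of the
#' spectrum contributes (the kernel narrows to a delta of mass `T`); for
#' small `T` all frequencies contribute with weight `T^2`.
#'
#' @param C a `spectral_density` (cross-spectrum or power spectrum).
#' @param T counting-window length in seconds. The grid must resolve
#'   `1/(10 T)` or an error is thrown.
#' @return Count covariance (variance for a power spectrum).
#' @export
count_stats_from_spectra <- function(C, T) {
  stopifnot(inherits(C, "spectral_density"), T > 0)
  df <- C$f[2] - C$f[1]
  if (df > 1 / (10 * T))
    stop("frequency grid too coarse for requested T (need df <= 1/(10 T))")
  2 * pracma::trapz(C$f, Re(C$values) * sinc_kernel(C$f, T))
}

#' Stimulus gain of a spiking response
#'
#' Estimates the frequency-resolved linear transfer from a stimulus to a
#' spike train as the ratio of the response-stimulus cross-spectrum to the
#' stimulus power spectrum. Frequencies where the stimulus carries
#' negligible power are masked to `NaN` with a warning.
#'
#' @param y the response [spike_train()].
#' @param s the stimulus (a [make_stimulus()] object or numeric with `dt`
#'   attribute), sampled at the spike-train bin width.
#' @param ... passed to [estimate_spectra()].
#' @param power_tol relative stimulus-power threshold below which the gain
#'   is masked.
#' @return An object of class `gain_fun` with `f` (Hz) and complex `values`
#'   (spikes/s per stimulus unit), `provenance = "estimated"`.
#' @export
estimate_gain <- function(y, s, ..., power_tol = 1e-6) {
  S_ys <- estimate_spectra(s, y, ...)
  S_ss <- estimate_spectra(s, ...)
  vals <- S_ys$values / S_ss$values
  weak <- Re(S_ss$values) < power_tol * max(Re(S_ss$values))
  if (any(weak)) {
    warning(sum(weak), " frequencies have negligible stimulus power; ",
            "gain masked to NaN there")
    vals[weak] <- NaN
  }
  structure(list(f = S_ys$f, values = vals, provenance = "estimated",
                 n_seg = S_ys$n_seg),
            class = "gain_fun")
}

#' @export
print.gain_fun <- function(x, ...) {
  cat(sprintf("<gain_fun> (%s) %d freqs up to %.1f Hz; |G(f1)| = %.3g\n",
              x$provenance, length(x$f), max(x$f), abs(x$values[2])))
  invisible(x)
}

#' @export
plot.gain_fun <- function(x, ...) {
  ok <- x$f > 0 & is.finite(x$values)
  graphics::plot(x$f[ok], Mod(x$values[ok]), type = "l", log = "x",
                 xlab = "frequency (Hz)", ylab = "|G(f)| (spk/s per unit)", ...)
  invisible(x)
}

#' Predicted spike-count covariance from stimulus gains
#'
#' Under conditional independence of the two spike trains given the
#' stimulus, the stimulus-induced cross-spectrum is
#' `G_i(f) Conj(G_j(f)) S_ss(f)`; its sinc-kernel integral predicts the
#' across-trial spike-count covariance over a window `T`.
#'
#' @param G_i,G_j `gain_fun` objects on a common frequency grid.
#' @param S_ss stimulus power `spectral_density` on the same grid.
#' @param T counting-window length in seconds.
#' @return Predicted count covariance.
#' @export
predict_count_cov_from_gains <- function(G_i, G_j, S_ss, T) {
  stopifnot(inherits(G_i, "gain_fun"), inherits(G_j, "gain_fun"),
            inherits(S_ss, "spectral_density"))
  if (length(G_i$f) != length(G_j$f) || length(G_i$f) != length(S_ss$f) ||
      max(abs(G_i$f - S_ss$f)) > 1e-9 || max(abs(G_i$f - G_j$f)) > 1e-9)
    stop("frequency grids do not match")
  integrand <- Re(G_i$values * Conj(G_j$values) * Re(S_ss$values))
  integrand[!is.finite(integrand)] <- 0
  2 * pracma::trapz(G_i$f, integrand * sinc_kernel(G_i$f, T))
}

#' Predicted across-trial count correlation from gains and count variances
#'
#' Normalises the gain-predicted count covariance by the geometric mean of
#' the (measured or theoretical) count variances.
#'
#' @inheritParams predict_count_cov_from_gains
#' @param var_i,var_j spike-count variances over the same window `T`.
#' @return Predicted correlation, or `NaN` when a variance is zero.
#' @export
predict_across_trial_rho <- function(G_i, G_j, S_ss, var_i, var_j, T) {
  if (var_i <= 0 || var_j <= 0) {
    warning("zero count variance; predicted correlation is NaN")
    return(NaN)
  }
  predict_count_cov_from_gains(G_i, G_j, S_ss, T) / sqrt(var_i * var_j)
}
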