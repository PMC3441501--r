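#' Spike-train cross-covariance function
#'
#' Empirical covariance density between two binarised spike trains expressed
#' in rate units (spikes^2/s^2): `c_ab(tau) = <a(t) b(t+tau)> - r_a r_b`,
#' evaluated on the lag grid `tau = m * bin_width`, `|tau| <= max_lag`. With
#' `a` and `b` the same train the result is the auto-covariance, whose lag-0
#' value carries the delta-like term `r/dt - r^2`.
#'
#' @param a,b [spike_train()] objects sharing duration and bin width.
#' @param max_lag largest lag in seconds (default 0.25 s, which covers both
#'   the synchrony and the rate co-variation timescales of interest).
#' @return An object of class `cov_fun` with fields `lags` (s) and `values`.
#' @export
cross_covariance <- function(a, b = a, max_lag = 0.25) {
  stopifnot(inherits(a, "spike_train"), inherits(b, "spike_train"))
  if (abs(a$bin_width - b$bin_width) > 1e-12)
    stop("trains have mismatched bin widths")
  if (abs(a$duration - b$duration) > 1e-9)
    stop("trains have mismatched durations")
  if (max_lag >= a$duration / 2)
    stop("max_lag must be below half the duration")
  dt <- a$bin_width
  ya <- bin_spikes(a) / dt
  yb <- bin_spikes(b) / dt
  n <- length(ya)
  m <- round(max_lag / dt)
  raw <- fft_cross_sum(ya, yb, m) / n
  lags <- seq(-m, m) * dt
  vals <- raw - mean(ya) * mean(yb)
  structure(list(lags = lags, values = vals, bin_width = dt,
                 n_bins = n, kind = "within_trial"),
            class = "cov_fun")
}

# sum_t x(t) y(t + m) for m = -max_m..max_m via zero-padded FFT
fft_cross_sum <- function(x, y, max_m) {
  n <- length(x)
  nfft <- 2^ceiling(log2(n + max_m + 1))
  X <- stats::fft(c(x, numeric(nfft - n)))
  Y <- stats::fft(c(y, numeric(nfft - n)))
  cc <- Re(stats::fft(Conj(X) * Y, inverse = TRUE)) / nfft
  # lag m >= 0 at index m + 1; lag m < 0 wraps to index nfft + m + 1
  c(cc[nfft + seq(-max_m, -1) + 1], cc[seq(0, max_m) + 1])
}

#' @export
print.cov_fun <- function(x, ...) {
  cat(sprintf("<cov_fun> %s, lags +/- %g ms (%d points), bin %.3g ms\n",
              x$kind, 1e3 * max(x$lags), length(x$lags), 1e3 * x$bin_width))
  invisible(x)
}

#' @export
plot.cov_fun <- function(x, ...) {
  graphics::plot(1e3 * x$lags, x$values, type = "l",
                 xlab = "lag (ms)", ylab = "covariance (spikes^2/s^2)", ...)
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}

#' Across-trial spike-train covariance
#'
#' Average of the cross-covariance between the response of neuron `i` in
#' trial `k` and neuron `j` in trial `l` over all ordered trial pairs
#' `k != l`. Because the two responses are never recorded simultaneously but
#' share the frozen stimulus, this isolates the stimulus-locked (signal)
#' component of the covariance; trial-to-trial noise correlations average out.
#'
#' @param ens a [trial_ensemble()] with at least two trials.
#' @param i,j neuron indices.
#' @param max_lag largest lag in seconds.
#' @return A `cov_fun` with `kind = "across_trial"`.
#' @export
across_trial_covariance <- function(ens, i, j, max_lag = 0.25) {
  stopifnot(inherits(ens, "trial_ensemble"))
  if (ens$n_trials < 2L)
    stop("across-trial covariance requires at least two trials")
  dt <- ens$bin_width
  if (max_lag >= ens$duration / 2)
    stop("max_lag must be below half the duration")
  m <- round(max_lag / dt)
  K <- ens$n_trials
  yi <- lapply(seq_len(K), function(k) {
    y <- bin_spikes(ens$trains[[k]][[i]]) / dt
    y - mean(y)
  })
  yj <- lapply(seq_len(K), function(k) {
    y <- bin_spikes(ens$trains[[k]][[j]]) / dt
    y - mean(y)
  })
  n <- length(yi[[1]])
  # sum over ordered pairs k != l equals (sum_k)(sum_l) minus the diagonal
  tot <- fft_cross_sum(Reduce(`+`, yi), Reduce(`+`, yj), m)
  diag_sum <- Reduce(`+`, lapply(seq_len(K),
                                 function(k) fft_cross_sum(yi[[k]], yj[[k]], m)))
  vals <- (tot - diag_sum) / (K * (K - 1)) / n
  structure(list(lags = seq(-m, m) * dt, values = vals, bin_width = dt,
                 n_bins = n, kind = "across_trial"),
            class = "cov_fun")
}

#' Across-trial spike-count correlation
#'
#' Count covariance between neurons `i` and `j` taken from distinct trials of
#' a frozen-stimulus ensemble (all ordered trial pairs `k != l`), normalised
#' by the geometric mean of the within-trial count variances. This is the
#' signal (stimulus) correlation at counting window `window_T`.
#'
#' @param ens a [trial_ensemble()] with at least two trials.
#' @param i,j neuron indices.
#' @param window_T counting-window length in seconds.
#' @param stride window stride in seconds (default one bin).
#' @return A correlation value in `[-1, 1]`, or `NaN` for zero variance.
#' @export
across_trial_correlation <- function(ens, i, j, window_T,
                                     stride = ens$bin_width) {
  stopifnot(inherits(ens, "trial_ensemble"))
  if (ens$n_trials < 2L)
    stop("across-trial correlation requires at least two trials")
  K <- ens$n_trials
  Ni <- lapply(seq_len(K), function(k)
    spike_counts(ens$trains[[k]][[i]], window_T, stride)$counts)
  Nj <- lapply(seq_len(K), function(k)
    spike_counts(ens$trains[[k]][[j]], window_T, stride)$counts)
  covs <- numeric(0)
  for (k in seq_len(K)) for (l in seq_len(K)) if (k != l)
    covs <- c(covs, stats::cov(Ni[[k]], Nj[[l]]))
  vi <- mean(vapply(Ni, stats::var, 0))
  vj <- mean(vapply(Nj, stats::var, 0))
  if (vi == 0 || vj == 0) {
    warning("zero count variance; correlation undefined (NaN)")
    return(NaN)
  }
  mean(covs) / sqrt(vi * vj)
}

#' Spike-count covariance from a covariance function
#'
#' Uses the standard relation between second-order spike-train and
#' spike-count statistics: the count covariance over a window `T` is the
#' triangular-kernel integral `int_{-T}^{T} (T - |tau|) c(tau) dtau`.
#'
#' @param c a `cov_fun` (from [cross_covariance()] or
#'   [across_trial_covariance()]).
#' @param T counting-window length in seconds; must not exceed the available
#'   lag range.
#' @return Count covariance (count variance when `c` is an auto-covariance).
#' @export
count_cov_from_covfun <- function(c, T) {
  stopifnot(inherits(c, "cov_fun"), T > 0)
  if (T > max(c$lags) + c$bin_width / 2)
    stop("T exceeds the available lag range of the covariance function")
  keep <- abs(c$lags) <= T
  sum((T - abs(c$lags[keep])) * c$values[keep]) * c$bin_width
}

#' Spike-count correlation as a function of window size
#'
#' Evaluates the pairwise spike-count correlation coefficient over a grid of
#' counting-window lengths, either within-trial (simultaneous counts,
#' averaged over trials) or across-trial (frozen-stimulus signal
#' correlation).
#'
#' @param ens a [trial_ensemble()].
#' @param i,j neuron indices.
#' @param windows_T vector of window lengths in seconds.
#' @param kind `"within_trial"` or `"across_trial"`.
#' @param stride window stride in seconds (default one bin).
#' @return An object of class `correlation_curve` with `windows_T` and `rho`.
#' @export
correlation_curve <- function(ens, i = 1L, j = 2L,
                              windows_T = c(0.005, 0.02, 0.05, 0.1, 0.2),
                              kind = c("within_trial", "across_trial"),
                              stride = ens$bin_width) {
  stopifnot(inherits(ens, "trial_ensemble"))
  kind <- match.arg(kind)
  rho <- vapply(windows_T, function(T) {
    if (kind == "across_trial") {
      across_trial_correlation(ens, i, j, T, stride)
    } else {
      mean(vapply(seq_len(ens$n_trials), function(k) {
        count_correlation(spike_counts(ens$trains[[k]][[i]], T, stride),
                          spike_counts(ens$trains[[k]][[j]], T, stride))
      }, 0))
    }
  }, 0)
  structure(list(windows_T = windows_T, rho = rho, kind = kind),
            class = "correlation_curve")
}

#' @export
print.correlation_curve <- function(x, ...) {
  cat(sprintf("<correlation_curve> (%s)\n", x$kind))
  print(data.frame(T_ms = 1e3 * x$windows_T, rho = signif(x$rho, 4)),
        row.names = FALSE)
  invisible(x)
}

#' @export
plot.correlation_curve <- function(x, ...) {
  graphics::plot(1e3 * x$windows_T, x$rho, log = "x", type = "b",
                 xlab = "window T (ms)", ylab = expression(rho(T)), ...)
  invisible(x)
}
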