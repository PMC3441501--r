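#' Generate a stimulus trace
#'
#' Produces a zero-mean, unit-variance sampled stimulus, optionally low-pass
#' filtered with an 8th-order Butterworth filter (cutoff 120 Hz), and
#' optionally with frozen-noise structure: a single noise epoch of
#' `frozen_segment_s` seconds repeated `n_repeats` times bit-identically,
#' which is the experimental protocol that makes across-trial (signal)
#' correlation estimates possible.
#'
#' @param kind `"white"` or `"butterworth_lowpass"`.
#' @param duration total duration in seconds. When frozen structure is
#'   requested it must equal `frozen_segment_s * n_repeats`.
#' @param dt sample interval in seconds (default 1e-4, i.e. 10 kHz).
#' @param seed integer seed; the trace is fully determined by its arguments.
#' @param frozen_segment_s frozen epoch length in seconds (`NULL` for none).
#' @param n_repeats number of repeats of the frozen epoch.
#' @param cutoff_hz,order Butterworth low-pass parameters.
#' @return An object of class `stimulus` with `samples`, `dt_sample`, and
#'   the generation metadata.
#' @export
make_stimulus <- function(kind = c("white", "butterworth_lowpass"),
                          duration, dt = 1e-4, seed = 1L,
                          frozen_segment_s = NULL, n_repeats = 1L,
                          cutoff_hz = 120, order = 8L) {
  kind <- match.arg(kind)
  stopifnot(duration > 0, dt > 0)
  if (!is.null(frozen_segment_s)) {
    if (abs(duration - frozen_segment_s * n_repeats) > dt / 2)
      stop("duration must equal frozen_segment_s * n_repeats")
    n_epoch <- round(frozen_segment_s / dt)
  } else {
    n_repeats <- 1L
    n_epoch <- round(duration / dt)
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  epoch <- stats::rnorm(n_epoch)
  if (kind == "butterworth_lowpass") {
    ny <- 1 / (2 * dt)
    if (cutoff_hz >= ny) stop("cutoff must be below the Nyquist frequency")
    bf <- signal::butter(order, cutoff_hz / ny, type = "low")
    epoch <- signal::filter(bf, epoch)
    epoch <- as.numeric(epoch)
  }
  epoch <- (epoch - mean(epoch)) / stats::sd(epoch)
  samples <- rep(epoch, n_repeats)
  structure(list(samples = samples, dt_sample = dt, kind = kind,
                 frozen_segment_s = frozen_segment_s, n_repeats = n_repeats,
                 seed = seed, cutoff_hz = if (kind == "white") NULL else cutoff_hz,
                 order = if (kind == "white") NULL else order),
            class = "stimulus")
}

#' @export
print.stimulus <- function(x, ...) {
  cat(sprintf("<stimulus> %s, %.1f s at %.0f kHz", x$kind,
              length(x$samples) * x$dt_sample, 1e-3 / x$dt_sample))
  if (!is.null(x$frozen_segment_s))
    cat(sprintf(", frozen %g s x %d", x$frozen_segment_s, x$n_repeats))
  cat("\n")
  invisible(x)
}

#' Frozen-noise stimulation protocol
#'
#' Convenience wrapper reproducing the standard electrosensory stimulation
#' protocol: Gaussian noise low-pass filtered at 120 Hz (8th-order
#' Butterworth), one 20 s frozen epoch repeated 6 times, sampled at 10 kHz
#' (120 s in total).
#'
#' @param seed integer seed.
#' @param frozen_segment_s,n_repeats,dt protocol parameters, defaulting to
#'   the standard values.
#' @return A `stimulus` object.
#' @export
frozen_protocol <- function(seed = 1L, frozen_segment_s = 20, n_repeats = 6L,
                            dt = 1e-4) {
  make_stimulus("butterworth_lowpass",
                duration = frozen_segment_s * n_repeats, dt = dt, seed = seed,
                frozen_segment_s = frozen_segment_s, n_repeats = n_repeats)
}

#' Resample a stimulus by bin averaging
#'
#' Averages consecutive samples so the stimulus lives on the spike-train bin
#' grid (needed by [estimate_gain()] when the stimulus was sampled faster
#' than the spike bin width).
#'
#' @param stim a `stimulus`.
#' @param bin_width target sample interval in seconds (integer multiple of
#'   the current one).
#' @return A `stimulus` at the coarser sampling.
#' @export
resample_stimulus <- function(stim, bin_width) {
  stopifnot(inherits(stim, "stimulus"))
  k <- round(bin_width / stim$dt_sample)
  if (k < 1 || abs(k * stim$dt_sample - bin_width) > 1e-12)
    stop("bin_width must be an integer multiple of the sample interval")
  if (k == 1L) return(stim)
  n <- (length(stim$samples) %/% k) * k
  out <- stim
  out$samples <- colMeans(matrix(stim$samples[1:n], nrow = k))
  out$dt_sample <- bin_width
  out
}
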