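#' Spike train object
#'
#' A spike train is an ordered set of spike times on `[0, duration)` together
#' with the bin width used for all binned statistics. The bin width must be
#' small enough that no bin ever contains two spikes, so that the binarised
#' train is a lossless representation of the point process.
#'
#' @param times numeric vector of spike times in seconds, strictly increasing.
#' @param duration recording duration in seconds.
#' @param bin_width discretisation bin width in seconds (default 0.5 ms).
#' @return An object of class `spike_train`.
#' @export
spike_train <- function(times, duration, bin_width = 5e-4) {
  times <- as.numeric(times)
  stopifnot(is.numeric(duration), length(duration) == 1L, duration > 0,
            bin_width > 0, bin_width <= duration)
  if (is.unsorted(times, strictly = TRUE))
    stop("spike times must be strictly increasing")
  if (length(times) && (times[1] < 0 || times[length(times)] >= duration))
    stop("spike times must lie in [0, duration)")
  if (length(times) > 1L && anyDuplicated(floor(times / bin_width)))
    stop("two spikes fall in one bin of width bin_width; ",
         "binarisation would be lossy")
  structure(list(times = times, duration = duration, bin_width = bin_width),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> %d spikes over %.3f s (%.2f Hz), bin %.3g ms\n",
              length(x$times), x$duration, firing_rate(x),
              1e3 * x$bin_width))
  invisible(x)
}

#' Binarise a spike train
#'
#' Discretises time into bins of the train's `bin_width` and sets bin `b` to 1
#' exactly when a spike time falls in `[b*dt, (b+1)*dt)`. Errors if two spikes
#' share a bin, since the binary representation would then lose a spike.
#'
#' @param train a [spike_train()].
#' @return Integer vector of 0/1 of length `floor(duration / bin_width)`.
#' @export
bin_spikes <- function(train) {
  stopifnot(inherits(train, "spike_train"))
  nb <- floor(train$duration / train$bin_width + 1e-9)
  idx <- floor(train$times / train$bin_width) + 1L
  idx <- idx[idx >= 1L & idx <= nb]
  out <- integer(nb)
  if (anyDuplicated(idx))
    stop("two spikes fall in one bin; decrease bin_width")
  out[idx] <- 1L
  out
}

#' Mean firing rate of a spike train
#'
#' @param train a [spike_train()].
#' @return Rate in Hz (spike count / duration).
#' @export
firing_rate <- function(train) {
  stopifnot(inherits(train, "spike_train"))
  length(train$times) / train$duration
}

#' Multi-neuron, multi-trial spike train ensemble
#'
#' Container for the spike trains of several neurons recorded (or simulated)
#' over one or more repetitions of a frozen stimulus. All trains share the
#' duration and bin width. Indexed as `ens$trains[[trial]][[neuron]]`.
#'
#' @param trains list (trials) of lists (neurons) of [spike_train()] objects,
#'   or a single list of trains for a one-trial ensemble.
#' @param duration,bin_width shared recording metadata; taken from the first
#'   train when missing.
#' @return An object of class `trial_ensemble`.
#' @export
trial_ensemble <- function(trains, duration = NULL, bin_width = NULL) {
  if (length(trains) && inherits(trains[[1]], "spike_train"))
    trains <- list(trains)
  stopifnot(length(trains) >= 1L, length(trains[[1]]) >= 1L)
  t0 <- trains[[1]][[1]]
  duration <- duration %||% t0$duration
  bin_width <- bin_width %||% t0$bin_width
  for (trial in trains) for (tr in trial) {
    stopifnot(inherits(tr, "spike_train"))
    if (abs(tr$duration - duration) > 1e-9 ||
        abs(tr$bin_width - bin_width) > 1e-12)
      stop("all trains in an ensemble must share duration and bin_width")
  }
  structure(list(trains = trains, n_trials = length(trains),
                 n_neurons = length(trains[[1]]), duration = duration,
                 bin_width = bin_width),
            class = "trial_ensemble")
}

#' @export
print.trial_ensemble <- function(x, ...) {
  cat(sprintf("<trial_ensemble> %d neurons x %d trials, %.3f s, bin %.3g ms\n",
              x$n_neurons, x$n_trials, x$duration, 1e3 * x$bin_width))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Windowed spike counts
#'
#' Counts spikes in sliding windows of length `window_T`. The default stride
#' of one bin gives maximally overlapping windows, which increases the number
#' of count estimates entering downstream correlation estimators.
#'
#' @param train a [spike_train()].
#' @param window_T counting-window length in seconds.
#' @param stride window stride in seconds; defaults to one bin.
#' @return An object of class `count_series` with integer `counts`.
#' @export
spike_counts <- function(train, window_T, stride = train$bin_width) {
  stopifnot(inherits(train, "spike_train"),
            window_T > 0, window_T <= train$duration,
            stride > 0, stride <= window_T)
  b <- bin_spikes(train)
  dt <- train$bin_width
  w <- max(1L, round(window_T / dt))
  s <- max(1L, round(stride / dt))
  cs <- c(0L, cumsum(b))
  starts <- seq.int(1L, length(b) - w + 1L, by = s)
  counts <- cs[starts + w] - cs[starts]
  structure(list(counts = counts, window_T = w * dt, stride = s * dt,
                 duration = train$duration),
            class = "count_series")
}

#' @export
print.count_series <- function(x, ...) {
  cat(sprintf("<count_series> %d windows of T = %g ms (stride %g ms), mean %.3f\n",
              length(x$counts), 1e3 * x$window_T, 1e3 * x$stride,
              mean(x$counts)))
  invisible(x)
}

#' Pearson correlation between two spike-count series
#'
#' The spike-count correlation over a window `T` measures synchrony for small
#' `T` and firing-rate co-variation for large `T`. Returns `NaN` (with a
#' warning) when either count sequence has zero variance.
#'
#' @param a,b [spike_counts()] series with aligned windows of equal length.
#' @return A single correlation value in `[-1, 1]`, or `NaN`.
#' @export
count_correlation <- function(a, b) {
  stopifnot(inherits(a, "count_series"), inherits(b, "count_series"))
  if (length(a$counts) != length(b$counts))
    stop("count series have different lengths")
  if (abs(a$window_T - b$window_T) > 1e-12)
    stop("count series have different window lengths")
  va <- stats::var(a$counts)
  vb <- stats::var(b$counts)
  if (va == 0 || vb == 0) {
    warning("zero count variance; correlation undefined (NaN)")
    return(NaN)
  }
  stats::cov(a$counts, b$counts) / sqrt(va * vb)
}
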