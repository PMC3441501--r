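#' Write and read spike-time tables
#'
#' Tidy CSV interchange format for spike trains: columns `neuron_id`,
#' `trial_id`, `spike_time_s`. The reader validates ordering and range and
#' rebuilds a [trial_ensemble()].
#'
#' @param ens a [trial_ensemble()].
#' @param path file path.
#' @return `write_spike_table` returns `path` invisibly;
#'   `read_spike_table` returns a `trial_ensemble`.
#' @export
write_spike_table <- function(ens, path) {
  stopifnot(inherits(ens, "trial_ensemble"))
  rows <- list()
  for (k in seq_len(ens$n_trials)) for (i in seq_len(ens$n_neurons)) {
    tt <- ens$trains[[k]][[i]]$times
    if (length(tt))
      rows[[length(rows) + 1L]] <-
        data.frame(neuron_id = i, trial_id = k, spike_time_s = tt)
  }
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(neuron_id = integer(), trial_id = integer(),
               spike_time_s = numeric())
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spike_table
#' @param duration,bin_width metadata for the rebuilt trains (duration
#'   defaults to just past the last spike).
#' @param n_neurons,n_trials expected counts (defaulting to the maxima
#'   found in the file, so silent neurons at the high end need them).
#' @export
read_spike_table <- function(path, duration = NULL, bin_width = 5e-4,
                             n_neurons = NULL, n_trials = NULL) {
  df <- utils::read.csv(path)
  need <- c("neuron_id", "trial_id", "spike_time_s")
  if (!all(need %in% names(df)))
    stop("spike table must have columns ", paste(need, collapse = ", "))
  if (nrow(df) && min(df$spike_time_s) < 0)
    stop("negative spike time in table")
  duration <- duration %||%
    (if (nrow(df)) max(df$spike_time_s) + bin_width else 1)
  n_neurons <- n_neurons %||% max(df$neuron_id, 1L)
  n_trials <- n_trials %||% max(df$trial_id, 1L)
  trials <- lapply(seq_len(n_trials), function(k)
    lapply(seq_len(n_neurons), function(i) {
      tt <- sort(df$spike_time_s[df$neuron_id == i & df$trial_id == k])
      spike_train(tt, duration, bin_width)
    }))
  trial_ensemble(trials)
}

#' Write and read stimulus traces
#'
#' Single-column text format with a header line carrying the sample rate
#' in Hz.
#'
#' @param stim a `stimulus`.
#' @param path file path.
#' @return `write_stimulus_trace` returns `path` invisibly;
#'   `read_stimulus_trace` returns a `stimulus`.
#' @export
write_stimulus_trace <- function(stim, path) {
  stopifnot(inherits(stim, "stimulus"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# sample_rate_hz %.10g", 1 / stim$dt_sample), con)
  writeLines(format(stim$samples, digits = 10, trim = TRUE,
                    scientific = TRUE), con)
  invisible(path)
}

#' @rdname write_stimulus_trace
#' @export
read_stimulus_trace <- function(path) {
  head <- readLines(path, n = 1L)
  m <- regmatches(head, regexec("sample_rate_hz ([0-9.eE+-]+)", head))[[1]]
  if (length(m) < 2) stop("missing sample_rate_hz header line")
  fs <- as.numeric(m[2])
  x <- utils::read.table(path, skip = 1L)[[1]]
  structure(list(samples = as.numeric(x), dt_sample = 1 / fs,
                 kind = "file", frozen_segment_s = NULL, n_repeats = 1L,
                 seed = NA),
            class = "stimulus")
}

#' @export
as.data.frame.correlation_curve <- function(x, ...) {
  data.frame(window_T = x$windows_T, rho = x$rho, kind = x$kind)
}

#' @export
as.data.frame.cov_fun <- function(x, ...) {
  data.frame(lag = x$lags, covariance = x$values, kind = x$kind)
}

#' @export
as.data.frame.spectral_density <- function(x, ...) {
  data.frame(frequency = x$f, re = Re(x$values), im = Im(x$values))
}

#' @export
as.data.frame.gain_fun <- function(x, ...) {
  data.frame(frequency = x$f, re = Re(x$values), im = Im(x$values),
             modulus = Mod(x$values), provenance = x$provenance)
}

#' @export
as.data.frame.feedback_filter <- function(x, ...) {
  data.frame(frequency = x$f, re = Re(x$values), im = Im(x$values),
             modulus = Mod(x$values))
}
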