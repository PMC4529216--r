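#' Create a voltage trace object
#'
#' @param samples Numeric vector of voltages (arbitrary units).
#' @param fs Sampling rate in Hz.
#' @param t0 Time of the first sample in seconds, relative to stimulus
#'   onset (default 0).
#' @return An object of class `voltage_trace`.
#' @export
voltage_trace <- function(samples, fs, t0 = 0) {
  stopifnot(is.numeric(samples), fs > 0)
  structure(list(samples = as.numeric(samples), fs = fs, t0 = t0),
            class = "voltage_trace")
}

#' Bandpass filter a voltage trace for spike detection
#'
#' Applies a 4th-order Butterworth bandpass, forward and backward
#' (`signal::filtfilt`), so the filter is zero-phase and spike times are
#' not shifted. The default 200--2000 Hz band isolates the spectral range
#' where extracellular spike waveforms carry most of their energy while
#' rejecting local field potentials below and noise above.
#'
#' @param trace A `voltage_trace`.
#' @param lo,hi Band edges in Hz; `0 < lo < hi < fs/2`.
#' @return The filtered `voltage_trace`.
#' @export
bandpass <- function(trace, lo = 200, hi = 2000) {
  stopifnot(inherits(trace, "voltage_trace"))
  fs <- trace$fs
  if (!(lo > 0 && hi > lo)) stop("require 0 < lo < hi")
  if (hi >= fs / 2) stop("upper band edge must be below the Nyquist frequency")
  bf <- signal::butter(2, c(lo, hi) / (fs / 2), type = "pass")
  trace$samples <- signal::filtfilt(bf, trace$samples)
  trace
}

#' Detect spikes by negative threshold crossing
#'
#' Finds strict local minima of an (already bandpassed) trace whose
#' amplitude falls below `-k_sd` standard deviations of the trace's
#' amplitude distribution. The threshold is recomputed per trace, making
#' detection invariant to global gain. A dead time suppresses secondary
#' peaks of the same spike waveform.
#'
#' @param trace A bandpassed `voltage_trace`.
#' @param k_sd Threshold magnitude in standard deviations (default 3.5).
#' @param dead_time_ms Minimum separation between accepted spikes in
#'   milliseconds (default 1).
#' @param robust_sd Use 1.4826 * MAD instead of the sample SD.
#' @param trial_id,stim_id Optional labels attached to the result.
#' @return An object of class `spike_train`: list with `times` (seconds,
#'   strictly increasing, relative to stimulus onset), `trial_id`,
#'   `stim_id`, and `duration` of the recorded window.
#' @export
detect_spikes <- function(trace, k_sd = 3.5, dead_time_ms = 1,
                          robust_sd = FALSE, trial_id = NA, stim_id = NA) {
  stopifnot(inherits(trace, "voltage_trace"))
  x <- trace$samples
  n <- length(x)
  if (n / trace$fs < 0.010) {
    stop("trace shorter than 10 ms: SD estimate unreliable")
  }
  s <- if (robust_sd) stats::mad(x) else stats::sd(x)
  thr <- -abs(k_sd) * s
  times <- numeric(0)
  if (s > 0) {
    # strict local minima below threshold; ties broken to the earlier sample
    # by requiring x[i] < x[i+1] (strict) and x[i] <= x[i-1] would accept
    # plateaus twice, so both comparisons are strict.
    i <- 2:(n - 1)
    is_min <- x[i] < x[i - 1] & x[i] < x[i + 1] & x[i] < thr
    cand <- i[is_min]
    if (length(cand) > 0) {
      dead_n <- dead_time_ms / 1000 * trace$fs
      keep <- numeric(0)
      last <- -Inf
      for (p in cand) {
        if (p - last >= dead_n) {
          keep <- c(keep, p)
          last <- p
        }
      }
      times <- trace$t0 + (keep - 1) / trace$fs
    }
  }
  spike_train(times, trial_id = trial_id, stim_id = stim_id,
              duration = trace$t0 + n / trace$fs)
}

#' Create a spike train object
#'
#' @param times Spike times in seconds relative to stimulus onset.
#' @param trial_id,stim_id Trial and stimulus labels.
#' @param duration Duration of the recorded window in seconds (optional).
#' @return An object of class `spike_train`.
#' @export
spike_train <- function(times, trial_id = NA, stim_id = NA, duration = NA) {
  times <- as.numeric(times)
  if (is.unsorted(times, strictly = TRUE)) {
    stop("spike times must be strictly increasing")
  }
  structure(list(times = times, trial_id = trial_id, stim_id = stim_id,
                 duration = duration),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("Spike train: %d spikes (stim %s, trial %s)\n",
              length(x$times), as.character(x$stim_id),
              as.character(x$trial_id)))
  invisible(x)
}
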