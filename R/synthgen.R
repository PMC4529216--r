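#' Construct a ground-truth tuning function
#'
#' Builds a deterministic mean onset firing rate r(S) over the valid cells
#' of a formant grid, the "L-N" part of a linear-nonlinear-Poisson site:
#' trials are later drawn as Poisson counts around r(S) plus background.
#' Available shapes:
#' \describe{
#'   \item{flat}{constant `amplitude` everywhere (a pure-noise site when
#'     `amplitude = 0`).}
#'   \item{bump}{Gaussian bump in octave coordinates; `params$center`
#'     = c(f1_hz, f2_hz), `params$width` in octaves.}
#'   \item{ridge}{elevated response where the two formants are within
#'     `params$half_width` octaves of each other (the diagonal-stripe
#'     motif of sites preferring closely spaced formants).}
#'   \item{gradient}{linear ramp along F2 from 0 to `amplitude`.}
#'   \item{smoothed_noise}{seeded white noise on the valid cells, smoothed
#'     with a Gaussian kernel of width `params$w` octaves (normalized
#'     masked convolution), then affinely mapped to [0, amplitude]. The
#'     field's intrinsic smoothness scale is therefore `w`, which makes
#'     this kind the workhorse for parameter-recovery studies.}
#' }
#'
#' @param kind One of "flat", "bump", "ridge", "gradient",
#'   "smoothed_noise".
#' @param params List of shape parameters (see Details).
#' @param grid A `formant_grid` (default: the standard 10--20 kHz grid).
#' @param amplitude Peak evoked rate above background, Hz (default 50).
#' @param background_rate Background firing rate, Hz (default 12.5, i.e.
#'   an expected count of 1 in an 80 ms baseline window).
#' @param seed Integer seed for the smoothed-noise draw (default 1).
#' @return An object of class `ground_truth`: list with `rates` (Hz, per
#'   manifest row, evoked component, >= 0), `background_rate`, `kind`,
#'   `params`, `grid`.
#' @export
make_ground_truth <- function(kind = c("flat", "bump", "ridge", "gradient",
                                       "smoothed_noise"),
                              params = list(), grid = make_formant_grid(),
                              amplitude = 50, background_rate = 12.5,
                              seed = 1) {
  kind <- match.arg(kind)
  if (amplitude < 0 || background_rate < 0) {
    stop("rates must be non-negative")
  }
  p <- grid$pairs
  r <- switch(kind,
    flat = rep(amplitude, nrow(p)),
    bump = {
      center <- params$center %||% c(10717, 13200)
      width <- params$width %||% 0.15
      d2 <- (p$f1_oct - oct_coord(grid, center[1]))^2 +
            (p$f2_oct - oct_coord(grid, center[2]))^2
      amplitude * exp(-d2 / (2 * width^2))
    },
    ridge = {
      hw <- params$half_width %||% 0.15
      amplitude * (p$f2_oct - p$f1_oct <= hw)
    },
    gradient = {
      span <- max(p$f2_oct) - min(p$f2_oct)
      amplitude * (p$f2_oct - min(p$f2_oct)) / span
    },
    smoothed_noise = {
      w <- params$w %||% 0.1
      set.seed(seed)
      z <- stats::rnorm(nrow(p))
      coords <- cbind(p$f1_oct, p$f2_oct)
      z <- as.numeric(smoothing_matrix(coords, w) %*% z)
      if (diff(range(z)) < 1e-12) {
        rep(amplitude / 2, nrow(p))
      } else {
        amplitude * (z - min(z)) / (max(z) - min(z))
      }
    })
  structure(
    list(rates = r, background_rate = background_rate, kind = kind,
         params = params, amplitude = amplitude, grid = grid, seed = seed),
    class = "ground_truth")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a trial table from a ground-truth site
#'
#' The Poisson stage of the LN-P model: per trial, the onset-window count
#' is drawn as Poisson((r(S) + background) * onset duration) and the
#' baseline-window count as Poisson(background * baseline duration),
#' independently across trials and stimuli. Spike-count variance therefore
#' equals the mean count (Fano factor 1), the "Poisson-like" variability
#' regime of cortical multi-unit responses.
#'
#' @param gt A `ground_truth`.
#' @param n_repeats Repeats per stimulus (default 15).
#' @param onset_win,baseline_win Count windows in ms.
#' @return A `trial_table`.
#' @export
simulate_trials <- function(gt, n_repeats = 15,
                            onset_win = c(20, 100),
                            baseline_win = c(400, 480)) {
  stopifnot(inherits(gt, "ground_truth"))
  if (n_repeats < 1) stop("n_repeats must be >= 1")
  p <- gt$grid$pairs
  n_stim <- nrow(p)
  onset_dur <- window_dur_s(onset_win)
  base_dur <- window_dur_s(baseline_win)
  lam_on <- rep((gt$rates + gt$background_rate) * onset_dur, each = n_repeats)
  onset <- stats::rpois(n_stim * n_repeats, lam_on)
  baseline <- stats::rpois(n_stim * n_repeats,
                           gt$background_rate * base_dur)
  counts <- data.frame(
    stim_id = rep(p$stim_id, each = n_repeats),
    repeat_idx = rep(seq_len(n_repeats), times = n_stim),
    onset_count = onset,
    baseline_count = baseline)
  trial_table(counts, p, onset_win = onset_win, baseline_win = baseline_win)
}

#' Default extracellular spike waveform template
#'
#' A negative-dominant biphasic shape: sharp negative trough followed by a
#' smaller positive rebound, about 1.2 ms long. Peak (trough) amplitude is
#' normalized to -1.
#'
#' @param fs Sampling rate in Hz.
#' @return Numeric vector of template samples.
#' @export
spike_template <- function(fs = 24000) {
  t <- seq(0, 0.0012, by = 1 / fs)
  w <- -exp(-((t - 0.0003) / 0.00012)^2) +
       0.35 * exp(-((t - 0.0007) / 0.00025)^2)
  w / max(abs(w))
}

#' Simulate a raw extracellular voltage trace
#'
#' Band-limited Gaussian noise plus a biphasic spike template at each
#' spike time. Spike amplitude is expressed in units of the noise SD, so a
#' trace with `amplitude_sd = 8` carries spikes eight noise-SDs deep —
#' easily detected — while `amplitude_sd = 1` buries them. Overlapping
#' templates superpose.
#'
#' @param train A `spike_train` (times in seconds).
#' @param duration Trace duration in seconds (default 0.5).
#' @param fs Sampling rate in Hz (default 24000).
#' @param amplitude_sd Spike trough amplitude in noise-SD units
#'   (default 8).
#' @param noise_sd Noise standard deviation in trace units (default 1).
#' @param noise_band Band limits of the noise in Hz (default 100--6000).
#' @param template Spike waveform (default [spike_template()]).
#' @return A `voltage_trace`.
#' @export
simulate_trace <- function(train, duration = 0.5, fs = 24000,
                           amplitude_sd = 8, noise_sd = 1,
                           noise_band = c(100, 6000),
                           template = spike_template(fs)) {
  stopifnot(inherits(train, "spike_train"))
  n <- round(duration * fs)
  noise <- stats::rnorm(n)
  bf <- signal::butter(2, noise_band / (fs / 2), type = "pass")
  noise <- signal::filtfilt(bf, noise)
  noise <- noise * (noise_sd / stats::sd(noise))
  x <- noise
  tpl <- template * amplitude_sd * noise_sd
  for (tt in train$times) {
    i0 <- round(tt * fs) + 1L
    idx <- i0:(i0 + length(tpl) - 1L)
    ok <- idx >= 1L & idx <= n
    x[idx[ok]] <- x[idx[ok]] + tpl[ok]
  }
  voltage_trace(x, fs = fs, t0 = 0)
}
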