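#' Synthesize a click train
#'
#' Generates a periodic train of unit-amplitude positive impulses, the
#' glottal-pulse analog that drives the formant resonators. Impulses are
#' placed at sample indices `round(k * fs / f0)`, k = 0, 1, ..., starting at
#' sample 0, so the period is rounded to the nearest sample.
#'
#' @param f0 Fundamental frequency in Hz (default 151).
#' @param duration Duration in seconds (default 0.2).
#' @param fs Sampling rate in Hz (default 97656).
#' @return An object of class `stimulus_waveform`: list with `samples`,
#'   `fs`, `f0`, `duration`, and (once filtered) `f1`, `f2`.
#' @export
synth_click_train <- function(f0 = 151, duration = 0.2, fs = 97656) {
  if (f0 <= 0) stop("f0 must be positive")
  if (duration <= 0) stop("duration must be positive")
  if (f0 >= fs / 2) stop("f0 must be below the Nyquist frequency fs/2")
  n <- round(duration * fs)
  samples <- numeric(n)
  k <- 0:floor(duration * f0)
  pos <- round(k * fs / f0) + 1L
  pos <- pos[pos <= n]
  samples[pos] <- 1
  structure(
    list(samples = samples, fs = fs, f0 = f0, f1 = NA_real_, f2 = NA_real_,
         duration = duration),
    class = "stimulus_waveform")
}

# Single second-order resonator, unity gain at the center frequency.
# Pole radius r = exp(-pi * bw / fs); optional matched zeros at z = +/- r.
resonate <- function(x, f, bw, fs, zeros = FALSE) {
  r <- exp(-pi * bw / fs)
  theta <- 2 * pi * f / fs
  a <- c(1, -2 * r * cos(theta), r^2)
  b <- if (zeros) c(1, 0, -r^2) else 1
  # unity gain at the resonance frequency
  z <- exp(1i * theta)
  h <- sum(b * z^-(seq_along(b) - 1)) / sum(a * z^-(0:2))
  b <- b / Mod(h)
  as.numeric(signal::filter(signal::Arma(b = b, a = a), x))
}

#' Apply a two-formant resonator cascade
#'
#' Passes a waveform through two second-order resonators in series, centered
#' at `f1` and `f2`. This shapes the flat harmonic spectrum of a click train
#' into a two-formant pulse-resonance sound: the harmonics of `f0` nearest
#' the resonance frequencies carry the most energy.
#'
#' The resonators are all-pole by default, with pole radius
#' `exp(-pi * bw / fs)`; set `zeros = TRUE` for a matched pole-zero
#' realization (zeros at +/- the pole radius).
#'
#' @param wave A `stimulus_waveform`.
#' @param f1,f2 Formant center frequencies in Hz, `0 < f1 <= f2 < fs/2`.
#' @param bw Resonator 3 dB bandwidth in Hz (default 200).
#' @param zeros Logical; use a matched pole-zero resonator instead of the
#'   pure-pole form.
#' @return The filtered `stimulus_waveform` with `f1`, `f2` recorded.
#' @export
apply_formant_cascade <- function(wave, f1, f2, bw = 200, zeros = FALSE) {
  stopifnot(inherits(wave, "stimulus_waveform"))
  fs <- wave$fs
  if (!(f1 > 0 && f2 >= f1 && f2 < fs / 2)) {
    stop("require 0 < f1 <= f2 < fs/2")
  }
  if (bw <= 0 || bw >= fs / 2) {
    stop("resonator bandwidth must lie in (0, fs/2) for a stable filter")
  }
  y <- resonate(wave$samples, f1, bw, fs, zeros = zeros)
  y <- resonate(y, f2, bw, fs, zeros = zeros)
  wave$samples <- y
  wave$f1 <- f1
  wave$f2 <- f2
  wave
}

#' Apply onset/offset ramps and calibrate RMS level
#'
#' Applies raised-cosine (cos^2 flank) amplitude ramps to the first and last
#' `ramp_ms` milliseconds, then rescales the whole waveform so its RMS
#' equals `rms_target`. Scaling is computed after ramping, so all stimuli in
#' a bank reach identical RMS regardless of their formant placement — the
#' software stand-in for presenting every stimulus at the same sound level.
#'
#' @param wave A `stimulus_waveform`.
#' @param ramp_ms Ramp duration in milliseconds (default 5).
#' @param rms_target Target linear RMS (default 0.05).
#' @return The ramped, calibrated `stimulus_waveform`.
#' @export
finalize_stimulus <- function(wave, ramp_ms = 5, rms_target = 0.05) {
  stopifnot(inherits(wave, "stimulus_waveform"))
  n <- length(wave$samples)
  n_ramp <- round(ramp_ms / 1000 * wave$fs)
  if (2 * n_ramp >= n) stop("ramps longer than the stimulus")
  x <- wave$samples
  if (n_ramp > 0) {
    # cos^2 flank rising from exactly 0 at the first sample
    ramp <- sin(pi / 2 * (seq_len(n_ramp) - 1) / n_ramp)^2
    x[seq_len(n_ramp)] <- x[seq_len(n_ramp)] * ramp
    x[n:(n - n_ramp + 1)] <- x[n:(n - n_ramp + 1)] * ramp
  }
  rms <- sqrt(mean(x^2))
  if (rms == 0) stop("cannot calibrate an all-zero waveform")
  wave$samples <- x * (rms_target / rms)
  wave$rms_target <- rms_target
  wave
}

#' Synthesize one two-formant pulse-resonance stimulus
#'
#' Convenience wrapper: click train -> formant cascade -> ramps + RMS
#' calibration.
#'
#' @inheritParams synth_click_train
#' @inheritParams apply_formant_cascade
#' @inheritParams finalize_stimulus
#' @return A calibrated `stimulus_waveform`.
#' @export
synth_stimulus <- function(f1, f2, f0 = 151, duration = 0.2, fs = 97656,
                           bw = 200, ramp_ms = 5, rms_target = 0.05,
                           zeros = FALSE) {
  w <- synth_click_train(f0 = f0, duration = duration, fs = fs)
  w <- apply_formant_cascade(w, f1, f2, bw = bw, zeros = zeros)
  finalize_stimulus(w, ramp_ms = ramp_ms, rms_target = rms_target)
}

#' Write a stimulus bank to disk
#'
#' Synthesizes every (F1, F2) pair of a formant grid, writes one WAV file
#' per stimulus, and returns (and writes) a CSV manifest describing the
#' bank. The manifest is the hand-off format between stimulus presentation
#' and analysis: trial tables refer to stimuli by its `stim_id`.
#'
#' @param grid A `formant_grid`.
#' @param out_dir Output directory (created if missing).
#' @param f0,duration,fs,bw,ramp_ms,rms_target Synthesis parameters, see
#'   [synth_stimulus()].
#' @param bits WAV sample format: 16 (PCM) or 32 (IEEE float).
#' @param write_wav Logical; set `FALSE` to write the manifest only.
#' @return Invisibly, the manifest data.frame with columns
#'   `stim_id, f1_hz, f2_hz, f1_oct, f2_oct, file`.
#' @export
write_bank <- function(grid, out_dir, f0 = 151, duration = 0.2, fs = 97656,
                       bw = 200, ramp_ms = 5, rms_target = 0.05, bits = 16,
                       write_wav = TRUE) {
  stopifnot(inherits(grid, "formant_grid"))
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop(sprintf("cannot create output directory '%s'", out_dir))
  }
  p <- grid$pairs
  files <- sprintf("stim_%03d_f1_%d_f2_%d.wav", p$stim_id,
                   round(p$f1_hz), round(p$f2_hz))
  if (write_wav && nrow(p) > 0) {
    for (i in seq_len(nrow(p))) {
      w <- synth_stimulus(p$f1_hz[i], p$f2_hz[i], f0 = f0,
                          duration = duration, fs = fs, bw = bw,
                          ramp_ms = ramp_ms, rms_target = rms_target)
      write_wav(w$samples, fs, file.path(out_dir, files[i]), bits = bits)
    }
  }
  manifest <- data.frame(
    stim_id = p$stim_id, f1_hz = p$f1_hz, f2_hz = p$f2_hz,
    f1_oct = p$f1_oct, f2_oct = p$f2_oct,
    file = if (nrow(p) > 0) files else character(0))
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}

#' Read a stimulus manifest CSV
#'
#' @param path Path to a manifest written by [write_bank()] (columns
#'   `stim_id, f1_hz, f2_hz, f1_oct, f2_oct[, file]`).
#' @return The manifest data.frame.
#' @export
read_manifest <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("stim_id", "f1_hz", "f2_hz", "f1_oct", "f2_oct")
  miss <- setdiff(need, names(m))
  if (length(miss) > 0) {
    stop(sprintf("manifest '%s' missing columns: %s", path,
                 paste(miss, collapse = ", ")))
  }
  m
}
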