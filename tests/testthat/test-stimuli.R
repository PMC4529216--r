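test_that("click train places impulses at the rounded period", {
  w <- synth_click_train(151, 0.2, 97656)
  expect_equal(length(w$samples), round(0.2 * 97656))
  expect_equal(sum(w$samples != 0), floor(0.2 * 151) + 1)   # 31 clicks
  expect_true(all(w$samples %in% c(0, 1)))
  expect_equal(w$samples[1], 1)                             # starts at sample 0

  w1 <- synth_click_train(1, 0.5, 1000)
  expect_equal(sum(w1$samples != 0), 1)
  expect_equal(which(w1$samples != 0), 1L)
})

test_that("click train spectrum has lines at multiples of f0", {
  fs <- 97656
  w <- synth_click_train(151, 0.2, fs)
  n <- length(w$samples)
  mag <- Mod(stats::fft(w$samples))[seq_len(floor(n / 2))]
  freqs <- (seq_along(mag) - 1) * fs / n
  # spectral lines in the formant band (the sample-rounded period smears
  # lines only near Nyquist) sit within one FFT bin of k*151
  sel <- freqs < 25000
  peaks <- freqs[sel][mag[sel] > max(mag) / 2]
  expect_gt(length(peaks), 100)
  nearest_harm <- round(peaks / 151) * 151
  expect_true(all(abs(peaks - nearest_harm) <= 2 * fs / n))
  expect_error(synth_click_train(0, 0.2, 97656), "positive")
  expect_error(synth_click_train(60000, 0.2, 97656), "Nyquist")
})

test_that("formant cascade concentrates energy at the formant harmonics", {
  w <- synth_click_train(151, 0.2, 97656)
  y <- apply_formant_cascade(w, 10717, 13200, bw = 200)
  pk <- fft_peak_hz(y$samples, y$fs)
  # strongest harmonic within 0.05 octave of one of the two formants
  expect_true(min(abs(log2(pk / 10717)), abs(log2(pk / 13200))) < 0.05)

  # coincident formants: single prominence near 15 kHz
  y2 <- apply_formant_cascade(w, 15000, 15000, bw = 200)
  pk2 <- fft_peak_hz(y2$samples, y2$fs)
  expect_lt(abs(log2(pk2 / 15000)), 0.05)

  expect_error(apply_formant_cascade(w, 13200, 10717), "f1 <= f2")
  expect_error(apply_formant_cascade(w, 10717, 13200, bw = 60000), "stable")
})

test_that("resonator response at center exceeds response one octave away", {
  fs <- 97656
  probe <- function(f, fc) {
    t <- seq(0, 0.2, by = 1 / fs)
    x <- structure(list(samples = sin(2 * pi * f * t), fs = fs, f0 = f,
                        duration = 0.2), class = "stimulus_waveform")
    y <- apply_formant_cascade(x, fc, fc, bw = 200)
    sqrt(mean(y$samples[-(1:2000)]^2))   # skip transient
  }
  expect_gt(probe(14000, 14000), probe(7000, 14000))
  expect_gt(probe(14000, 14000), probe(28000, 14000))
})

test_that("ramps rise from zero and calibration hits the target RMS", {
  fs <- 97656
  const <- structure(list(samples = rep(1, round(0.2 * fs)), fs = fs,
                          f0 = NA, duration = 0.2),
                     class = "stimulus_waveform")
  out <- finalize_stimulus(const, ramp_ms = 5, rms_target = 0.05)
  n_ramp <- round(0.005 * fs)
  n <- length(out$samples)
  expect_equal(out$samples[1], 0)
  expect_equal(out$samples[n], 0)
  # the unramped plateau stays constant: ramping touches only the flanks
  plateau <- out$samples[(n_ramp + 1):(n - n_ramp)]
  expect_equal(max(plateau), min(plateau))
  expect_true(all(diff(out$samples[1:n_ramp]) >= 0))   # monotone onset
  expect_lt(abs(sqrt(mean(out$samples^2)) - 0.05) / 0.05, 1e-3)
  expect_error(finalize_stimulus(
    structure(list(samples = numeric(100), fs = 1000, duration = 0.1),
              class = "stimulus_waveform"), ramp_ms = 5), "all-zero")
})

test_that("all calibrated stimuli share the same RMS", {
  g <- make_formant_grid()
  idx <- c(1, 20, 55)
  rms <- vapply(idx, function(i) {
    w <- synth_stimulus(g$pairs$f1_hz[i], g$pairs$f2_hz[i])
    sqrt(mean(w$samples^2))
  }, numeric(1))
  expect_true(all(abs(rms - 0.05) / 0.05 < 1e-3))
})

test_that("stimulus bank manifest covers all 55 pairs and WAVs round-trip", {
  out_dir <- withr::local_tempdir()
  g <- make_formant_grid()
  # keep the bank write fast: manifest for all pairs, audio for a subset
  manifest <- write_bank(g, out_dir, write_wav = FALSE)
  expect_equal(nrow(manifest), 55)
  expect_named(manifest, c("stim_id", "f1_hz", "f2_hz", "f1_oct", "f2_oct",
                           "file"))
  m2 <- read_manifest(file.path(out_dir, "manifest.csv"))
  expect_equal(m2$f1_hz, manifest$f1_hz, tolerance = 1e-9)

  w <- synth_stimulus(10000, 13200, duration = 0.05)
  write_wav(w$samples, w$fs, file.path(out_dir, "x16.wav"), bits = 16)
  r16 <- read_wav(file.path(out_dir, "x16.wav"))
  expect_equal(r16$fs, w$fs)
  expect_lt(max(abs(r16$samples - w$samples)), 1 / 32767)  # PCM quantization
  write_wav(w$samples, w$fs, file.path(out_dir, "x32.wav"), bits = 32)
  r32 <- read_wav(file.path(out_dir, "x32.wav"))
  expect_lt(max(abs(r32$samples - w$samples)), 1e-7)
})
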