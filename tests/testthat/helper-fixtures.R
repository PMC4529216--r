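# Shared fixtures and independent oracles.

default_grid <- make_formant_grid()

# trial table with identical counts in every trial
constant_table <- function(onset = 4L, baseline = 0L, n_repeats = 3,
                           grid = default_grid) {
  p <- grid$pairs
  counts <- data.frame(
    stim_id = rep(p$stim_id, each = n_repeats),
    repeat_idx = rep(seq_len(n_repeats), times = nrow(p)),
    onset_count = onset, baseline_count = baseline)
  trial_table(counts, p)
}

# random frf_map with an arbitrary validity mask (at least 2 valid cells)
random_masked_frf <- function(grid = default_grid, p_valid = 0.6) {
  n <- length(grid$centers)
  mask <- matrix(stats::runif(n * n) < p_valid, n, n) & upper.tri(matrix(0, n, n))
  if (sum(mask) < 2) mask[1, 2] <- mask[1, 3] <- TRUE
  values <- matrix(NA_real_, n, n)
  values[mask] <- stats::rnorm(sum(mask), sd = 20)
  structure(list(values = values, mask = mask, grid = grid,
                 background = 0), class = "frf_map")
}

# brute-force normalized masked convolution: explicit double loop over
# valid cell pairs, independent of the matrix-based implementation
smooth_frf_oracle <- function(frf, sigma) {
  idx <- which(frf$mask, arr.ind = TRUE)
  oct <- frf$grid$centers_oct
  out <- frf
  for (a in seq_len(nrow(idx))) {
    num <- 0; den <- 0
    for (b in seq_len(nrow(idx))) {
      d2 <- (oct[idx[a, 1]] - oct[idx[b, 1]])^2 +
            (oct[idx[a, 2]] - oct[idx[b, 2]])^2
      w <- exp(-d2 / (2 * sigma^2))
      num <- num + w * frf$values[idx[b, 1], idx[b, 2]]
      den <- den + w
    }
    out$values[idx[a, 1], idx[a, 2]] <- num / den
  }
  out
}

site_seed_for_test <- frfres:::site_seed

# amplitude spectrum peak frequency of a waveform
fft_peak_hz <- function(samples, fs) {
  n <- length(samples)
  mag <- Mod(stats::fft(samples))[seq_len(floor(n / 2))]
  (which.max(mag) - 1) * fs / n
}
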