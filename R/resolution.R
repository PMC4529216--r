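#' Gaussian kernel weight at a given octave distance
#'
#' Relative weight, with respect to the kernel center, that a 2-D Gaussian
#' smoothing kernel of width `sigma` assigns to a point `d` octaves away:
#' `exp(-d^2 / (2 sigma^2))`. Useful for interpreting a fitted sigma: at
#' sigma = 0.08 oct a stimulus 0.1 oct away still contributes ~46% of the
#' center weight, at sigma = 0.02 only ~4 parts per million.
#'
#' @param d Distance in octaves (vectorized, >= 0).
#' @param sigma Kernel standard deviation in octaves (> 0).
#' @return Dimensionless weight in (0, 1].
#' @export
kernel_weight <- function(d, sigma) {
  if (any(sigma <= 0)) stop("sigma must be positive")
  if (any(d < 0)) stop("d must be non-negative")
  exp(-d^2 / (2 * sigma^2))
}

# Row-normalized smoothing matrix over the valid cells of a mask.
# coords: 2-column matrix of (F1, F2) octave coordinates of valid cells.
# Returns W with W[i, j] = w(|x_i - x_j|) / sum_j w: out = W %*% values.
smoothing_matrix <- function(coords, sigma) {
  d2 <- outer(coords[, 1], coords[, 1], "-")^2 +
        outer(coords[, 2], coords[, 2], "-")^2
  w <- exp(-d2 / (2 * sigma^2))
  w / rowSums(w)
}

mask_coords <- function(frf) {
  idx <- which(frf$mask, arr.ind = TRUE)
  oct <- frf$grid$centers_oct
  cbind(oct[idx[, 1]], oct[idx[, 2]])
}

#' Smooth a formant receptive field with a 2-D Gaussian kernel
#'
#' Normalized (masked) convolution: each valid cell is replaced by the
#' kernel-weighted average of all valid cells, with weights renormalized
#' over the valid cells only. Distances are measured in octave
#' coordinates. This is the only masked smoothing that leaves constant
#' fields exactly unchanged and whose large-sigma limit is exactly the
#' grand mean — invalid cells neither leak zeros nor distort the edges of
#' the triangular F1 < F2 domain.
#'
#' @param frf An `frf_map`.
#' @param sigma Kernel standard deviation in octaves (> 0).
#' @return The smoothed `frf_map`.
#' @export
smooth_frf <- function(frf, sigma) {
  stopifnot(inherits(frf, "frf_map"))
  if (length(sigma) != 1 || sigma <= 0) stop("sigma must be a positive scalar")
  if (!any(frf$mask)) stop("FRF has no valid cells")
  W <- smoothing_matrix(mask_coords(frf), sigma)
  out <- frf
  out$values[out$mask] <- as.numeric(W %*% frf$values[frf$mask])
  out
}

#' Mean squared prediction error between two FRF maps
#'
#' Mean over valid cells of the squared difference, in Hz^2. Used to score
#' how well a smoothed training-set FRF predicts a held-out test-set FRF.
#'
#' @param pred,obs `frf_map` objects on identical grids and masks.
#' @return Mean squared difference (Hz^2).
#' @export
prediction_error <- function(pred, obs) {
  stopifnot(inherits(pred, "frf_map"), inherits(obs, "frf_map"))
  if (!identical(dim(pred$mask), dim(obs$mask)) ||
      !identical(pred$mask, obs$mask)) {
    stop("FRF masks do not match")
  }
  mean((pred$values[pred$mask] - obs$values[obs$mask])^2)
}

#' Split a trial table into train and test FRFs
#'
#' For every stimulus independently, repeats are partitioned without
#' replacement into disjoint subsets of `n_train` and `n_test` trials
#' (surplus repeats are left out at random). Each subset is reduced to an
#' FRF with [build_frf()], so train and test each estimate their own
#' background rate from their own trials — the two halves stay
#' statistically independent.
#'
#' @param table A `trial_table`.
#' @param n_train,n_test Repeats per stimulus in each half (defaults 10
#'   and 5).
#' @param grid Optional `formant_grid`.
#' @return List with elements `train` and `test`, both `frf_map`s.
#' @export
cv_split <- function(table, n_train = 10, n_test = 5, grid = NULL) {
  stopifnot(inherits(table, "trial_table"))
  manifest <- attr(table, "manifest")
  if (is.null(grid)) grid <- grid_from_manifest(manifest)
  m <- table_matrices(table)
  check_split_sizes(m, n_train, n_test)
  sp <- split_matrices(m, n_train, n_test)
  list(
    train = frf_from_matrices(sp$train_onset, sp$train_base, table, grid, manifest),
    test = frf_from_matrices(sp$test_onset, sp$test_base, table, grid, manifest)
  )
}

check_split_sizes <- function(m, n_train, n_test) {
  if (n_train < 1 || n_test < 1) stop("n_train and n_test must be >= 1")
  short <- m$n_rep < n_train + n_test
  if (any(short)) {
    stop(sprintf(
      "insufficient repeats for a %d/%d split; stim_id (n): %s",
      n_train, n_test,
      paste(sprintf("%s (%d)", m$stim_ids[short], m$n_rep[short]),
            collapse = ", ")))
  }
}

# one random split of the count matrices; NA-aware for ragged repeat counts
split_matrices <- function(m, n_train, n_test) {
  n_stim <- nrow(m$onset)
  tr_on <- matrix(NA_real_, n_stim, n_train)
  tr_ba <- matrix(NA_real_, n_stim, n_train)
  te_on <- matrix(NA_real_, n_stim, n_test)
  te_ba <- matrix(NA_real_, n_stim, n_test)
  for (s in seq_len(n_stim)) {
    avail <- which(!is.na(m$onset[s, ]))
    pick <- sample(avail, n_train + n_test)
    itr <- pick[seq_len(n_train)]
    ite <- pick[n_train + seq_len(n_test)]
    tr_on[s, ] <- m$onset[s, itr]; tr_ba[s, ] <- m$baseline[s, itr]
    te_on[s, ] <- m$onset[s, ite]; te_ba[s, ] <- m$baseline[s, ite]
  }
  list(train_onset = tr_on, train_base = tr_ba,
       test_onset = te_on, test_base = te_ba)
}

frf_from_matrices <- function(onset, baseline, table, grid, manifest) {
  onset_dur <- window_dur_s(attr(table, "onset_win"))
  base_dur <- window_dur_s(attr(table, "baseline_win"))
  background <- stats::median(baseline) / base_dur
  vals <- rowMeans(onset) / onset_dur - background
  frf_from_values(vals, grid, manifest, background = background)
}

#' Default sigma search grid
#'
#' Nine geometrically spaced kernel widths, 0.02 to 5.12 octaves, each
#' double the previous.
#' @return Numeric vector of sigmas in octaves.
#' @export
default_sigmas <- function() 0.02 * 2^(0:8)

#' Estimate the formant-resolution parameter sigma by cross-validation
#'
#' The core estimator. For each candidate kernel width sigma, the trial
#' table is repeatedly split at random into independent training and test
#' halves ([cv_split()]); the training FRF is smoothed with that sigma and
#' scored against the raw test FRF by mean squared error. Too little
#' smoothing transmits trial noise; too much blurs real tuning structure —
#' the sigma minimizing the cross-validated error is the estimate of the
#' frequency resolution of the site's responses. A natural cubic spline
#' through the per-sigma mean errors (as a function of log2 sigma) is
#' evaluated on a dense grid and its argmin is returned as `best_sigma`,
#' allowing estimates between the sampled widths.
#'
#' @param table A `trial_table`.
#' @param sigmas Candidate kernel widths in octaves (default
#'   [default_sigmas()]).
#' @param n_boot Random splits per sigma (default 500).
#' @param n_train,n_test Split sizes (defaults 10 and 5).
#' @param grid Optional `formant_grid`.
#' @param share_splits Reuse the same `n_boot` splits for every sigma
#'   (variance reduction); by default a fresh split is drawn per
#'   (sigma, iteration).
#' @param n_dense Dense-grid points for the spline argmin (default 1000).
#' @return An object of class `cv_curve`: list with `sigmas`, `mse_mean`,
#'   `mse_sem` (Hz^2), `best_sigma` (octaves), `spline` (data.frame
#'   `sigma`, `mse` of the interpolated curve), `n_boot`, and `flat`
#'   (TRUE when the error curve carries no information, e.g. an all-zero
#'   table; then `best_sigma` is the largest sigma).
#' @export
estimate_resolution <- function(table, sigmas = default_sigmas(),
                                n_boot = 500, n_train = 10, n_test = 5,
                                grid = NULL, share_splits = FALSE,
                                n_dense = 1000) {
  stopifnot(inherits(table, "trial_table"))
  if (n_boot < 2) stop("n_boot must be >= 2")
  if (is.unsorted(sigmas, strictly = TRUE)) stop("sigmas must be increasing")
  manifest <- attr(table, "manifest")
  if (is.null(grid)) grid <- grid_from_manifest(manifest)
  m <- table_matrices(table)
  check_split_sizes(m, n_train, n_test)

  frf0 <- build_frf(table, grid)        # mask/coords only
  coords <- mask_coords(frf0)
  Ws <- lapply(sigmas, function(s) smoothing_matrix(coords, s))

  onset_dur <- window_dur_s(attr(table, "onset_win"))
  base_dur <- window_dur_s(attr(table, "baseline_win"))
  # map manifest order -> mask order so FRF vectors line up with coords
  i1 <- match_center(manifest$f1_hz, grid)
  i2 <- match_center(manifest$f2_hz, grid)
  cell_of_stim <- match((i2 - 1L) * nrow(frf0$mask) + i1, which(frf0$mask))
  to_mask_order <- order(cell_of_stim)

  vals_from_split <- function(on, ba) {
    bg <- stats::median(ba) / base_dur
    v <- rowMeans(on) / onset_dur - bg
    v[to_mask_order]
  }

  err <- matrix(NA_real_, n_boot, length(sigmas))
  for (b in seq_len(n_boot)) {
    if (share_splits) {
      sp <- split_matrices(m, n_train, n_test)
      v_tr <- vals_from_split(sp$train_onset, sp$train_base)
      v_te <- vals_from_split(sp$test_onset, sp$test_base)
      for (k in seq_along(sigmas)) {
        err[b, k] <- mean((as.numeric(Ws[[k]] %*% v_tr) - v_te)^2)
      }
    } else {
      for (k in seq_along(sigmas)) {
        sp <- split_matrices(m, n_train, n_test)
        v_tr <- vals_from_split(sp$train_onset, sp$train_base)
        v_te <- vals_from_split(sp$test_onset, sp$test_base)
        err[b, k] <- mean((as.numeric(Ws[[k]] %*% v_tr) - v_te)^2)
      }
    }
  }

  mse_mean <- colMeans(err)
  mse_sem <- apply(err, 2, stats::sd) / sqrt(n_boot)

  flat <- diff(range(mse_mean)) <= 1e-12 * max(abs(mse_mean), 1e-300)
  lx <- log2(sigmas)
  dense_x <- seq(min(lx), max(lx), length.out = n_dense)
  sf <- stats::splinefun(lx, mse_mean, method = "natural")
  dense_y <- sf(dense_x)
  best_sigma <- if (flat) max(sigmas) else 2^dense_x[which.min(dense_y)]

  structure(
    list(sigmas = sigmas, mse_mean = mse_mean, mse_sem = mse_sem,
         best_sigma = best_sigma,
         spline = data.frame(sigma = 2^dense_x, mse = dense_y),
         n_boot = n_boot, n_train = n_train, n_test = n_test, flat = flat),
    class = "cv_curve")
}

#' @export
print.cv_curve <- function(x, ...) {
  cat(sprintf(
    "CV curve: %d sigmas in [%.3g, %.3g] oct, %d splits each; best sigma = %.4f oct%s\n",
    length(x$sigmas), min(x$sigmas), max(x$sigmas), x$n_boot, x$best_sigma,
    if (x$flat) " (flat error curve)" else ""))
  invisible(x)
}

#' Plot a cross-validation error curve
#'
#' Mean squared prediction error (+/- 1 SEM) against kernel width on a log
#' axis, with the interpolating spline and the selected minimum.
#'
#' @param x A `cv_curve`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.cv_curve <- function(x, ...) {
  graphics::plot(x$sigmas, x$mse_mean, log = "x", pch = 19,
                 xlab = "kernel width sigma (octaves)",
                 ylab = "mean squared prediction error (Hz^2)", ...)
  graphics::arrows(x$sigmas, x$mse_mean - x$mse_sem,
                   x$sigmas, x$mse_mean + x$mse_sem,
                   angle = 90, code = 3, length = 0.03)
  graphics::lines(x$spline$sigma, x$spline$mse, col = "grey40")
  graphics::abline(v = x$best_sigma, lty = 2)
  invisible(x)
}
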