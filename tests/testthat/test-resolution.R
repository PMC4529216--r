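test_that("kernel weights match the closed form at interpretable sigmas", {
  expect_equal(kernel_weight(0.1, 0.08), exp(-0.5 * (0.1 / 0.08)^2))
  expect_equal(kernel_weight(0.1, 0.08), 0.4578, tolerance = 1e-4)
  expect_equal(kernel_weight(0.1, 0.04), 0.0439, tolerance = 1e-3)
  expect_equal(kernel_weight(0.1, 0.02), 3.73e-6, tolerance = 1e-3)
  expect_equal(kernel_weight(0, 0.3), 1)
  expect_error(kernel_weight(0.1, 0), "positive")
  expect_error(kernel_weight(-0.1, 0.1), "non-negative")
})

test_that("smoothing preserves constant fields exactly for every sigma", {
  frf <- build_frf(constant_table(onset = 6L, baseline = 2L))
  for (s in default_sigmas()) {
    sm <- smooth_frf(frf, s)
    expect_equal(frf_values(sm), rep(50, 55), tolerance = 1e-12)
  }
})

test_that("masked smoothing matches the brute-force pairwise oracle", {
  set.seed(42)
  for (i in 1:20) {
    frf <- random_masked_frf()
    sigma <- stats::runif(1, 0.03, 2)
    a <- smooth_frf(frf, sigma)
    b <- smooth_frf_oracle(frf, sigma)
    expect_equal(frf_values(a), frf_values(b), tolerance = 1e-10)
  }
})

test_that("an isolated impulse spreads with the unnormalized kernel ratio", {
  # one cell at 1, all others 0: the unnormalized weighted sum at a cell
  # 0.1 oct away relates to the peak cell by exp(-0.5 (0.1/sigma)^2)
  frf <- build_frf(constant_table(onset = 0L, baseline = 0L))
  frf$values[frf$mask] <- 0
  frf$values[1, 2] <- 1
  sigma <- 0.08
  idx <- which(frf$mask, arr.ind = TRUE)
  oct <- frf$grid$centers_oct
  w_sum <- function(i, j) {
    sum(exp(-((oct[idx[, 1]] - oct[i])^2 + (oct[idx[, 2]] - oct[j])^2) /
            (2 * sigma^2)) * frf$values[idx])
  }
  expect_equal(w_sum(1, 3) / w_sum(1, 2),
               exp(-0.5 * (0.1 / 0.08)^2), tolerance = 1e-12)
  expect_equal(w_sum(1, 3) / w_sum(1, 2), 0.458, tolerance = 1e-3)
})

test_that("smoothing limits: raw map at tiny sigma, grand mean at huge sigma", {
  set.seed(8)
  frf <- random_masked_frf(p_valid = 1)
  tiny <- smooth_frf(frf, 0.02)
  expect_equal(frf_values(tiny), frf_values(frf), tolerance = 1e-4)

  big <- smooth_frf(frf, 5.12)
  # kernel-weighted grand mean: weights nearly equal across the 1-oct grid
  sigma <- 5.12
  idx <- which(frf$mask, arr.ind = TRUE)
  oct <- frf$grid$centers_oct
  v <- frf_values(frf)
  for (k in c(1, 10, 30)) {
    w <- exp(-((oct[idx[, 1]] - oct[idx[k, 1]])^2 +
               (oct[idx[, 2]] - oct[idx[k, 2]])^2) / (2 * sigma^2))
    expect_equal(frf_values(big)[k], sum(w * v) / sum(w), tolerance = 1e-12)
  }
  expect_lt(diff(range(frf_values(big))) / diff(range(v)), 0.01)
})

test_that("prediction error is the mean squared cell difference", {
  set.seed(12)
  a <- random_masked_frf(p_valid = 1)
  expect_equal(prediction_error(a, a), 0)
  b <- a
  b$values[b$mask] <- b$values[b$mask] + 3
  expect_equal(prediction_error(a, b), 9)
  c_ <- a
  c_$values[c_$mask] <- stats::rnorm(sum(c_$mask))
  # independent loop-based oracle
  tot <- 0; nidx <- which(a$mask, arr.ind = TRUE)
  for (k in seq_len(nrow(nidx))) {
    tot <- tot + (a$values[nidx[k, 1], nidx[k, 2]] -
                  c_$values[nidx[k, 1], nidx[k, 2]])^2
  }
  expect_equal(prediction_error(a, c_), tot / nrow(nidx))
  d <- a; d$mask[1, 2] <- FALSE
  expect_error(prediction_error(a, d), "mask")
})

test_that("cv splits are disjoint, exhaustive per stimulus, and seeded", {
  gt <- make_ground_truth("bump", seed = 2)
  set.seed(2)
  tab <- simulate_trials(gt, n_repeats = 15)

  set.seed(5)
  sp <- cv_split(tab, 10, 5)
  expect_s3_class(sp$train, "frf_map")
  expect_equal(sp$train$mask, sp$test$mask)

  set.seed(5)
  sp2 <- cv_split(tab, 10, 5)
  expect_identical(sp$train$values, sp2$train$values)
  expect_identical(sp$test$values, sp2$test$values)

  # leave-one-out variant runs on the same table
  set.seed(6)
  loo <- cv_split(tab, 14, 1)
  expect_s3_class(loo$test, "frf_map")

  expect_error(cv_split(tab, 14, 2), "insufficient repeats")
})

test_that("train/test means reconstruct the full per-stimulus mean", {
  # disjointness check through the counts: for a 10/5 split of 15 repeats,
  # 10 * train_mean + 5 * test_mean must equal the sum over all repeats
  gt <- make_ground_truth("bump", seed = 4)
  set.seed(4)
  tab <- simulate_trials(gt, n_repeats = 15)
  set.seed(9)
  sp <- cv_split(tab, 10, 5)
  p <- attr(tab, "manifest")
  tot <- tapply(tab$onset_count, tab$stim_id, sum)[as.character(p$stim_id)]
  tr <- (sp$train$values[cbind(p$i1, p$i2)] + sp$train$background) * 0.08 * 10
  te <- (sp$test$values[cbind(p$i1, p$i2)] + sp$test$background) * 0.08 * 5
  expect_equal(unname(tr + te), as.numeric(tot), tolerance = 1e-9)
})

test_that("resolution estimation is deterministic given a seed", {
  gt <- make_ground_truth("smoothed_noise", params = list(w = 0.1), seed = 13)
  set.seed(13)
  tab <- simulate_trials(gt)
  set.seed(100)
  cv1 <- estimate_resolution(tab, n_boot = 20)
  set.seed(100)
  cv2 <- estimate_resolution(tab, n_boot = 20)
  expect_identical(cv1$mse_mean, cv2$mse_mean)
  expect_identical(cv1$best_sigma, cv2$best_sigma)
  expect_true(cv1$best_sigma >= min(cv1$sigmas) &&
              cv1$best_sigma <= max(cv1$sigmas))
})

test_that("the interpolated minimum does not exceed any sampled mean", {
  gt <- make_ground_truth("smoothed_noise", params = list(w = 0.2), seed = 17)
  set.seed(17)
  tab <- simulate_trials(gt)
  set.seed(17)
  cv <- estimate_resolution(tab, n_boot = 30)
  expect_lte(min(cv$spline$mse), min(cv$mse_mean) + 1e-12)
  # spline interpolates the sampled points
  at_samples <- cv$spline$mse[vapply(cv$sigmas, function(s)
    which.min(abs(cv$spline$sigma - s)), integer(1))]
  expect_equal(at_samples, cv$mse_mean, tolerance = 1e-3)
})

test_that("bootstrap SEM shrinks like one over root n_boot", {
  gt <- make_ground_truth("smoothed_noise", params = list(w = 0.1), seed = 19)
  set.seed(19)
  tab <- simulate_trials(gt)
  set.seed(19)
  cv_small <- estimate_resolution(tab, n_boot = 50)
  set.seed(19)
  cv_big <- estimate_resolution(tab, n_boot = 200)
  ratio <- median(cv_small$mse_sem / cv_big$mse_sem)
  expect_lt(abs(ratio - 2) / 2, 0.35)
})

test_that("an all-zero table yields the flat fallback at the largest sigma", {
  tab <- constant_table(onset = 0L, baseline = 0L, n_repeats = 15)
  set.seed(1)
  cv <- estimate_resolution(tab, n_boot = 5)
  expect_true(cv$flat)
  expect_equal(cv$best_sigma, max(default_sigmas()))
})

test_that("smooth ground truth drives the best sigma up, sharp drives it down", {
  run_one <- function(w, amp, seed) {
    gt <- make_ground_truth("smoothed_noise", params = list(w = w),
                            amplitude = amp, seed = seed)
    set.seed(seed + 1000)
    tab <- simulate_trials(gt, n_repeats = 15)
    estimate_resolution(tab, n_boot = 40)$best_sigma
  }
  # broad tuning in heavy Poisson noise vs sharp tuning at high SNR
  broad <- vapply(1:5, function(s) run_one(0.4, 10, s), numeric(1))
  fine <- vapply(6:10, function(s) run_one(0.05, 60, s), numeric(1))
  expect_gt(median(broad), 2 * median(fine))
  expect_lt(median(fine), 0.16)      # lower half of the sigma grid
})
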