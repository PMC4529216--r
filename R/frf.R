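#' Count spikes in a half-open time window
#'
#' Counts spike times `t` with `win_start <= t < win_end` (times and window
#' edges in milliseconds after stimulus onset). The half-open convention
#' makes adjacent windows partition time without double counting.
#'
#' @param train A `spike_train` (times in seconds) or numeric vector of
#'   spike times in seconds.
#' @param win_start,win_end Window edges in milliseconds.
#' @return Integer spike count.
#' @export
count_in_window <- function(train, win_start, win_end) {
  if (win_start >= win_end) stop("win_start must be before win_end")
  times <- if (inherits(train, "spike_train")) train$times else as.numeric(train)
  t_ms <- times * 1000
  sum(t_ms >= win_start & t_ms < win_end)
}

#' Build a trial table from spike trains
#'
#' Tabulates, for every (stimulus, repeat), the spike count in the onset
#' window (evoked response) and in the late baseline window (background
#' activity). The trial table is the unit of all downstream resampling.
#'
#' @param trains List of `spike_train` objects, each tagged with a
#'   `stim_id` present in the manifest and a `trial_id` (repeat index
#'   within stimulus).
#' @param manifest Stimulus manifest data.frame (see [read_manifest()]) or
#'   a `formant_grid` (its `pairs` are used).
#' @param onset_win,baseline_win Length-2 numeric windows in ms after
#'   stimulus onset; defaults 20--100 ms and 400--480 ms.
#' @return An object of class `trial_table`: a data.frame with columns
#'   `stim_id, repeat_idx, onset_count, baseline_count` and attributes
#'   `onset_win`, `baseline_win`, `manifest`.
#' @export
build_trial_table <- function(trains, manifest,
                              onset_win = c(20, 100),
                              baseline_win = c(400, 480)) {
  if (inherits(manifest, "formant_grid")) manifest <- manifest$pairs
  stim_ids <- manifest$stim_id
  ids <- vapply(trains, function(tr) as.integer(tr$stim_id), integer(1))
  bad <- setdiff(unique(ids), stim_ids)
  if (length(bad) > 0) {
    stop(sprintf("spike trains reference unknown stim_id(s): %s",
                 paste(bad, collapse = ", ")))
  }
  rep_idx <- vapply(trains, function(tr) as.integer(tr$trial_id), integer(1))
  onset <- vapply(trains, count_in_window, integer(1),
                  win_start = onset_win[1], win_end = onset_win[2])
  baseline <- vapply(trains, count_in_window, integer(1),
                     win_start = baseline_win[1], win_end = baseline_win[2])
  tab <- data.frame(stim_id = ids, repeat_idx = rep_idx,
                    onset_count = onset, baseline_count = baseline)
  tab <- tab[order(tab$stim_id, tab$repeat_idx), ]
  rownames(tab) <- NULL
  trial_table(tab, manifest, onset_win = onset_win,
              baseline_win = baseline_win)
}

#' Construct a trial table from pre-tabulated counts
#'
#' @param counts Data.frame with columns
#'   `stim_id, repeat_idx, onset_count, baseline_count`.
#' @param manifest Stimulus manifest data.frame or `formant_grid`.
#' @param onset_win,baseline_win Count windows in ms (defaults 20--100 and
#'   400--480); their durations convert counts to rates.
#' @return A `trial_table`.
#' @export
trial_table <- function(counts, manifest,
                        onset_win = c(20, 100), baseline_win = c(400, 480)) {
  if (inherits(manifest, "formant_grid")) manifest <- manifest$pairs
  need <- c("stim_id", "repeat_idx", "onset_count", "baseline_count")
  miss <- setdiff(need, names(counts))
  if (length(miss) > 0) {
    stop(sprintf("trial table missing columns: %s", paste(miss, collapse = ", ")))
  }
  if (any(counts$onset_count < 0) || any(counts$baseline_count < 0)) {
    stop("spike counts must be non-negative")
  }
  bad <- setdiff(unique(counts$stim_id), manifest$stim_id)
  if (length(bad) > 0) {
    stop(sprintf("counts reference unknown stim_id(s): %s",
                 paste(bad, collapse = ", ")))
  }
  structure(as.data.frame(counts),
            onset_win = onset_win, baseline_win = baseline_win,
            manifest = manifest,
            class = c("trial_table", "data.frame"))
}

window_dur_s <- function(win) diff(win) / 1000

# counts -> list of matrices [n_stim x max_repeats], NA for missing repeats,
# rows ordered by manifest stim_id. Backbone of the fast CV path.
table_matrices <- function(table) {
  manifest <- attr(table, "manifest")
  stim_ids <- manifest$stim_id
  n_stim <- length(stim_ids)
  reps <- table(factor(table$stim_id, levels = stim_ids))
  max_rep <- max(as.integer(reps))
  onset <- matrix(NA_real_, n_stim, max_rep)
  baseline <- matrix(NA_real_, n_stim, max_rep)
  row <- match(table$stim_id, stim_ids)
  # column position = running repeat index within stimulus
  ord <- order(row, table$repeat_idx)
  col <- stats::ave(seq_along(row)[ord], row[ord], FUN = seq_along)
  onset[cbind(row[ord], col)] <- table$onset_count[ord]
  baseline[cbind(row[ord], col)] <- table$baseline_count[ord]
  list(onset = onset, baseline = baseline, stim_ids = stim_ids,
       n_rep = as.integer(reps))
}

#' Build a formant receptive field from a trial table
#'
#' The FRF value for stimulus S is the mean (over repeats) onset firing
#' rate minus the background rate, where the background is the median
#' baseline-window rate over all (stimulus, repeat) trials. Rates are in
#' Hz (count divided by window duration). Values can be negative: a site
#' may fire below its background during the onset window.
#'
#' @param table A `trial_table`.
#' @param grid A `formant_grid` (defaults to the grid implied by the
#'   table's manifest).
#' @return An object of class `frf_map`: list with `values` (n x n matrix,
#'   `[i1, i2]` indexed by F1 and F2 grid position, NA where invalid),
#'   `mask` (logical matrix, TRUE iff F1 < F2 cell), `grid`, and
#'   `background` (Hz).
#' @export
build_frf <- function(table, grid = NULL) {
  stopifnot(inherits(table, "trial_table"))
  manifest <- attr(table, "manifest")
  if (is.null(grid)) grid <- grid_from_manifest(manifest)
  m <- table_matrices(table)
  if (any(m$n_rep == 0)) {
    stop(sprintf("stimuli with zero repeats: %s",
                 paste(m$stim_ids[m$n_rep == 0], collapse = ", ")))
  }
  onset_dur <- window_dur_s(attr(table, "onset_win"))
  base_dur <- window_dur_s(attr(table, "baseline_win"))
  background <- stats::median(m$baseline[!is.na(m$baseline)]) / base_dur
  mean_onset <- rowMeans(m$onset / onset_dur, na.rm = TRUE)
  vals <- mean_onset - background
  frf_from_values(vals, grid, manifest, background = background)
}

# manifest rows -> frf_map given a vector of per-stimulus values
frf_from_values <- function(vals, grid, manifest, background = NA_real_) {
  n <- length(grid$centers)
  values <- matrix(NA_real_, n, n)
  mask <- matrix(FALSE, n, n)
  i1 <- match_center(manifest$f1_hz, grid)
  i2 <- match_center(manifest$f2_hz, grid)
  values[cbind(i1, i2)] <- vals
  mask[cbind(i1, i2)] <- TRUE
  structure(list(values = values, mask = mask, grid = grid,
                 background = background),
            class = "frf_map")
}

match_center <- function(f, grid) {
  i <- vapply(f, function(x) which.min(abs(grid$centers - x)), integer(1))
  if (any(abs(log2(f / grid$centers[i])) > 1e-6)) {
    stop("manifest frequencies do not lie on the formant grid")
  }
  i
}

grid_from_manifest <- function(manifest) {
  f <- sort(unique(c(manifest$f1_hz, manifest$f2_hz)))
  steps <- diff(log2(f))
  step <- stats::median(steps)
  if (any(abs(steps - step) > 1e-6)) {
    stop("manifest frequencies are not evenly log-spaced; supply a grid")
  }
  make_formant_grid(f_min = min(f), f_max = max(f), step_oct = step)
}

#' Vector of valid-cell FRF values
#'
#' @param frf An `frf_map`.
#' @return Numeric vector of values at valid (F1 < F2) cells, in
#'   column-major mask order.
#' @export
frf_values <- function(frf) frf$values[frf$mask]

#' @export
print.frf_map <- function(x, ...) {
  v <- frf_values(x)
  cat(sprintf(
    "FRF map: %d valid cells on a %dx%d grid; range [%.2f, %.2f] Hz; background %.2f Hz\n",
    sum(x$mask), nrow(x$values), ncol(x$values), min(v), max(v), x$background))
  invisible(x)
}

#' Heatmap of a formant receptive field
#'
#' @param x An `frf_map`.
#' @param main Plot title.
#' @param ... Passed to [graphics::image()].
#' @export
plot.frf_map <- function(x, main = "Formant receptive field", ...) {
  graphics::image(x$grid$centers_oct, x$grid$centers_oct, x$values,
                  xlab = "F1 (octaves re f_min)", ylab = "F2 (octaves re f_min)",
                  main = main, ...)
  invisible(x)
}

#' Write an FRF map as a CSV matrix
#'
#' Writes the value matrix with F1 centers as column `f_hz` and F2 centers
#' as remaining column names; invalid cells are empty.
#'
#' @param frf An `frf_map`.
#' @param path Output CSV path.
#' @export
write_frf_csv <- function(frf, path) {
  df <- as.data.frame(frf$values)
  names(df) <- sprintf("f2_%d", round(frf$grid$centers))
  df <- cbind(f1_hz = round(frf$grid$centers), df)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}
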