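#' Construct a logarithmically spaced formant grid
#'
#' Builds the set of formant center frequencies spaced at a fixed octave
#' interval between `f_min` and `f_max`, together with all ordered
#' two-formant combinations (F1 < F2). With the defaults (10--20 kHz,
#' 0.1 octave steps) this yields 11 centers and choose(11, 2) = 55 pairs,
#' the stimulus set used throughout the package.
#'
#' Octave coordinates are measured relative to `f_min`: a frequency `f`
#' sits at `log2(f / f_min)` octaves, so the default grid spans [0, 1].
#'
#' @param f_min Lowest center frequency in Hz (default 10000).
#' @param f_max Highest center frequency in Hz (default 20000). The span
#'   `log2(f_max / f_min)` must be an integer multiple of `step_oct`.
#' @param step_oct Grid spacing in octaves (default 0.1).
#' @return An object of class `formant_grid`: a list with elements
#'   `centers` (Hz), `centers_oct` (octaves re `f_min`), `pairs` (data.frame
#'   with columns `stim_id`, `f1_hz`, `f2_hz`, `f1_oct`, `f2_oct`,
#'   `i1`, `i2` where `i1 < i2` index into `centers`), and the construction
#'   parameters.
#' @examples
#' g <- make_formant_grid()
#' length(g$centers)   # 11
#' nrow(g$pairs)       # 55
#' @export
make_formant_grid <- function(f_min = 10000, f_max = 20000, step_oct = 0.1) {
  stopifnot(is.numeric(f_min), is.numeric(f_max), is.numeric(step_oct),
            length(f_min) == 1L, length(f_max) == 1L, length(step_oct) == 1L)
  if (f_min <= 0) stop("f_min must be positive")
  if (f_max <= f_min) stop("f_max must exceed f_min")
  if (step_oct <= 0) stop("step_oct must be positive")
  span <- log2(f_max / f_min)
  n_steps <- span / step_oct
  if (abs(n_steps - round(n_steps)) > 1e-9) {
    stop(sprintf(
      "grid span %.6f octaves is not an integer multiple of step_oct = %g",
      span, step_oct))
  }
  n_steps <- round(n_steps)
  k <- 0:n_steps
  centers_oct <- k * step_oct
  centers <- f_min * 2^centers_oct
  # force the endpoint exact: f_max = f_min * 2^span by construction
  centers[n_steps + 1L] <- f_max

  idx <- which(upper.tri(matrix(0, n_steps + 1L, n_steps + 1L)), arr.ind = TRUE)
  # order pairs by (i1, i2) so stim_id enumeration is stable
  idx <- idx[order(idx[, "row"], idx[, "col"]), , drop = FALSE]
  i1 <- idx[, "row"]
  i2 <- idx[, "col"]
  pairs <- data.frame(
    stim_id = seq_along(i1),
    f1_hz = centers[i1],
    f2_hz = centers[i2],
    f1_oct = centers_oct[i1],
    f2_oct = centers_oct[i2],
    i1 = i1,
    i2 = i2
  )
  structure(
    list(f_min = f_min, f_max = f_max, step_oct = step_oct,
         centers = centers, centers_oct = centers_oct, pairs = pairs),
    class = "formant_grid")
}

#' Octave coordinate of a frequency on a grid
#'
#' @param grid A `formant_grid`.
#' @param f Frequency in Hz (vectorized).
#' @return Octaves relative to the grid's lowest center, `log2(f / f_min)`.
#' @export
oct_coord <- function(grid, f) {
  stopifnot(inherits(grid, "formant_grid"))
  log2(f / grid$f_min)
}

#' @export
print.formant_grid <- function(x, ...) {
  cat(sprintf(
    "Formant grid: %d centers, %.0f-%.0f Hz, %g oct spacing, %d F1<F2 pairs\n",
    length(x$centers), x$f_min, x$f_max, x$step_oct, nrow(x$pairs)))
  invisible(x)
}
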