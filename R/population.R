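#' Summarize per-site resolution estimates
#'
#' @param results Data.frame with at least `best_sigma` and, if present,
#'   `included` (only included sites are summarized when the column
#'   exists).
#' @param range_oct Resolution band of interest in octaves (default
#'   c(0.05, 0.2)); the summary reports the fraction of sites inside it.
#' @param breaks Number of log-spaced histogram bins (default 20) over
#'   `hist_range`.
#' @param hist_range Histogram support in octaves (default c(0.02, 5.12)).
#' @return List with `n_total`, `n_included`, `median_sigma`,
#'   `frac_in_range`, `range_oct`, and `histogram` (data.frame with bin
#'   edges and counts).
#' @export
summarize_sites <- function(results, range_oct = c(0.05, 0.2),
                            breaks = 20, hist_range = c(0.02, 5.12)) {
  if (nrow(results) == 0) stop("no sites to summarize")
  n_total <- nrow(results)
  if ("included" %in% names(results)) {
    results <- results[results$included, , drop = FALSE]
  }
  if (nrow(results) == 0) stop("no included sites to summarize")
  s <- results$best_sigma
  edges <- 2^seq(log2(hist_range[1]), log2(hist_range[2]),
                 length.out = breaks + 1)
  # clamp into the histogram support so extreme sites are still counted
  s_cl <- pmin(pmax(s, edges[1]), edges[length(edges)])
  h <- graphics::hist(s_cl, breaks = edges, plot = FALSE)
  list(
    n_total = n_total,
    n_included = length(s),
    median_sigma = stats::median(s),
    frac_in_range = mean(s >= range_oct[1] & s <= range_oct[2]),
    range_oct = range_oct,
    histogram = data.frame(lo = edges[-length(edges)], hi = edges[-1],
                           count = h$counts))
}

#' Compare resolution estimates between groups of sites
#'
#' Kruskal-Wallis omnibus test of the per-site `best_sigma` grouped by a
#' column of the results table — typically `penetration_id` (do different
#' cortical columns resolve formants differently?) or `depth_um` (is
#' resolution laminar?).
#'
#' @param results Data.frame with `best_sigma` and the grouping column.
#' @param group_by Name of the grouping column (default
#'   "penetration_id").
#' @param depth_step Optional; when grouping by depth, keep only sites
#'   whose depth is a multiple of this spacing in micrometers (subsample
#'   densely sampled penetrations to a common grid).
#' @return List with `p_value`, `statistic`, `df`, `n_groups`.
#' @export
compare_groups <- function(results, group_by = "penetration_id",
                           depth_step = NULL) {
  if (!group_by %in% names(results)) {
    stop(sprintf("no column '%s' in results", group_by))
  }
  if (!is.null(depth_step)) {
    if (!"depth_um" %in% names(results)) stop("no depth_um column")
    keep <- results$depth_um %% depth_step == 0
    results <- results[keep, , drop = FALSE]
  }
  g <- factor(results[[group_by]])
  sizes <- base::table(g)
  if (nlevels(g) < 2 || any(sizes < 2)) {
    stop("need >= 2 groups with >= 2 sites each")
  }
  x <- results$best_sigma
  if (length(unique(x)) == 1L) {
    return(list(p_value = 1, statistic = 0, df = nlevels(g) - 1L,
                n_groups = nlevels(g)))
  }
  kw <- stats::kruskal.test(x, g)
  list(p_value = kw$p.value, statistic = unname(kw$statistic),
       df = unname(kw$parameter), n_groups = nlevels(g))
}

#' Convert an octave interval to a percent frequency shift
#'
#' An interval of `delta_oct` octaves multiplies frequency by
#' `2^delta_oct`; the corresponding shift is `100 * (2^delta_oct - 1)`
#' percent. A resolution of ~0.11 octaves, for example, corresponds to a
#' formant shift of about 8%.
#'
#' @param delta_oct Interval in octaves (vectorized).
#' @return Percent frequency shift.
#' @export
octaves_to_percent <- function(delta_oct) 100 * (2^delta_oct - 1)

#' Convert an octave bandwidth to Hz at a center frequency
#'
#' @param delta_oct Bandwidth in octaves.
#' @param f_center Center frequency in Hz.
#' @return Bandwidth in Hz, `f_center * (2^delta_oct - 1)`.
#' @export
octaves_to_hz <- function(delta_oct, f_center) f_center * (2^delta_oct - 1)
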