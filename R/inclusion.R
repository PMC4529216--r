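#' Assign a stimulus to a formant-space quadrant
#'
#' Partitions the triangular F1 < F2 stimulus space into four roughly
#' equal-sized regions by precedence: quadrant 1 if F2 < `f_split`
#' ("bottom left" of the space with F1 on the x-axis); else quadrant 2 if
#' F1 > `f_split` ("top right"); else quadrant 3 if F1 + F2 > `sum_split`
#' ("top left"); else quadrant 4 (central). The inequalities are strict;
#' boundary stimuli fall through to later quadrants.
#'
#' The default thresholds sit on the middle center frequency of the
#' standard grid, 10 * 2^0.4 ~ 13.195 kHz (13.2 kHz in round numbers), so
#' that — the inequalities being strict — stimuli with a formant exactly
#' at that grid position fall through to the later quadrants.
#'
#' @param f1,f2 Formant frequencies in Hz (vectorized), `f1 < f2`.
#' @param f_split Frequency threshold in Hz (default 10000 * 2^0.4).
#' @param sum_split Threshold on F1 + F2 in Hz (default 2 * f_split).
#' @return Integer vector of quadrant ids in 1:4.
#' @export
assign_quadrant <- function(f1, f2, f_split = 10000 * 2^0.4,
                            sum_split = 2 * f_split) {
  if (any(f1 >= f2)) stop("require f1 < f2")
  q <- ifelse(f2 < f_split, 1L,
       ifelse(f1 > f_split, 2L,
       ifelse(f1 + f2 > sum_split, 3L, 4L)))
  as.integer(q)
}

#' Kruskal-Wallis inclusion test for stimulus-driven responses
#'
#' Decides whether a recording site's firing is significantly modulated by
#' the stimuli. Onset-window spike counts are pooled by formant-space
#' quadrant (four groups) and compared — together with the baseline-window
#' counts from all trials as a fifth group — by a Kruskal-Wallis test. A
#' site is included when the omnibus p-value falls below `alpha`: its
#' median count differs between some quadrants or between stimulation and
#' baseline.
#'
#' @param table A `trial_table`.
#' @param alpha Significance level (default 0.05).
#' @param f_split,sum_split Quadrant thresholds, see [assign_quadrant()].
#' @return List with `p_value`, `include` (logical), `statistic`
#'   (Kruskal-Wallis chi-squared), and `group_sizes`.
#' @export
inclusion_test <- function(table, alpha = 0.05,
                           f_split = 10000 * 2^0.4,
                           sum_split = 2 * f_split) {
  stopifnot(inherits(table, "trial_table"))
  manifest <- attr(table, "manifest")
  quad <- assign_quadrant(manifest$f1_hz, manifest$f2_hz,
                          f_split = f_split, sum_split = sum_split)
  quad_of_trial <- quad[match(table$stim_id, manifest$stim_id)]
  x <- c(table$onset_count, table$baseline_count)
  g <- factor(c(quad_of_trial, rep(5L, nrow(table))), levels = 1:5)
  sizes <- as.integer(base::table(g))
  if (any(sizes[unique(as.integer(g))] < 2)) {
    stop("need >= 2 trials per group")
  }
  if (length(unique(x)) == 1L) {
    # no variation at all: cannot reject, by convention p = 1
    return(list(p_value = 1, include = FALSE, statistic = 0,
                group_sizes = sizes))
  }
  kw <- stats::kruskal.test(x, g)
  list(p_value = kw$p.value, include = kw$p.value < alpha,
       statistic = unname(kw$statistic), group_sizes = sizes)
}
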