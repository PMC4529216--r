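#' Default run configuration
#'
#' Collects every tunable parameter of the pipeline with its standard
#' value: 151 Hz fundamental, 10--20 kHz grid at 0.1 octave spacing,
#' 20--100 ms onset and 400--480 ms baseline windows, 200--2000 Hz
#' detection band at -3.5 SD, 10/5 cross-validation splits with 500
#' bootstrap iterations over the nine-sigma search grid.
#'
#' @param ... Named overrides of any default field.
#' @return An object of class `run_config` (a named list).
#' @export
run_config <- function(...) {
  cfg <- list(
    f0 = 151, f_min = 10000, f_max = 20000, step_oct = 0.1,
    fs_stim = 97656, duration = 0.2, ramp_ms = 5, rms_target = 0.05,
    bw = 200,
    onset_win = c(20, 100), baseline_win = c(400, 480),
    band = c(200, 2000), k_sd = 3.5, dead_time_ms = 1,
    sigmas = default_sigmas(), n_train = 10, n_test = 5, n_boot = 500,
    alpha = 0.05, f_split = 10000 * 2^0.4, sum_split = 2 * 10000 * 2^0.4,
    n_repeats = 15, seed = 1)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown) > 0) {
    stop(sprintf("unknown config field(s): %s", paste(unknown, collapse = ", ")))
  }
  cfg[names(over)] <- over
  validate_config(structure(cfg, class = "run_config"))
}

validate_config <- function(cfg) {
  if (cfg$n_test < 1) stop("config: n_test must be >= 1")
  if (cfg$n_train < 1) stop("config: n_train must be >= 1")
  if (cfg$n_train + cfg$n_test > cfg$n_repeats) {
    stop("config: n_train + n_test exceeds n_repeats")
  }
  if (cfg$n_boot < 2) stop("config: n_boot must be >= 2")
  if (cfg$alpha <= 0 || cfg$alpha >= 1) stop("config: alpha must be in (0, 1)")
  if (any(cfg$sigmas <= 0)) stop("config: sigmas must be positive")
  cfg
}

# deterministic per-site seed below 2^31, derived from the run seed
site_seed <- function(seed, site_index) {
  (as.numeric(seed) * 1000003 + site_index * 7919) %% 2147483647 + 1
}

#' Run the full pipeline on a synthetic population
#'
#' Generates `n_sites` LN-Poisson recording sites (cycling through the
#' supplied ground-truth smoothness widths), simulates trials, applies the
#' quadrant inclusion test, estimates per-site resolution by
#' cross-validated kernel smoothing, and aggregates population summaries.
#' Fully reproducible from (`config`, `config$seed`); each site draws
#' from its own deterministic substream so individual sites can be
#' regenerated independently.
#'
#' @param config A `run_config`.
#' @param n_sites Number of synthetic sites (default 20).
#' @param widths Ground-truth smoothness widths in octaves, recycled over
#'   sites (default c(0.05, 0.1, 0.2, 0.4)).
#' @param amplitude,background_rate Passed to [make_ground_truth()].
#' @param sites_per_penetration Sites per simulated electrode penetration
#'   (default 10); depth advances by `depth_step_um` within each.
#' @param depth_step_um Electrode spacing in micrometers (default 100).
#' @param out_dir Optional output directory; when given, writes
#'   `results.csv`, `summary.json`, and `config.json`.
#' @param verbose Print per-stage progress.
#' @return List with `results` (one row per site: `site_id, animal_id,
#'   penetration_id, depth_um, truth_width, p_inclusion, included,
#'   best_sigma, flat`), `summary` (see [summarize_sites()]), and
#'   `config`.
#' @export
run_synthetic <- function(config = run_config(), n_sites = 20,
                          widths = c(0.05, 0.1, 0.2, 0.4),
                          amplitude = 50, background_rate = 12.5,
                          sites_per_penetration = 10, depth_step_um = 100,
                          out_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  grid <- make_formant_grid(config$f_min, config$f_max, config$step_oct)
  rows <- vector("list", n_sites)
  for (i in seq_len(n_sites)) {
    w <- widths[(i - 1L) %% length(widths) + 1L]
    sseed <- site_seed(config$seed, i)
    gt <- make_ground_truth("smoothed_noise", params = list(w = w),
                            grid = grid, amplitude = amplitude,
                            background_rate = background_rate, seed = sseed)
    set.seed(sseed)
    tab <- simulate_trials(gt, n_repeats = config$n_repeats,
                           onset_win = config$onset_win,
                           baseline_win = config$baseline_win)
    inc <- inclusion_test(tab, alpha = config$alpha,
                          f_split = config$f_split,
                          sum_split = config$sum_split)
    cv <- estimate_resolution(tab, sigmas = config$sigmas,
                              n_boot = config$n_boot,
                              n_train = config$n_train,
                              n_test = config$n_test, grid = grid)
    pen <- (i - 1L) %/% sites_per_penetration + 1L
    rows[[i]] <- data.frame(
      site_id = i, animal_id = 1L, penetration_id = pen,
      depth_um = ((i - 1L) %% sites_per_penetration) * depth_step_um,
      truth_width = w, p_inclusion = inc$p_value, included = inc$include,
      best_sigma = cv$best_sigma, flat = cv$flat)
    if (verbose) {
      message(sprintf("site %d/%d: w = %.2f oct -> best sigma %.4f oct (p = %.3g)",
                      i, n_sites, w, cv$best_sigma, inc$p_value))
    }
  }
  results <- do.call(rbind, rows)
  summary <- summarize_sites(results)
  out <- list(results = results, summary = summary, config = config)
  if (!is.null(out_dir)) write_results(out, out_dir)
  out
}

#' Run the pipeline on user-supplied trial data
#'
#' Reads a trial-count CSV and stimulus manifest, then applies the same
#' inclusion and resolution stages as [run_synthetic()]. The trials file
#' needs columns `site_id, stim_id, repeat_idx, onset_count,
#' baseline_count` (a single-site file may omit `site_id`).
#'
#' @param trials_path Path to the trials CSV.
#' @param manifest_path Path to the manifest CSV (see [read_manifest()]).
#' @param config A `run_config`.
#' @param out_dir Optional output directory.
#' @return As [run_synthetic()], minus ground-truth columns.
#' @export
run_real <- function(trials_path, manifest_path, config = run_config(),
                     out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  manifest <- read_manifest(manifest_path)
  trials <- utils::read.csv(trials_path, stringsAsFactors = FALSE)
  if (nrow(trials) == 0) stop(sprintf("trials file '%s' is empty", trials_path))
  need <- c("stim_id", "repeat_idx", "onset_count", "baseline_count")
  miss <- setdiff(need, names(trials))
  if (length(miss) > 0) {
    stop(sprintf("trials file missing columns: %s", paste(miss, collapse = ", ")))
  }
  bad <- setdiff(unique(trials$stim_id), manifest$stim_id)
  if (length(bad) > 0) {
    stop(sprintf("trials reference stim_id(s) absent from manifest: %s",
                 paste(bad, collapse = ", ")))
  }
  if (!"site_id" %in% names(trials)) trials$site_id <- 1L
  grid <- grid_from_manifest(manifest)
  site_ids <- sort(unique(trials$site_id))
  rows <- vector("list", length(site_ids))
  for (i in seq_along(site_ids)) {
    sub <- trials[trials$site_id == site_ids[i],
                  c("stim_id", "repeat_idx", "onset_count", "baseline_count")]
    tab <- trial_table(sub, manifest, onset_win = config$onset_win,
                       baseline_win = config$baseline_win)
    inc <- inclusion_test(tab, alpha = config$alpha,
                          f_split = config$f_split,
                          sum_split = config$sum_split)
    set.seed(site_seed(config$seed, i))
    cv <- estimate_resolution(tab, sigmas = config$sigmas,
                              n_boot = config$n_boot,
                              n_train = config$n_train,
                              n_test = config$n_test, grid = grid)
    rows[[i]] <- data.frame(
      site_id = site_ids[i], p_inclusion = inc$p_value,
      included = inc$include, best_sigma = cv$best_sigma, flat = cv$flat)
  }
  results <- do.call(rbind, rows)
  summary <- summarize_sites(results)
  out <- list(results = results, summary = summary, config = config)
  if (!is.null(out_dir)) write_results(out, out_dir)
  out
}

write_results <- function(out, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  utils::write.csv(out$results, file.path(out_dir, "results.csv"),
                   row.names = FALSE)
  s <- out$summary
  s$histogram <- NULL
  jsonlite::write_json(s, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(unclass(out$config), file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' Write a trial table to CSV
#'
#' @param table A `trial_table`.
#' @param path Output path.
#' @param site_id Optional site label column.
#' @export
write_trials_csv <- function(table, path, site_id = NULL) {
  df <- as.data.frame(table)
  if (!is.null(site_id)) df <- cbind(site_id = site_id, df)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
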