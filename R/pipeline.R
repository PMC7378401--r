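#' End-to-end run configuration
#'
#' Bundles the stage configurations of a full analysis run: simulate a
#' cohort, build feature matrices per condition, decode per scope, run
#' stability selection, and write structured outputs. One master seed
#' deterministically derives per-stage seeds (fixed offsets per stage), so
#' stages can be rerun independently.
#'
#' @param simulation A [simulation_config()].
#' @param n_per_average,n_averages,window_ms Feature-stage settings
#'   (`n_averages = NULL` = maximal disjoint partition).
#' @param grid,folds,train_fraction,split_unit,scopes Decoding settings.
#' @param stability A [stability_params()]; its seed is overridden by the
#'   derived stage seed.
#' @param thresholds,report_threshold Stability sweep settings.
#' @param output_dir Output directory (created on run); `NULL` keeps
#'   results in memory only.
#' @param seed Master seed.
#' @return List of class `run_config`.
#' @export
run_config <- function(simulation = simulation_config(),
                       n_per_average = 100, n_averages = NULL,
                       window_ms = 10, grid = grid_spec(), folds = 5,
                       train_fraction = 0.8,
                       split_unit = c("pseudo_trial", "subject"),
                       scopes = c("whole", "LH", "RH"),
                       stability = stability_params(),
                       thresholds = default_thresholds(),
                       report_threshold = 0.5,
                       output_dir = NULL, seed = 1L) {
  split_unit <- match.arg(split_unit)
  structure(list(simulation = simulation, n_per_average = n_per_average,
                 n_averages = n_averages, window_ms = window_ms,
                 grid = grid, folds = folds,
                 train_fraction = train_fraction, split_unit = split_unit,
                 scopes = scopes, stability = stability,
                 thresholds = thresholds,
                 report_threshold = report_threshold,
                 output_dir = output_dir, seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full decoding and region-selection pipeline
#'
#' Simulates the cohort, builds the pseudo-trial feature matrix for each
#' condition, runs sliding-window decoding for every scope, runs stability
#' selection on whole-brain features, and (when `output_dir` is set)
#' writes a peak-performance summary table, per-window accuracy time
#' courses, the threshold sweep, the ranked ROI networks, and a JSON
#' manifest with seeds, parameters and file checksums.
#'
#' @param config A [run_config()].
#' @return List of class `pipeline_run`: `decoding` (list per
#'   condition/scope), `stability` (list per condition), `summary` (data
#'   frame of peak metrics), `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  seeds <- list(simulate = derive_seed(config$seed, "simulate"),
                features = derive_seed(config$seed, "features"),
                decode = derive_seed(config$seed, "decode"),
                stability = derive_seed(config$seed, "stability"))
  sim_cfg <- config$simulation
  sim_cfg$seed <- seeds$simulate
  conditions <- c("clear", "noise")
  atlas <- if (sim_cfg$n_rois == 68L) make_atlas() else NULL

  decoding <- list(); stab <- list(); rows <- list()
  for (cond in conditions) {
    cohort <- simulate_cohort(sim_cfg, conditions = cond)
    fm <- build_feature_matrix(cohort, condition = cond,
                               n_per_average = config$n_per_average,
                               n_averages = config$n_averages,
                               window_ms = config$window_ms,
                               baseline_ms = sim_cfg$baseline_ms,
                               atlas = atlas, seed = seeds$features)
    rm(cohort); gc(verbose = FALSE)
    for (scope in config$scopes) {
      dr <- decode_windows(fm, scope = scope, grid = config$grid,
                           folds = config$folds,
                           train_fraction = config$train_fraction,
                           split_unit = config$split_unit,
                           seed = seeds$decode)
      decoding[[paste(cond, scope, sep = "_")]] <- dr
      rows[[paste(cond, scope)]] <- data.frame(
        condition = cond, scope = scope,
        accuracy_pct = 100 * dr$best$accuracy,
        auc_pct = 100 * dr$best$auc, f1_pct = 100 * dr$best$f1,
        latency_ms = dr$best$latency_ms, C = dr$best$C,
        gamma = dr$best$gamma)
    }
    sp <- config$stability
    sp$seed <- seeds$stability
    stab[[cond]] <- stability_selection(
      fm, params = sp, thresholds = config$thresholds,
      report_threshold = config$report_threshold, grid = config$grid,
      folds = config$folds, train_fraction = config$train_fraction,
      split_unit = config$split_unit, atlas = atlas)
  }
  summary_tab <- do.call(rbind, rows)
  rownames(summary_tab) <- NULL

  manifest <- list(seed = config$seed, stage_seeds = seeds,
                   n_subjects = c(NH = sim_cfg$n_nh, HI = sim_cfg$n_hi),
                   n_trials = sim_cfg$n_trials,
                   n_features = length(stab[[1]]$scores),
                   files = character())

  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- character()
    f <- file.path(config$output_dir, "peak_performance.csv")
    utils::write.csv(summary_tab, f, row.names = FALSE); paths <- c(paths, f)
    tc <- do.call(rbind, lapply(names(decoding), function(k) {
      cbind(condition = decoding[[k]]$condition,
            scope = decoding[[k]]$scope, decoding[[k]]$per_window)
    }))
    f <- file.path(config$output_dir, "accuracy_timecourse.csv")
    utils::write.csv(tc, f, row.names = FALSE); paths <- c(paths, f)
    for (cond in conditions) {
      f <- file.path(config$output_dir,
                     paste0("threshold_sweep_", cond, ".csv"))
      utils::write.csv(stab[[cond]]$sweep, f, row.names = FALSE)
      paths <- c(paths, f)
      if (!is.null(stab[[cond]]$chosen$regions)) {
        f <- file.path(config$output_dir,
                       paste0("roi_network_", cond, ".csv"))
        utils::write.csv(stab[[cond]]$chosen$regions, f, row.names = FALSE)
        paths <- c(paths, f)
      }
    }
    manifest$files <- as.list(tools::md5sum(paths))
    jsonlite::write_json(manifest,
                         file.path(config$output_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  structure(list(decoding = decoding, stability = stab,
                 summary = summary_tab, manifest = manifest),
            class = "pipeline_run")
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("Pipeline run: peak decoding performance\n")
  tab <- x$summary
  tab[, 3:6] <- round(tab[, 3:6], 2)
  print(tab, row.names = FALSE)
  for (cond in names(x$stability)) {
    reg <- x$stability[[cond]]$chosen$regions
    if (!is.null(reg))
      cat(sprintf("%s: %d stable ROIs at threshold %.2f\n", cond,
                  nrow(reg), x$stability[[cond]]$chosen$threshold))
  }
  invisible(x)
}

#' Hemisphere summary of a selected ROI network
#'
#' Fraction of selected regions per hemisphere (the lateralization
#' summary) and counts per lobe, computed from a ranked region table.
#'
#' @param regions A region table from [select_regions()].
#' @return List with `n`, `by_hemisphere` (counts and fractions) and
#'   `by_lobe` (counts).
#' @export
lateralization_summary <- function(regions) {
  n <- nrow(regions)
  hemi <- table(factor(regions$hemisphere, levels = c("L", "R")))
  list(n = n,
       by_hemisphere = data.frame(hemisphere = names(hemi),
                                  n = as.integer(hemi),
                                  fraction = if (n) as.integer(hemi) / n
                                             else rep(NA_real_, 2)),
       by_lobe = as.data.frame(table(lobe = regions$lobe),
                               stringsAsFactors = FALSE))
}
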