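# Reporting layer: a validated JSON run configuration and the three pipeline
# entry points (base case, threshold grid, scenario discovery), each writing
# plain-text outputs with the seed and a configuration hash embedded as a
# comment header for provenance.

CONFIG_KEYS <- c("natural_history", "life_table", "econ", "colonoscopy",
                 "scenario_spec", "cohort_n", "seed", "models", "output_dir")

#' Assemble and validate a run configuration
#'
#' @param natural_history list of [nathist_params()] arguments.
#' @param life_table optional path to a life-table CSV (`age,q`); `NULL`
#'   uses the parametric Gompertz-Makeham default.
#' @param econ list of [econ_params()] arguments.
#' @param colonoscopy list of [colonoscopy_profile()] arguments.
#' @param scenario_spec list of [scenario_spec()] arguments.
#' @param cohort_n shared cohort size.
#' @param seed master seed.
#' @param models number of natural-history parameter variants run to mimic
#'   cross-model ranges (1 = the calibrated default only).
#' @param output_dir directory for output files.
#' @return a list of class `run_config` with instantiated parameter objects.
#' @export
run_config <- function(natural_history = list(), life_table = NULL,
                       econ = list(), colonoscopy = list(),
                       scenario_spec = list(), cohort_n = 20000L, seed = 1L,
                       models = 1L, output_dir = ".") {
  cfg <- list(
    params = do.call(nathist_params, natural_history),
    life_table = if (is.null(life_table)) gompertz_makeham_life_table()
                 else read_life_table(life_table),
    econ = do.call(econ_params, econ),
    colo = do.call(colonoscopy_profile, colonoscopy),
    spec = do.call("scenario_spec", scenario_spec),
    cohort_n = as.integer(cohort_n),
    seed = as.integer(seed),
    models = as.integer(models),
    output_dir = output_dir)
  stopifnot(cfg$cohort_n >= 1L, cfg$models >= 1L)
  cfg$hash <- stream_id(as.character(jsonlite::toJSON(
    list(natural_history, life_table, econ, colonoscopy, scenario_spec,
         cohort_n, seed, models), auto_unbox = TRUE)))
  class(cfg) <- "run_config"
  cfg
}

#' Read a run configuration from JSON
#'
#' Keys mirror the [run_config()] arguments; unknown keys are rejected with
#' the offending name.
#'
#' @param path path to a JSON configuration file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  unknown <- setdiff(names(raw), CONFIG_KEYS)
  if (length(unknown))
    stop("read_run_config: unknown configuration key(s): ",
         paste(unknown, collapse = ", "))
  do.call(run_config, raw)
}

provenance_header <- function(cfg)
  sprintf("# crcscreen seed=%d config_hash=%d", cfg$seed, cfg$hash)

write_output_csv <- function(df, path, cfg) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_header(cfg), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(df)
}

#' Read back a pipeline output CSV
#'
#' Skips the provenance comment header written by the pipeline functions.
#' @param path CSV path.
#' @return data.frame.
#' @export
read_output_csv <- function(path)
  utils::read.csv(path, comment.char = "#")

# k slightly perturbed natural-history parameter sets standing in for the
# spread of independently calibrated models
nathist_model_variants <- function(params, k) {
  if (k == 1L) return(list(default = params))
  scale <- seq(0.94, 1.06, length.out = k)
  out <- list()
  for (m in seq_len(k)) {
    p <- params
    p$baseline_onset_rate <- params$baseline_onset_rate * scale[m]
    out[[paste0("model", m)]] <- p
  }
  out
}

#' Run the base-case comparison
#'
#' Evaluates no screening, annual FIT, decennial colonoscopy and the
#' triennial CMS-minimum blood test (74% CRC sensitivity, 10% advanced
#' adenoma, 90% specificity, $500) on one cohort and writes `summary.csv`
#' (one row per strategy, headline-table column order), `frontier.csv`, and
#' `events_sample.csv` (the full event log of a small prefix of the cohort).
#'
#' @param config a `run_config`.
#' @return invisibly, a list with `summaries`, `frontier` and output paths.
#' @export
run_base_case <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- simulate_cohort(config$params, config$life_table,
                            n = config$cohort_n, seed = config$seed)
  strategies <- list(strategy_no_screening(), strategy_fit(),
                     strategy_colonoscopy(), strategy_blood())
  outs <- lapply(strategies, function(s)
    run_strategy(cohort, s, config$colo, config$econ))
  summaries <- lapply(outs, summarize_outcomes, no_screen_outcome = outs[[1L]],
                      econ = config$econ)
  frontier <- compute_frontier(summaries, config$econ)
  sample_cohort <- simulate_cohort(config$params, config$life_table,
                                   n = min(100L, config$cohort_n),
                                   seed = config$seed)
  ev <- run_strategy(sample_cohort, strategy_fit(), config$colo, config$econ,
                     keep_events = TRUE)$events
  paths <- file.path(config$output_dir,
                     c("summary.csv", "frontier.csv", "events_sample.csv"))
  write_summary_wrapped(summaries, frontier, paths[1L], config)
  write_output_csv(frontier, paths[2L], config)
  write_output_csv(ev, paths[3L], config)
  invisible(list(summaries = summaries, frontier = frontier, paths = paths))
}

write_summary_wrapped <- function(summaries, frontier, path, cfg) {
  tmp <- tempfile(fileext = ".csv")
  df <- write_summary_csv(summaries, frontier, tmp)
  unlink(tmp)
  write_output_csv(df, path, cfg)
}

#' Run the full-factorial threshold analysis
#'
#' Evaluates the configuration's scenario grid (900 scenarios by default)
#' against annual FIT and decennial colonoscopy on the shared cohort, once
#' per natural-history variant when `models > 1`, and writes
#' `scenarios.csv`.
#'
#' @param config a `run_config`.
#' @param progress print per-regimen progress.
#' @return invisibly, the scenario table.
#' @export
run_threshold <- function(config, progress = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  grid <- build_scenario_grid(config$spec)
  variants <- nathist_model_variants(config$params, config$models)
  tabs <- lapply(names(variants), function(nm) {
    cohort <- simulate_cohort(variants[[nm]], config$life_table,
                              n = config$cohort_n, seed = config$seed)
    evaluate_scenarios(grid, cohort, econ = config$econ, colo = config$colo,
                       model = nm, progress = progress)
  })
  tab <- do.call(rbind, tabs)
  write_output_csv(tab, file.path(config$output_dir, "scenarios.csv"), config)
  invisible(tab)
}

#' Run scenario discovery on a threshold-analysis table
#'
#' Ranks the design variables by random-forest Gini importance, fits the
#' smoothed NMB surface over the top numeric characteristics conditioned on
#' 92% CRC sensitivity, extracts iso-NMB contours (including the
#' colonoscopy reference level), and writes `importance.csv`,
#' `nmb_surface.csv` and `contours.json`.
#'
#' @param config a `run_config`.
#' @param scenario_table a table from [run_threshold()]; recomputed when
#'   `NULL`.
#' @param reference_nmb the colonoscopy net monetary benefit used as contour
#'   reference; computed from the cohort when `NULL`.
#' @param contour_levels additional contour levels (USD).
#' @return invisibly, a list with `importance`, `surface`, `contours`.
#' @export
run_discovery <- function(config, scenario_table = NULL,
                          reference_nmb = NULL,
                          contour_levels = NULL) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(scenario_table)) scenario_table <- run_threshold(config)
  if (is.null(reference_nmb)) {
    cohort <- simulate_cohort(config$params, config$life_table,
                              n = config$cohort_n, seed = config$seed)
    o_ns <- run_strategy(cohort, strategy_no_screening(), config$colo, config$econ)
    o_col <- run_strategy(cohort, strategy_colonoscopy(), config$colo, config$econ)
    reference_nmb <- summarize_outcomes(o_col, o_ns, config$econ)$nmb_per_person
  }
  importance <- rank_importance(scenario_table, seed = config$seed)
  surface <- fit_nmb_surface(scenario_table,
                             conditioning = list(crc_sens = max(scenario_table$crc_sens)))
  levels <- sort(unique(c(reference_nmb, contour_levels)))
  contours <- extract_contours(surface, levels)
  write_output_csv(as.data.frame(importance),
                   file.path(config$output_dir, "importance.csv"), config)
  write_output_csv(surface$grid,
                   file.path(config$output_dir, "nmb_surface.csv"), config)
  jsonlite::write_json(
    list(levels = levels, reference_nmb = reference_nmb,
         panels = lapply(unclass(contours), function(panel)
           lapply(panel, function(pp)
             list(level = pp$level, x = pp$x, y = pp$y)))),
    file.path(config$output_dir, "contours.json"),
    auto_unbox = TRUE, digits = NA)
  invisible(list(importance = importance, surface = surface,
                 contours = contours, reference_nmb = reference_nmb))
}
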