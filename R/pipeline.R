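pipeline_defaults <- list(
  baseline_year = 1970, final_year = 2014, cap = 1, bootstrap = 1000,
  seed = 1, window = "song", buffer_radius_km = 5, influence = FALSE,
  specialists_only = FALSE)

read_pipeline_config <- function(config) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  utils::modifyList(pipeline_defaults, cfg)
}

#' Run the index stage of the pipeline
#'
#' Reads the population and richness tables, builds the weighted composite
#' index with bootstrap bands, and writes `index.csv` (year, index, ci_low,
#' ci_high, n_species), `species_trends.csv` and `diagnostics.csv` (per-year
#' percent declining plus per-group mean rates) under `out_dir`. Every
#' filter step reports the number of populations it removed.
#'
#' @param config Path to a YAML config or an equivalent named list. Keys:
#'   `populations`, `richness`, `out_dir`, and optionally `baseline_year`,
#'   `final_year`, `cap`, `bootstrap`, `seed`, `specialists_only`.
#' @return The `forest_index` object, invisibly.
#' @export
pipeline_index <- function(config) {
  cfg <- read_pipeline_config(config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  pop <- read_population_table(cfg$populations)
  inform(sprintf("index stage: %d populations read, %d rejected (<2 years)",
                 dplyr::n_distinct(pop$population_id),
                 length(attr(pop, "rejected"))))
  if (isTRUE(cfg$specialists_only)) {
    n0 <- dplyr::n_distinct(pop$population_id)
    pop <- filter(pop, .data$specialist)
    inform(sprintf("index stage: specialists filter removed %d population(s)",
                   n0 - dplyr::n_distinct(pop$population_id)))
  }
  rich <- read_richness_table(cfg$richness)
  fi <- forest_index(pop, rich, baseline_year = cfg$baseline_year,
                     final_year = cfg$final_year, cap = cfg$cap,
                     bootstrap = cfg$bootstrap, seed = cfg$seed)
  readr::write_csv(fi$index, file.path(cfg$out_dir, "index.csv"))
  readr::write_csv(fi$species_rates,
                   file.path(cfg$out_dir, "species_trends.csv"))
  diag <- percent_declining(fi$species_rates)
  readr::write_csv(diag, file.path(cfg$out_dir, "diagnostics.csv"))
  groups <- bind_rows(
    mutate(group_mean_rates(fi$species_rates, "taxon_group"),
           grouping = "taxon_group"),
    mutate(group_mean_rates(fi$species_rates, "realm"), grouping = "realm"),
    mutate(group_mean_rates(fi$species_rates, "biome_group"),
           grouping = "biome_group"))
  readr::write_csv(groups, file.path(cfg$out_dir, "group_summary.csv"))
  inform(sprintf("index stage: final index %.3f over %d species",
                 tail(fi$index$index, 1), fi$meta$n_species))
  invisible(fi)
}

#' Run the correlates stage of the pipeline
#'
#' Reads the population and covariate tables, computes windowed average
#' rates of change, derives the tree-cover covariates under a 1-year lag,
#' fits the univariate mixed-model battery for all forest populations and
#' for specialists only, and writes `model_comparison.csv` (and
#' `influence.csv` when `influence: true`) under `out_dir`.
#'
#' @param config Path to a YAML config or an equivalent named list. Keys:
#'   `populations`, `covariates`, `out_dir`, and optionally `window`
#'   (`"song"`/`"hansen"`), `cap`, `influence`, `buffer_radius_km`.
#' @return The model-comparison tibble, invisibly.
#' @export
pipeline_correlates <- function(config) {
  cfg <- read_pipeline_config(config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  pop <- read_population_table(cfg$populations)
  cov <- read_covariate_table(cfg$covariates,
                              buffer_radius_km = cfg$buffer_radius_km)
  adj <- adjust_zeros(pop)
  rates <- annual_log_rates(fit_population_model(adj), cap = cfg$cap)
  resp <- windowed_response(rates, pop, window = cfg$window)
  inform(sprintf(
    "correlates stage: %d populations retained, %d excluded by the window rule",
    nrow(resp), length(attr(resp, "excluded"))))
  smoothed <- smooth_cover_series(cov, buffer_radius_km = cfg$buffer_radius_km)
  cc <- derive_cover_covariates(smoothed, cov, resp)
  dat <- prepare_predictors(resp, cc, cov)
  predictors <- c("cover_trend", "mean_tree_cover", "mean_bare_ground",
                  "cover_2000", "loss_area", "prop_change_2000_2010",
                  "exploitation", "log_body_mass", "road_density", "hpd",
                  "travel_time")
  predictors <- predictors[vapply(predictors, function(p) {
    sum(!is.na(dat[[p]])) >= 10 && dplyr::n_distinct(stats::na.omit(dat[[p]])) > 1
  }, TRUE)]
  models <- bind_rows(
    mutate(fit_correlate_models(dat, predictors), subset = "all"),
    mutate(fit_correlate_models(filter(dat, .data$specialist), predictors),
           subset = "specialists"))
  models$window <- if (is.character(cfg$window)) cfg$window else
    paste(cfg$window, collapse = "-")
  readr::write_csv(models, file.path(cfg$out_dir, "model_comparison.csv"))
  if (isTRUE(cfg$influence)) {
    infl <- purrr::map(predictors, function(p) {
      mutate(genus_influence(dat, p), predictor = p)
    }) %>% bind_rows()
    readr::write_csv(infl, file.path(cfg$out_dir, "influence.csv"))
  }
  inform(sprintf("correlates stage: %d model comparisons written",
                 nrow(models)))
  invisible(models)
}

#' Run the simulate stage of the pipeline
#'
#' Generates the population, richness and covariate tables of a scenario
#' together with their ground-truth sidecars, and writes all five CSVs under
#' `out_dir`.
#'
#' @param config Path to a YAML config or an equivalent named list. Keys:
#'   `out_dir`, `seed`, and any [forest_scenario()] argument.
#' @return Named list of the written file paths, invisibly.
#' @export
pipeline_simulate <- function(config) {
  cfg <- read_pipeline_config(config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  sc_args <- cfg[intersect(names(cfg), names(formals(forest_scenario)))]
  sc <- do.call(forest_scenario, sc_args)
  gp <- generate_populations(sc, seed = cfg$seed)
  gc <- generate_cover_series(sc, gp$truth, seed = cfg$seed)
  paths <- list(
    populations = file.path(cfg$out_dir, "populations.csv"),
    richness = file.path(cfg$out_dir, "richness.csv"),
    covariates = file.path(cfg$out_dir, "covariates.csv"),
    truth = file.path(cfg$out_dir, "truth_populations.csv"),
    cover_truth = file.path(cfg$out_dir, "truth_cover.csv"))
  write_population_table(gp$populations, paths$populations)
  write_richness_table(generate_richness(sc), paths$richness)
  write_covariate_table(gc$covariates, paths$covariates)
  readr::write_csv(gp$truth, paths$truth)
  readr::write_csv(gc$cover_truth, paths$cover_truth)
  inform(sprintf("simulate stage: %d populations written to %s",
                 dplyr::n_distinct(gp$populations$population_id),
                 cfg$out_dir))
  invisible(paths)
}

#' Run the full pipeline from a config file
#'
#' Dispatches the named stages in order. With a fixed `seed` the outputs are
#' byte-identical across runs.
#'
#' @param config Path to a YAML config or an equivalent named list.
#' @param stages Character vector among `"simulate"`, `"index"`,
#'   `"correlates"`.
#' @return Named list of stage results, invisibly.
#' @export
run_pipeline <- function(config, stages = c("index", "correlates")) {
  stages <- match.arg(stages, c("simulate", "index", "correlates"),
                      several.ok = TRUE)
  res <- list()
  for (stage in stages) {
    res[[stage]] <- tryCatch(
      switch(stage,
             simulate = pipeline_simulate(config),
             index = pipeline_index(config),
             correlates = pipeline_correlates(config)),
      error = function(e) {
        abort(sprintf("pipeline stage '%s' failed: %s", stage,
                      conditionMessage(e)))
      })
  }
  invisible(res)
}
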