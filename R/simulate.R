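#' Define a synthetic-data scenario
#'
#' Bundles every knob of the synthetic Living-Planet-style dataset into one
#' validated list. The defaults describe the reference scenario used
#' throughout the package's recovery checks: 455 populations of 268 species
#' spread over the 14 realm-by-taxon subsets (Palaearctic herptiles absent),
#' monitored over spans inside 1970-2014, with a common true annual
#' multiplicative change of 0.983 (the forest-specialist headline decline
#' rate), multiplicative lognormal observation noise and 20% yearly
#' missingness.
#'
#' @param n_populations Total number of populations (default 455).
#' @param n_species Number of species the populations belong to (268).
#' @param mu_rate Mean true annual log10 rate (default `log10(0.983)`).
#' @param sigma_rate SD of the true rate across populations (default 0:
#'   every population shares `mu_rate`).
#' @param sigma_obs SD of multiplicative lognormal observation noise on the
#'   natural-log scale (default 0.05).
#' @param p_missing Probability that an interior survey year is unobserved
#'   (default 0.2); first and last years are always kept.
#' @param first_year,last_year Bounds of the monitored era (1970, 2014).
#' @param span_min,span_max Min/max intended series duration in years
#'   (10, 44); realized spans are clipped to `last_year`.
#' @param p_exploit Probability a population's primary threat is
#'   exploitation (default 0.07, matching the sparse prevalence in real
#'   extracts).
#' @param delta_exploit Additive shift of the true annual log10 rate for
#'   exploited populations (default 0).
#' @param pops_per_location Mean number of populations sharing a monitoring
#'   location (default 3).
#' @param drop_palaearctic_herptiles Mirror the real 14-subset layout
#'   (default TRUE).
#' @param cover_intercept_range Range of location cover intercepts, km^2
#'   (default `c(20, 70)` inside the ~78.5 km^2 buffer).
#' @param cover_slope_mean,cover_slope_sd Distribution of true linear cover
#'   trends, km^2 per year (defaults -0.3, 0.2).
#' @param cover_phi,cover_sigma AR(1) coefficient and innovation SD of the
#'   cover noise (defaults 0.6, 2 km^2).
#' @param buffer_radius_km Buffer radius (default 5).
#' @param richness Optional richness tibble; `NULL` uses built-in plausible
#'   forest species counts.
#' @return A list of class `forest_scenario`.
#' @export
forest_scenario <- function(n_populations = 455,
                            n_species = 268,
                            mu_rate = log10(0.983),
                            sigma_rate = 0,
                            sigma_obs = 0.05,
                            p_missing = 0.2,
                            first_year = 1970,
                            last_year = 2014,
                            span_min = 10,
                            span_max = 44,
                            p_exploit = 0.07,
                            delta_exploit = 0,
                            pops_per_location = 3,
                            drop_palaearctic_herptiles = TRUE,
                            cover_intercept_range = c(20, 70),
                            cover_slope_mean = -0.3,
                            cover_slope_sd = 0.2,
                            cover_phi = 0.6,
                            cover_sigma = 2,
                            buffer_radius_km = 5,
                            richness = NULL) {
  sc <- as.list(environment())
  stopifnot(sc$n_populations >= sc$n_species, sc$n_species >= 1,
            sc$sigma_rate >= 0, sc$sigma_obs >= 0,
            sc$p_missing >= 0, sc$p_missing < 1,
            sc$p_exploit >= 0, sc$p_exploit <= 1,
            sc$span_min >= 2, sc$span_max >= sc$span_min,
            sc$last_year > sc$first_year,
            sc$cover_phi >= 0, sc$cover_phi < 1, sc$cover_sigma >= 0)
  if (is.null(sc$richness)) sc$richness <- default_richness(sc)
  structure(sc, class = "forest_scenario")
}

# Plausible forest species-richness counts per realm and taxon: tropical
# realms richest, birds the largest class everywhere.
default_richness <- function(sc) {
  rich <- tidyr::expand_grid(realm = lpi_realms, taxon_group = lpi_taxa) %>%
    mutate(species_count = dplyr::case_when(
      .data$realm == "Neotropical" & .data$taxon_group == "birds" ~ 2000,
      .data$realm == "Neotropical" & .data$taxon_group == "mammals" ~ 600,
      .data$realm == "Neotropical" & .data$taxon_group == "herptiles" ~ 900,
      .data$realm == "Afrotropical" & .data$taxon_group == "birds" ~ 1200,
      .data$realm == "Afrotropical" & .data$taxon_group == "mammals" ~ 500,
      .data$realm == "Afrotropical" & .data$taxon_group == "herptiles" ~ 400,
      .data$realm == "IndoPacific" & .data$taxon_group == "birds" ~ 1700,
      .data$realm == "IndoPacific" & .data$taxon_group == "mammals" ~ 700,
      .data$realm == "IndoPacific" & .data$taxon_group == "herptiles" ~ 600,
      .data$realm == "Nearctic" & .data$taxon_group == "birds" ~ 300,
      .data$realm == "Nearctic" & .data$taxon_group == "mammals" ~ 120,
      .data$realm == "Nearctic" & .data$taxon_group == "herptiles" ~ 80,
      .data$realm == "Palaearctic" & .data$taxon_group == "birds" ~ 400,
      .data$realm == "Palaearctic" & .data$taxon_group == "mammals" ~ 150,
      .data$realm == "Palaearctic" & .data$taxon_group == "herptiles" ~ 60))
  if (sc$drop_palaearctic_herptiles) {
    rich <- filter(rich, !(.data$realm == "Palaearctic" &
                             .data$taxon_group == "herptiles"))
  }
  rich
}

#' Generate the synthetic richness table
#'
#' @param scenario A [forest_scenario()].
#' @return Richness tibble valid under [validate_richness_table()].
#' @export
generate_richness <- function(scenario) {
  validate_richness_table(scenario$richness)
}

scenario_subsets <- function(scenario) {
  distinct(scenario$richness, .data$realm, .data$taxon_group)
}

# sample() with scalar-x surprise removed.
resample <- function(x, n) x[sample.int(length(x), n, replace = TRUE)]

# Biome label per realm: tropical realms tropical, the rest temperate.
realm_biome <- function(realm) {
  ifelse(realm %in% c("Neotropical", "Afrotropical", "IndoPacific"),
         "tropical", "temperate")
}

#' Generate a synthetic population table with known ground truth
#'
#' Builds one abundance series per population: a geometric trajectory
#' `N_t = N_first * 10^(r * (t - first))` at the population's true annual
#' log10 rate `r`, perturbed by multiplicative lognormal observation noise,
#' with interior years dropped at the missingness probability (the first and
#' last years are always observed, preserving the span). Species are spread
#' over the scenario's realm-by-taxon subsets; populations of a species
#' share its subset; locations are shared by a few populations each; genera
#' group a handful of species. Exploited populations (flag drawn at
#' `p_exploit`) have their true rate shifted by `delta_exploit`.
#'
#' @param scenario A [forest_scenario()].
#' @param seed Integer seed; the same seed yields the identical table.
#' @return List with `populations` (long tibble passing
#'   [validate_population_table()]) and `truth` (one row per population:
#'   `population_id`, `species_id`, `genus`, `location_id`, `realm`,
#'   `taxon_group`, `exploitation`, `true_rate`, `first_year`, `last_year`).
#' @export
generate_populations <- function(scenario, seed = 1) {
  sc <- scenario
  set.seed(seed)
  subsets <- scenario_subsets(sc)
  n_sub <- nrow(subsets)

  # Species across subsets (round-robin keeps every subset populated), one
  # guaranteed population per species, the rest multinomial.
  species <- tibble::tibble(
    species_id = sprintf("S%04d", seq_len(sc$n_species)),
    subset = rep(seq_len(n_sub), length.out = sc$n_species))
  extra <- sc$n_populations - sc$n_species
  extra_counts <- if (extra > 0) {
    tabulate(sample.int(sc$n_species, extra, replace = TRUE),
             nbins = sc$n_species)
  } else rep(0L, sc$n_species)
  species$n_pops <- 1L + extra_counts
  # Genera: ~3 species each, never straddling subsets.
  species <- species %>%
    group_by(.data$subset) %>%
    mutate(genus = sprintf("G%02d_%02d", .data$subset[1],
                           (dplyr::row_number() - 1) %/% 3 + 1)) %>%
    ungroup()

  truth <- species[rep(seq_len(nrow(species)), species$n_pops), ] %>%
    mutate(population_id = sprintf("P%05d", dplyr::row_number()),
           realm = subsets$realm[.data$subset],
           taxon_group = subsets$taxon_group[.data$subset],
           biome_group = realm_biome(.data$realm),
           specialist = TRUE,
           exploitation = runif(n()) < sc$p_exploit,
           true_rate = rnorm(n(), sc$mu_rate, sc$sigma_rate) +
             ifelse(.data$exploitation, sc$delta_exploit, 0),
           span = resample(seq(sc$span_min, sc$span_max), n()),
           first_year = resample(seq(sc$first_year,
                                     sc$last_year - sc$span_min), n()),
           last_year = pmin(.data$first_year + .data$span, sc$last_year)) %>%
    select(-"span", -"subset", -"n_pops")
  # Locations shared by a few populations within the same subset.
  truth <- truth %>%
    group_by(.data$realm, .data$taxon_group) %>%
    mutate(location_id = sprintf(
      "L%s_%s_%03d", substr(.data$realm[1], 1, 3),
      substr(.data$taxon_group[1], 1, 2),
      (dplyr::row_number() - 1) %/% max(1, round(sc$pops_per_location)) + 1)) %>%
    ungroup()

  obs <- purrr::pmap(
    list(truth$population_id, truth$first_year, truth$last_year,
         truth$true_rate),
    function(pid, y0, y1, r) {
      years <- y0:y1
      keep <- c(TRUE, runif(length(years) - 2) >= sc$p_missing, TRUE)
      years <- years[keep]
      n0 <- 10^runif(1, 1, 4)
      ab <- n0 * 10^(r * (years - y0)) *
        exp(rnorm(length(years), 0, sc$sigma_obs))
      tibble::tibble(population_id = pid, year = as.integer(years),
                     abundance = ab)
    }) %>%
    bind_rows()

  populations <- obs %>%
    left_join(select(truth, "population_id", "species_id", "genus",
                     "taxon_group", "realm", "biome_group", "specialist",
                     "location_id", "exploitation"),
              by = "population_id") %>%
    select("population_id", "species_id", "genus", "taxon_group", "realm",
           "biome_group", "specialist", "location_id", "exploitation",
           "year", "abundance")
  list(populations = validate_population_table(populations),
       truth = select(truth, "population_id", "species_id", "genus",
                      "location_id", "realm", "taxon_group", "exploitation",
                      "true_rate", "first_year", "last_year"))
}

#' Generate synthetic annual tree-cover covariates with known trends
#'
#' Per location: annual cover is `clip(intercept + slope * (t - first) +
#' AR(1) noise, 0, buffer area)`; the loss series is the year-on-year cover
#' decrease (`max(0, cover_{t-1} - cover_t)`); bare ground mirrors cover
#' downward around a location offset. Populations at the same location share
#' the series. Static pressures (body mass, road density, human population
#' density, travel time) are drawn from broad plausible ranges.
#'
#' @param scenario A [forest_scenario()].
#' @param truth Truth tibble from [generate_populations()] (locations and
#'   populations to cover).
#' @param seed Integer seed.
#' @return List with `covariates` (long tibble valid under
#'   [validate_covariate_table()]) and `cover_truth` (per location:
#'   `location_id`, `true_slope`, `intercept`).
#' @export
generate_cover_series <- function(scenario, truth, seed = 1) {
  sc <- scenario
  set.seed(seed + 10000L)
  amax <- buffer_area_km2(sc$buffer_radius_km)
  years <- seq(sc$first_year - 1, sc$last_year)
  n_y <- length(years)

  locs <- distinct(truth, .data$location_id)
  cover_truth <- locs %>%
    mutate(intercept = runif(n(), sc$cover_intercept_range[1],
                             sc$cover_intercept_range[2]),
           true_slope = rnorm(n(), sc$cover_slope_mean, sc$cover_slope_sd),
           bare_offset = runif(n(), 2, 10))

  loc_series <- purrr::pmap(
    list(cover_truth$location_id, cover_truth$intercept,
         cover_truth$true_slope, cover_truth$bare_offset),
    function(loc, a, b, bo) {
      e <- numeric(n_y)
      if (sc$cover_sigma > 0) {
        e[1] <- rnorm(1, 0, sc$cover_sigma / sqrt(1 - sc$cover_phi^2))
        for (t in 2:n_y) {
          e[t] <- sc$cover_phi * e[t - 1] + rnorm(1, 0, sc$cover_sigma)
        }
      }
      cover <- pmin(pmax(a + b * (years - years[1]) + e, 0), amax)
      loss <- c(0, pmax(0, cover[-n_y] - cover[-1]))
      bare <- pmin(pmax(bo + 0.3 * (amax - cover - bo), 0), amax - cover)
      tibble::tibble(location_id = loc, year = as.integer(years),
                     tree_cover_km2 = cover, bare_ground_km2 = bare,
                     loss_km2 = loss)
    }) %>%
    bind_rows()

  statics <- truth %>%
    select("population_id", "location_id", "taxon_group") %>%
    mutate(body_mass_g = 10^rnorm(n(), mean = ifelse(
      .data$taxon_group == "mammals", 3,
      ifelse(.data$taxon_group == "birds", 2, 1.5)), sd = 0.8),
      road_density_km = stats::rexp(n(), rate = 1 / 20),
      hpd = 10^runif(n(), 0, 3),
      travel_time_min = stats::rexp(n(), rate = 1 / 300))

  covariates <- statics %>%
    left_join(loc_series, by = "location_id",
              relationship = "many-to-many") %>%
    left_join(select(loc_series, "location_id", "year", "tree_cover_km2") %>%
                filter(.data$year %in% c(2000L, 2010L)) %>%
                tidyr::pivot_wider(names_from = "year",
                                   values_from = "tree_cover_km2",
                                   names_prefix = "cover_") %>%
                rename(cover_2000_km2 = "cover_2000",
                       cover_2010_km2 = "cover_2010"),
              by = "location_id") %>%
    select("population_id", "year", "tree_cover_km2", "bare_ground_km2",
           "loss_km2", "cover_2000_km2", "cover_2010_km2", "body_mass_g",
           "road_density_km", "hpd", "travel_time_min")
  list(covariates = validate_covariate_table(
         covariates, buffer_radius_km = sc$buffer_radius_km),
       cover_truth = select(cover_truth, "location_id", "intercept",
                            "true_slope"))
}

#' Simulate response tables for mixed-model power and size studies
#'
#' Draws per-population windowed average rates directly from the
#' mixed-model data-generating process: a shared mean, a Gaussian location
#' random intercept, Gaussian residual noise, and an additive shift `delta`
#' for exploited populations. Used to characterise the power and size of
#' the AIC >= 2 decision rule without running the full pipeline.
#'
#' @param n Number of populations (default 500).
#' @param n_locations Number of monitoring locations (default 100).
#' @param delta True exploitation effect on the annual log10 rate
#'   (default -0.02).
#' @param p_exploit Exploitation prevalence (default 0.3).
#' @param mu Baseline mean rate (default -0.0075, a mild decline).
#' @param sigma_location SD of the location random intercept (default 0.02).
#' @param sigma_resid Residual SD (default 0.04).
#' @param seed Integer seed.
#' @return Tibble `population_id`, `location_id`, `genus`, `exploitation`,
#'   `avg_rate`.
#' @export
simulate_mixed_responses <- function(n = 500, n_locations = 100,
                                     delta = -0.02, p_exploit = 0.3,
                                     mu = -0.0075, sigma_location = 0.02,
                                     sigma_resid = 0.04, seed = 1) {
  set.seed(seed)
  loc <- sample.int(n_locations, n, replace = TRUE)
  u <- rnorm(n_locations, 0, sigma_location)
  expl <- runif(n) < p_exploit
  tibble::tibble(
    population_id = sprintf("P%05d", seq_len(n)),
    location_id = sprintf("L%03d", loc),
    genus = sprintf("G%02d", (loc - 1) %% 25 + 1),
    exploitation = expl,
    avg_rate = mu + delta * expl + u[loc] + rnorm(n, 0, sigma_resid))
}
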