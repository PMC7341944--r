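#' Read a long-format population abundance table
#'
#' Reads a CSV with one row per population-year holding the abundance
#' observation plus the taxonomy/geography tags used downstream. Required
#' columns: `population_id`, `species_id`, `genus`, `taxon_group`, `realm`,
#' `biome_group`, `specialist`, `location_id`, `exploitation`, `year`,
#' `abundance`.
#'
#' Structural violations (missing columns, duplicate population-year rows,
#' negative abundance, non-integer years) are errors. Populations with fewer
#' than two observation years cannot carry a trend and are dropped with a
#' message; the dropped ids are kept in the `"rejected"` attribute so that
#' filter accounting reconciles (input = used + rejected).
#'
#' @param path Path to a CSV file.
#' @return A tibble of validated population-year records, ordered by
#'   population and year, with attribute `"rejected"` (character vector of
#'   dropped population ids).
#' @export
read_population_table <- function(path) {
  cols <- readr::cols(
    population_id = readr::col_character(),
    species_id = readr::col_character(),
    genus = readr::col_character(),
    taxon_group = readr::col_character(),
    realm = readr::col_character(),
    biome_group = readr::col_character(),
    specialist = readr::col_logical(),
    location_id = readr::col_character(),
    exploitation = readr::col_logical(),
    year = readr::col_double(),
    abundance = readr::col_double()
  )
  pop <- readr::read_csv(path, col_types = cols)
  validate_population_table(pop)
}

#' Validate an in-memory population table
#'
#' Applies the same contract as [read_population_table()] to a data frame
#' already in memory (e.g. straight from [generate_populations()]).
#'
#' @param pop Data frame of population-year records.
#' @return Validated tibble (see [read_population_table()]).
#' @export
validate_population_table <- function(pop) {
  required <- c("population_id", "species_id", "genus", "taxon_group",
                "realm", "biome_group", "specialist", "location_id",
                "exploitation", "year", "abundance")
  missing_cols <- setdiff(required, names(pop))
  if (length(missing_cols) > 0) {
    abort(paste0("population table is missing required column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  pop <- tibble::as_tibble(pop)

  if (any(pop$year %% 1 != 0)) {
    abort("population table: 'year' must be integer-valued")
  }
  bad_ab <- which(is.na(pop$abundance) | pop$abundance < 0)
  if (length(bad_ab) > 0) {
    ex <- pop[bad_ab[1], ]
    abort(sprintf(
      "population table: missing or negative abundance (first offender: %s, %d)",
      ex$population_id, as.integer(ex$year)))
  }
  dup <- pop %>%
    count(.data$population_id, .data$year) %>%
    filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(sprintf(
      "population table: duplicate (population_id, year) rows, e.g. (%s, %d)",
      dup$population_id[1], as.integer(dup$year[1])))
  }
  bad_taxon <- setdiff(unique(pop$taxon_group), lpi_taxa)
  if (length(bad_taxon) > 0) {
    abort(paste0("unknown taxon_group label(s): ",
                 paste(bad_taxon, collapse = ", ")))
  }
  bad_realm <- setdiff(unique(pop$realm), lpi_realms)
  if (length(bad_realm) > 0) {
    abort(paste0("unknown realm label(s): ", paste(bad_realm, collapse = ", ")))
  }

  n_years <- pop %>%
    count(.data$population_id, name = "n_years")
  rejected <- n_years$population_id[n_years$n_years < 2]
  if (length(rejected) > 0) {
    inform(sprintf(
      "dropping %d population(s) with fewer than 2 observation years",
      length(rejected)))
    pop <- filter(pop, !.data$population_id %in% rejected)
  }

  pop <- arrange(pop, .data$population_id, .data$year)
  pop$year <- as.integer(pop$year)
  attr(pop, "rejected") <- rejected
  pop
}

#' Write a population table
#'
#' Inverse of [read_population_table()]; the pair round-trips exactly.
#'
#' @param pop Population tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_population_table <- function(pop, path) {
  readr::write_csv(pop, path)
  invisible(path)
}

#' Read a forest species-richness table
#'
#' CSV with columns `realm`, `taxon_group`, `species_count`: the number of
#' forest species per biogeographic realm and taxonomic group, used to weight
#' the composite index. Rows with non-positive counts or unknown labels are
#' errors; a (realm, taxon) pair may simply be absent when no richness
#' weighting is needed for it.
#'
#' @param path Path to a CSV file.
#' @return A tibble with columns `realm`, `taxon_group`, `species_count`.
#' @export
read_richness_table <- function(path) {
  cols <- readr::cols(
    realm = readr::col_character(),
    taxon_group = readr::col_character(),
    species_count = readr::col_double()
  )
  rich <- readr::read_csv(path, col_types = cols)
  validate_richness_table(rich)
}

#' Validate an in-memory richness table
#'
#' @param rich Data frame with columns `realm`, `taxon_group`,
#'   `species_count`.
#' @return Validated tibble.
#' @export
validate_richness_table <- function(rich) {
  required <- c("realm", "taxon_group", "species_count")
  missing_cols <- setdiff(required, names(rich))
  if (length(missing_cols) > 0) {
    abort(paste0("richness table is missing required column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  rich <- tibble::as_tibble(rich)
  if (any(is.na(rich$species_count) | rich$species_count <= 0)) {
    abort("richness table: species_count must be a positive integer")
  }
  bad_realm <- setdiff(unique(rich$realm), lpi_realms)
  if (length(bad_realm) > 0) {
    abort(paste0("unknown realm label(s): ", paste(bad_realm, collapse = ", ")))
  }
  bad_taxon <- setdiff(unique(rich$taxon_group), lpi_taxa)
  if (length(bad_taxon) > 0) {
    abort(paste0("unknown taxon_group label(s): ",
                 paste(bad_taxon, collapse = ", ")))
  }
  dup <- rich %>%
    count(.data$realm, .data$taxon_group) %>%
    filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort("richness table: duplicate (realm, taxon_group) rows")
  }
  arrange(rich, .data$realm, .data$taxon_group)
}

#' Write a richness table
#' @param rich Richness tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_richness_table <- function(rich, path) {
  readr::write_csv(rich, path)
  invisible(path)
}

#' Read a per-population covariate table
#'
#' Long format, one row per population-year, carrying the annual 5 km-buffer
#' tree-cover series together with population-level (time-constant)
#' covariates repeated down the rows. Columns: `population_id`, `year`,
#' `tree_cover_km2`, `bare_ground_km2`, `loss_km2`, `cover_2000_km2`,
#' `cover_2010_km2`, `body_mass_g`, `road_density_km`, `hpd`,
#' `travel_time_min`. Any covariate may be `NA` (missing is a flagged state,
#' not an error), but areas must lie in `[0, pi * radius^2]`.
#'
#' @param path Path to a CSV file.
#' @param buffer_radius_km Buffer radius used for the area bound (default 5).
#' @return A tibble of covariate records.
#' @export
read_covariate_table <- function(path, buffer_radius_km = 5) {
  cols <- readr::cols(
    population_id = readr::col_character(),
    year = readr::col_double(),
    tree_cover_km2 = readr::col_double(),
    bare_ground_km2 = readr::col_double(),
    loss_km2 = readr::col_double(),
    cover_2000_km2 = readr::col_double(),
    cover_2010_km2 = readr::col_double(),
    body_mass_g = readr::col_double(),
    road_density_km = readr::col_double(),
    hpd = readr::col_double(),
    travel_time_min = readr::col_double()
  )
  cov <- readr::read_csv(path, col_types = cols)
  validate_covariate_table(cov, buffer_radius_km = buffer_radius_km)
}

#' Validate an in-memory covariate table
#'
#' @param cov Data frame of covariate records.
#' @param buffer_radius_km Buffer radius used for the area bound.
#' @return Validated tibble.
#' @export
validate_covariate_table <- function(cov, buffer_radius_km = 5) {
  required <- c("population_id", "year", "tree_cover_km2", "bare_ground_km2",
                "loss_km2", "cover_2000_km2", "cover_2010_km2", "body_mass_g",
                "road_density_km", "hpd", "travel_time_min")
  missing_cols <- setdiff(required, names(cov))
  if (length(missing_cols) > 0) {
    abort(paste0("covariate table is missing required column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  cov <- tibble::as_tibble(cov)
  if (any(cov$year %% 1 != 0, na.rm = TRUE)) {
    abort("covariate table: 'year' must be integer-valued")
  }
  amax <- buffer_area_km2(buffer_radius_km)
  for (col in c("tree_cover_km2", "bare_ground_km2", "loss_km2",
                "cover_2000_km2", "cover_2010_km2")) {
    x <- cov[[col]]
    if (any(x < 0 | x > amax + 1e-9, na.rm = TRUE)) {
      abort(sprintf("covariate table: %s outside [0, %.2f] km^2", col, amax))
    }
  }
  dup <- cov %>%
    count(.data$population_id, .data$year) %>%
    filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort("covariate table: duplicate (population_id, year) rows")
  }
  cov$year <- as.integer(cov$year)
  arrange(cov, .data$population_id, .data$year)
}

#' Write a covariate table
#' @param cov Covariate tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_covariate_table <- function(cov, path) {
  readr::write_csv(cov, path)
  invisible(path)
}
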