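# Fixture builders used across the suite. Everything is generated in code;
# no data files.

# A minimal valid population table: one row per (population, year).
make_pop_table <- function(population_id, year, abundance,
                           species_id = population_id,
                           genus = "Genus1",
                           taxon_group = "birds",
                           realm = "Nearctic",
                           biome_group = "temperate",
                           specialist = TRUE,
                           location_id = "L1",
                           exploitation = FALSE) {
  tibble::tibble(
    population_id = population_id, species_id = species_id, genus = genus,
    taxon_group = taxon_group, realm = realm, biome_group = biome_group,
    specialist = specialist, location_id = location_id,
    exploitation = exploitation, year = as.integer(year),
    abundance = abundance)
}

# A species-trend table built directly (species_id, year, rate triples).
make_species_trends <- function(species_id, year, rate,
                                realm = "Nearctic", taxon_group = "birds",
                                biome_group = "temperate",
                                n_populations = 1L) {
  tibble::tibble(species_id = species_id, realm = realm,
                 taxon_group = taxon_group, biome_group = biome_group,
                 year = as.integer(year), rate = rate,
                 n_populations = n_populations)
}

# A small scenario that runs the full pipeline in a few seconds.
small_scenario <- function(...) {
  args <- utils::modifyList(list(n_populations = 60, n_species = 40),
                            list(...))
  do.call(forest_scenario, args)
}

# Richness covering a single Nearctic-birds subset (weights trivially 1).
one_subset_richness <- function() {
  tibble::tibble(realm = "Nearctic", taxon_group = "birds",
                 species_count = 100)
}
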