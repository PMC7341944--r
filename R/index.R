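#' Diversity weights from a forest species-richness table
#'
#' Two-level weighting of the aggregation hierarchy: a realm's weight is
#' proportional to its total number of forest species, and within a realm
#' each taxonomic group's weight is proportional to that group's forest
#' species count, renormalized over the groups actually represented in the
#' data (so a realm with no herptile time series splits its weight over
#' birds and mammals). Weights are strictly positive and sum to one at each
#' level.
#'
#' @param richness Richness tibble (see [read_richness_table()]).
#' @param subsets Tibble of available `(realm, taxon_group)` pairs, e.g.
#'   `dplyr::distinct(pop, realm, taxon_group)`.
#' @return Tibble with one row per available subset: `realm`, `taxon_group`,
#'   `species_count`, `realm_weight`, `taxon_weight`, and the product
#'   `weight`.
#' @export
compute_weights <- function(richness, subsets) {
  subsets <- distinct(subsets, .data$realm, .data$taxon_group)
  missing <- dplyr::anti_join(subsets, richness,
                              by = c("realm", "taxon_group"))
  if (nrow(missing) > 0) {
    abort(paste0("richness table lacks subset(s) present in the data: ",
                 paste(missing$realm, missing$taxon_group, sep = "/",
                       collapse = ", ")))
  }
  realm_totals <- richness %>%
    filter(.data$realm %in% subsets$realm) %>%
    group_by(.data$realm) %>%
    summarise(realm_total = sum(.data$species_count), .groups = "drop") %>%
    mutate(realm_weight = .data$realm_total / sum(.data$realm_total))

  subsets %>%
    left_join(richness, by = c("realm", "taxon_group")) %>%
    left_join(realm_totals, by = "realm") %>%
    group_by(.data$realm) %>%
    mutate(taxon_weight = .data$species_count / sum(.data$species_count)) %>%
    ungroup() %>%
    mutate(weight = .data$realm_weight * .data$taxon_weight) %>%
    select("realm", "taxon_group", "species_count", "realm_weight",
           "taxon_weight", "weight") %>%
    arrange(.data$realm, .data$taxon_group)
}

#' Species-level annual trends
#'
#' Averages population annual rates up to the species level within each
#' `(realm, taxon_group)` subset: for each species and year, the arithmetic
#' mean of `d_t` over the populations that have a rate that year. A year
#' appears for a species iff at least one of its populations has a rate that
#' year. The species' biome label is the majority biome of its populations.
#'
#' @param rates Output of [annual_log_rates()].
#' @param pop Population tibble supplying the `population_id` to
#'   species/subset mapping.
#' @return Tibble `species_id`, `realm`, `taxon_group`, `biome_group`,
#'   `year`, `rate`, `n_populations`.
#' @export
species_trends <- function(rates, pop) {
  meta <- pop %>%
    distinct(.data$population_id, .data$species_id, .data$realm,
             .data$taxon_group, .data$biome_group)
  rates %>%
    dplyr::inner_join(meta, by = "population_id") %>%
    group_by(.data$species_id, .data$realm, .data$taxon_group, .data$year) %>%
    summarise(
      rate = mean(.data$rate),
      n_populations = dplyr::n_distinct(.data$population_id),
      biome_group = names(sort(table(.data$biome_group), decreasing = TRUE))[1],
      .groups = "drop") %>%
    select("species_id", "realm", "taxon_group", "biome_group", "year",
           "rate", "n_populations") %>%
    arrange(.data$species_id, .data$year)
}

#' Overall (per-species) rate of change
#'
#' Collapses a species' annual trend to a single number: the arithmetic mean
#' of its annual rates over the years it has data. This is the quantity
#' summarised by taxon/realm/biome in the disaggregation figures.
#'
#' @param sp Output of [species_trends()].
#' @return Tibble `species_id`, `realm`, `taxon_group`, `biome_group`,
#'   `overall_rate`, `first_year`, `last_year`, `n_years`.
#' @export
species_overall_rates <- function(sp) {
  sp %>%
    group_by(.data$species_id, .data$realm, .data$taxon_group,
             .data$biome_group) %>%
    summarise(overall_rate = mean(.data$rate),
              first_year = min(.data$year),
              last_year = max(.data$year),
              n_years = n(), .groups = "drop")
}

#' Subset-level annual mean rates
#'
#' For each `(realm, taxon_group)` subset and year, the arithmetic mean of
#' the species annual rates across the species with data that year. Years
#' with no species are omitted.
#'
#' @param sp Output of [species_trends()].
#' @return Tibble `realm`, `taxon_group`, `year`, `rate`, `n_species`.
#' @export
subset_annual_rates <- function(sp) {
  sp %>%
    group_by(.data$realm, .data$taxon_group, .data$year) %>%
    summarise(rate = mean(.data$rate), n_species = n(), .groups = "drop") %>%
    arrange(.data$realm, .data$taxon_group, .data$year)
}

# Weighted global mean rate for each chain year, renormalizing the two-level
# weights each year over the subsets that have data. rate_mat is subsets x
# years (NA = no data); wt carries realm_total and species_count per subset
# row in the same order.
weighted_annual_rates <- function(rate_mat, wt_realm, wt_count, realms) {
  n_years <- ncol(rate_mat)
  d <- rep(NA_real_, n_years)
  for (j in seq_len(n_years)) {
    av <- !is.na(rate_mat[, j])
    if (!any(av)) next
    r_av <- realms[av]
    rt <- tapply(wt_realm[av], r_av, max)    # one total per realm
    w_realm <- rt / sum(rt)
    dj <- 0
    for (r in names(w_realm)) {
      idx <- which(av & realms == r)
      w_tax <- wt_count[idx] / sum(wt_count[idx])
      dj <- dj + w_realm[[r]] * sum(w_tax * rate_mat[idx, j])
    }
    d[j] <- dj
  }
  d
}

# Pivot subset rates to a subsets x years matrix aligned with `wt` rows.
subset_rate_matrix <- function(subset_rates, wt, years) {
  key <- paste(wt$realm, wt$taxon_group, sep = "\r")
  m <- matrix(NA_real_, nrow = nrow(wt), ncol = length(years),
              dimnames = list(key, years))
  i <- match(paste(subset_rates$realm, subset_rates$taxon_group, sep = "\r"),
             key)
  j <- match(subset_rates$year, years)
  keep <- !is.na(i) & !is.na(j)
  m[cbind(i[keep], j[keep])] <- subset_rates$rate[keep]
  m
}

#' Chain subset rates into a composite index
#'
#' The composite index starts at 1 in the baseline year and multiplies by
#' `10^d_t` each year, where `d_t` is the two-level diversity-weighted mean
#' of the subset annual rates. Weights are renormalized every year over the
#' subsets with data; a year in which no subset has data holds the index
#' flat. It is an error for the first chain step (baseline + 1) to have no
#' data: pick a baseline year inside the data span.
#'
#' @param subset_rates Output of [subset_annual_rates()].
#' @param weights Output of [compute_weights()].
#' @param baseline_year Index = 1 here (default 1970).
#' @param final_year Last chained year (default 2014).
#' @return Tibble `year`, `index`, `n_species` covering
#'   `baseline_year..final_year`.
#' @export
chain_index <- function(subset_rates, weights, baseline_year = 1970,
                        final_year = 2014) {
  stopifnot(final_year > baseline_year)
  chain_years <- seq(baseline_year + 1, final_year)
  m <- subset_rate_matrix(subset_rates, weights, chain_years)
  if (all(is.na(m[, 1]))) {
    abort(sprintf(paste0(
      "no subset has rate data in %d; choose a baseline year inside the ",
      "data span"), baseline_year + 1))
  }
  d <- weighted_annual_rates(m, weights$realm_weight, weights$species_count,
                             weights$realm)
  d[is.na(d)] <- 0
  idx <- cumprod(c(1, 10^d))
  n_sp <- subset_rates %>%
    group_by(.data$year) %>%
    summarise(n_species = sum(.data$n_species), .groups = "drop")
  tibble::tibble(year = as.integer(c(baseline_year, chain_years)),
                 index = idx) %>%
    left_join(n_sp, by = "year") %>%
    mutate(n_species = tidyr::replace_na(.data$n_species, 0L))
}

#' Bootstrap confidence bands for the composite index
#'
#' Resamples species with replacement within each `(realm, taxon_group)`
#' subset, rebuilds the subset mean rates and rechains the index `B` times;
#' the band is the per-year 2.5% and 97.5% percentile envelope. Subsets with
#' a single species contribute no resampling variation (their band collapses
#' for that subset; a warning is raised).
#'
#' @param sp Output of [species_trends()].
#' @param weights Output of [compute_weights()].
#' @param B Number of bootstrap replicates (default 1000, minimum 100).
#' @param seed Integer seed for the resampling generator.
#' @param baseline_year,final_year Chain span (defaults 1970, 2014).
#' @param probs Lower/upper band probabilities (default `c(0.025, 0.975)`).
#' @return Tibble `year`, `ci_low`, `ci_high`.
#' @export
bootstrap_index_ci <- function(sp, weights, B = 1000, seed = NULL,
                               baseline_year = 1970, final_year = 2014,
                               probs = c(0.025, 0.975)) {
  if (B < 100) abort("bootstrap_index_ci() needs B >= 100")
  if (!is.null(seed)) set.seed(seed)
  chain_years <- seq(baseline_year + 1, final_year)
  n_years <- length(chain_years)

  # Per subset: species x years rate matrix, NAs zeroed alongside an
  # observation-indicator matrix so resampled means are colSums ratios.
  subset_key <- paste(weights$realm, weights$taxon_group, sep = "\r")
  sp_key <- paste(sp$realm, sp$taxon_group, sep = "\r")
  per_subset <- lapply(subset_key, function(k) {
    s <- sp[sp_key == k & sp$year %in% chain_years, ]
    ids <- unique(s$species_id)
    r <- matrix(0, nrow = length(ids), ncol = n_years,
                dimnames = list(ids, chain_years))
    o <- matrix(0, nrow = length(ids), ncol = n_years)
    i <- match(s$species_id, ids)
    j <- match(s$year, chain_years)
    r[cbind(i, j)] <- s$rate
    o[cbind(i, j)] <- 1
    list(rate = r, obs = o, n = length(ids))
  })
  if (any(vapply(per_subset, function(x) x$n, 1L) == 1)) {
    warn("subset(s) with a single species: bootstrap band is degenerate there")
  }

  boot <- matrix(NA_real_, nrow = B, ncol = n_years + 1)
  for (b in seq_len(B)) {
    m <- matrix(NA_real_, nrow = length(per_subset), ncol = n_years)
    for (s in seq_along(per_subset)) {
      ps <- per_subset[[s]]
      if (ps$n == 0) next
      rows <- sample.int(ps$n, ps$n, replace = TRUE)
      num <- colSums(ps$rate[rows, , drop = FALSE])
      den <- colSums(ps$obs[rows, , drop = FALSE])
      m[s, ] <- ifelse(den > 0, num / den, NA_real_)
    }
    d <- weighted_annual_rates(m, weights$realm_weight, weights$species_count,
                               weights$realm)
    d[is.na(d)] <- 0
    boot[b, ] <- cumprod(c(1, 10^d))
  }
  qs <- apply(boot, 2, quantile, probs = probs, names = FALSE)
  tibble::tibble(year = as.integer(c(baseline_year, chain_years)),
                 ci_low = qs[1, ], ci_high = qs[2, ])
}

#' Build a Forest Specialist Index from a population table
#'
#' End-to-end wrapper: zero adjustment, per-population trend fitting, capped
#' annual log10 rates, species- and subset-level aggregation, diversity
#' weighting, chaining, and (optionally) species-level bootstrap confidence
#' bands.
#'
#' @param pop Population tibble (see [read_population_table()]).
#' @param richness Richness tibble for the weighting.
#' @param baseline_year,final_year Index span (defaults 1970, 2014).
#' @param cap Cap on annual log10 rates (default 1).
#' @param bootstrap Number of bootstrap replicates for the confidence band;
#'   0 skips the bootstrap.
#' @param seed Seed for the bootstrap resampler.
#' @return A `forest_index` object: list with `index` (tibble `year`,
#'   `index`, `ci_low`, `ci_high`, `n_species`), `weights`, `species_rates`,
#'   `population_rates` and `meta`. Supports [tidy()], [glance()],
#'   [autoplot()].
#' @export
forest_index <- function(pop, richness, baseline_year = 1970,
                         final_year = 2014, cap = 1, bootstrap = 1000,
                         seed = NULL) {
  pop <- validate_population_table(pop)
  adj <- adjust_zeros(pop)
  fitted <- fit_population_model(adj)
  rates <- annual_log_rates(fitted, cap = cap)
  sp <- species_trends(rates, pop)
  wt <- compute_weights(richness, distinct(sp, .data$realm, .data$taxon_group))
  idx <- chain_index(subset_annual_rates(sp), wt,
                     baseline_year = baseline_year, final_year = final_year)
  if (bootstrap > 0) {
    ci <- bootstrap_index_ci(sp, wt, B = bootstrap, seed = seed,
                             baseline_year = baseline_year,
                             final_year = final_year)
    idx <- left_join(idx, ci, by = "year")
  } else {
    idx$ci_low <- NA_real_
    idx$ci_high <- NA_real_
  }
  structure(
    list(index = select(idx, "year", "index", "ci_low", "ci_high",
                        "n_species"),
         weights = wt,
         species_rates = sp,
         population_rates = rates,
         meta = list(baseline_year = baseline_year, final_year = final_year,
                     cap = cap, bootstrap = bootstrap, seed = seed,
                     n_populations = dplyr::n_distinct(pop$population_id),
                     n_species = dplyr::n_distinct(sp$species_id))),
    class = "forest_index")
}

#' Constant annual decline implied by a final index value
#'
#' Inverts the chained index: if an index falls from 1 to `final_index` over
#' `n_steps` equal annual steps, each year it loses
#' `100 * (1 - final_index^(1/n_steps))` percent. An index of 0.47 over 44
#' steps implies a 1.7% annual decline.
#'
#' @param final_index Index value at the end of the span (baseline = 1).
#' @param n_steps Number of annual steps (default 44, i.e. 1970-2014).
#' @return Percent decline per year (positive for a declining index).
#' @export
implied_annual_decline <- function(final_index, n_steps = 44) {
  stopifnot(final_index > 0, n_steps >= 1)
  100 * (1 - final_index^(1 / n_steps))
}

#' @export
print.forest_index <- function(x, ...) {
  final <- tail(x$index, 1)
  cat(sprintf("<forest_index> %d-%d, %d populations, %d species, %d subsets\n",
              x$meta$baseline_year, x$meta$final_year, x$meta$n_populations,
              x$meta$n_species, nrow(x$weights)))
  if (is.na(final$ci_low)) {
    cat(sprintf("final index: %.3f\n", final$index))
  } else {
    cat(sprintf("final index: %.3f (95%% band %.3f-%.3f)\n", final$index,
                final$ci_low, final$ci_high))
  }
  invisible(x)
}
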