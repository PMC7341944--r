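#' Share of species declining each year
#'
#' For each year, the fraction of species (with a rate that year) whose
#' annual mean rate is strictly negative, strictly positive, or exactly
#' zero. "Declining" means rate < 0; exact zeros are counted in their own
#' bin, so the three shares always sum to one.
#'
#' @param sp Output of [species_trends()].
#' @param years Optional integer vector restricting the years reported.
#' @return Tibble `year`, `n_species`, `pct_declining`, `pct_increasing`,
#'   `pct_zero` (fractions in `[0, 1]`).
#' @export
percent_declining <- function(sp, years = NULL) {
  if (!is.null(years)) {
    sp <- filter(sp, .data$year %in% years)
    missing_years <- setdiff(years, unique(sp$year))
    if (length(missing_years) > 0) {
      warn(paste0("no species have rates in year(s): ",
                  paste(missing_years, collapse = ", ")))
    }
  }
  sp %>%
    group_by(.data$year) %>%
    summarise(n_species = n(),
              pct_declining = mean(.data$rate < 0),
              pct_increasing = mean(.data$rate > 0),
              pct_zero = mean(.data$rate == 0),
              .groups = "drop")
}

#' Group mean rates of change with standard errors
#'
#' Summarises per-species overall rates by taxonomic group, realm or biome
#' group: arithmetic mean, standard error (sample SD / sqrt(n)), and species
#' count. A group with a single species has no defined SE and reports `NA`.
#'
#' @param sp Output of [species_trends()].
#' @param grouping One of `"taxon_group"`, `"realm"`, `"biome_group"`.
#' @return Tibble `group`, `mean_rate`, `se`, `n_species`.
#' @export
group_mean_rates <- function(sp, grouping = c("taxon_group", "realm",
                                              "biome_group")) {
  grouping <- match.arg(grouping)
  species_overall_rates(sp) %>%
    group_by(group = .data[[grouping]]) %>%
    summarise(mean_rate = mean(.data$overall_rate),
              se = ifelse(n() > 1, sd(.data$overall_rate) / sqrt(n()),
                          NA_real_),
              n_species = n(), .groups = "drop")
}

#' Dataset turnover within a year window
#'
#' Composite indices move not only with population status but with species'
#' data series entering and leaving the dataset. For a window `[a, b]`, a
#' species is *leaving* if its last rate-year falls in the window and
#' *entering* if its first rate-year does; each is split by the sign of the
#' species' overall rate (declining < 0, increasing > 0, stable = 0). A
#' species whose data span the whole index is neither.
#'
#' @param sp Output of [species_trends()].
#' @param window Length-2 integer vector `c(year_a, year_b)`, inclusive.
#' @return Tibble `status` (entering/leaving), `trend` (declining/
#'   increasing/stable), `n_species`; all six combinations present.
#' @export
turnover <- function(sp, window) {
  stopifnot(length(window) == 2, window[1] <= window[2])
  rates <- species_overall_rates(sp) %>%
    mutate(trend = dplyr::case_when(.data$overall_rate < 0 ~ "declining",
                                    .data$overall_rate > 0 ~ "increasing",
                                    TRUE ~ "stable"))
  entering <- rates %>%
    filter(.data$first_year >= window[1], .data$first_year <= window[2]) %>%
    count(.data$trend, name = "n_species") %>%
    mutate(status = "entering")
  leaving <- rates %>%
    filter(.data$last_year >= window[1], .data$last_year <= window[2]) %>%
    count(.data$trend, name = "n_species") %>%
    mutate(status = "leaving")
  tidyr::expand_grid(status = c("entering", "leaving"),
                     trend = c("declining", "increasing", "stable")) %>%
    left_join(bind_rows(entering, leaving), by = c("status", "trend")) %>%
    mutate(n_species = tidyr::replace_na(.data$n_species, 0L))
}
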