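#' Windowed average rate of change per population
#'
#' Restricts each population's annual rates to the analysis window of the
#' tree-cover dataset in use (`"song"`: 1982-2016; `"hansen"`: 2000-2015, or
#' an explicit `c(first, last)`), then applies the retention rule: at least
#' 2 rate-years spread over at least a 5-year period (last - first >= 4).
#' The response is the arithmetic mean of the retained annual rates.
#'
#' @param rates Output of [annual_log_rates()].
#' @param pop Population tibble supplying location/genus/specialist tags.
#' @param window `"song"`, `"hansen"`, or integer `c(first, last)`.
#' @return Tibble `population_id`, `species_id`, `genus`, `taxon_group`,
#'   `biome_group`, `specialist`, `location_id`, `exploitation`,
#'   `first_year`, `last_year`, `n_years`, `avg_rate`; attribute
#'   `"excluded"` holds the ids that failed the rule.
#' @export
windowed_response <- function(rates, pop, window = "song") {
  window <- resolve_window(window)
  meta <- pop %>%
    distinct(.data$population_id, .data$species_id, .data$genus,
             .data$taxon_group, .data$biome_group, .data$specialist,
             .data$location_id, .data$exploitation)
  resp <- rates %>%
    filter(.data$year >= window[1], .data$year <= window[2]) %>%
    group_by(.data$population_id) %>%
    summarise(first_year = min(.data$year), last_year = max(.data$year),
              n_years = n(), avg_rate = mean(.data$rate), .groups = "drop")
  keep <- resp$n_years >= 2 & (resp$last_year - resp$first_year) >= 4
  excluded <- union(resp$population_id[!keep],
                    setdiff(unique(rates$population_id), resp$population_id))
  if (length(excluded) > 0) {
    inform(sprintf(
      "windowed_response: %d population(s) fail the 2-year/5-year-span rule in window %d-%d",
      length(excluded), window[1], window[2]))
  }
  out <- resp[keep, ] %>%
    dplyr::inner_join(meta, by = "population_id") %>%
    select("population_id", "species_id", "genus", "taxon_group",
           "biome_group", "specialist", "location_id", "exploitation",
           "first_year", "last_year", "n_years", "avg_rate")
  attr(out, "excluded") <- excluded
  out
}

resolve_window <- function(window) {
  if (is.character(window)) {
    switch(match.arg(window, c("song", "hansen")),
           song = c(1982L, 2016L),
           hansen = c(2000L, 2015L))
  } else {
    stopifnot(length(window) == 2, window[1] < window[2])
    as.integer(window)
  }
}

#' Smooth annual tree-cover series
#'
#' Inter-annual noise in satellite-derived cover series is smoothed with the
#' same contract as the population trends, but on the untransformed scale:
#' series with at least 6 annual values get a penalised spline (basis
#' dimension `ceiling(n/2)`, GCV), shorter series an OLS line. Fitted values
#' are clipped to `[0, buffer area]`.
#'
#' @param cov Covariate tibble (see [read_covariate_table()]); rows with
#'   missing `tree_cover_km2` are ignored.
#' @param buffer_radius_km Buffer radius for the clip bound (default 5).
#' @return Tibble `population_id`, `year`, `fitted_cover`, `method`.
#' @export
smooth_cover_series <- function(cov, buffer_radius_km = 5) {
  amax <- buffer_area_km2(buffer_radius_km)
  cov %>%
    filter(!is.na(.data$tree_cover_km2)) %>%
    group_by(.data$population_id) %>%
    filter(n() >= 2) %>%
    group_modify(~ fit_one_series(.x$year, .x$tree_cover_km2)) %>%
    ungroup() %>%
    mutate(fitted_cover = pmin(pmax(.data$fitted_log10, 0), amax)) %>%
    select("population_id", "year", "fitted_cover", "method")
}

#' Tree-cover covariates over each population's study period
#'
#' Pairs cover with the population data under a 1-year lag (cover in year
#' `t` is matched to population data in year `t + 1`), then summarises over
#' each population's windowed study period: mean fitted tree cover, mean
#' bare ground, the cover trend (OLS slope of fitted cover on year, km^2 per
#' year), static Hansen-style covariates (cover in 2000, summed loss over
#' the study period, proportional 2000-2010 change), and flags. Populations
#' whose cover is zero in every year are removed.
#'
#' @param smoothed Output of [smooth_cover_series()].
#' @param cov Raw covariate tibble (for bare ground, loss and statics).
#' @param responses Output of [windowed_response()] (supplies study periods).
#' @param lag Years of lag between cover and population data (default 1).
#' @return Tibble `population_id`, `mean_tree_cover`, `mean_bare_ground`,
#'   `cover_trend`, `cover_2000`, `cover_2010`, `loss_area`,
#'   `prop_change_2000_2010`; attribute `"zero_cover"` lists removed ids.
#' @export
derive_cover_covariates <- function(smoothed, cov, responses, lag = 1) {
  statics <- cov %>%
    group_by(.data$population_id) %>%
    summarise(cover_2000 = .data$cover_2000_km2[1],
              cover_2010 = .data$cover_2010_km2[1], .groups = "drop")

  one <- function(pid, first_year, last_year) {
    lag_years <- seq(first_year - lag, last_year - lag)
    fc <- smoothed %>%
      filter(.data$population_id == pid, .data$year %in% lag_years)
    raw <- cov %>% filter(.data$population_id == pid)
    bare <- raw %>% filter(.data$year %in% lag_years)
    loss <- raw %>%
      filter(.data$year >= first_year, .data$year <= last_year)
    trend <- if (nrow(fc) >= 2 && var(fc$year) > 0) {
      unname(coef(lm(fitted_cover ~ year, data = fc))[2])
    } else NA_real_
    tibble::tibble(
      population_id = pid,
      mean_tree_cover = if (nrow(fc) > 0) mean(fc$fitted_cover) else NA_real_,
      mean_bare_ground = if (any(!is.na(bare$bare_ground_km2))) {
        mean(bare$bare_ground_km2, na.rm = TRUE)
      } else NA_real_,
      cover_trend = trend,
      loss_area = if (any(!is.na(loss$loss_km2))) {
        sum(loss$loss_km2, na.rm = TRUE)
      } else NA_real_)
  }

  out <- purrr::pmap(
    list(responses$population_id, responses$first_year, responses$last_year),
    one) %>%
    bind_rows() %>%
    left_join(statics, by = "population_id") %>%
    mutate(prop_change_2000_2010 = ifelse(
      !is.na(.data$cover_2000) & .data$cover_2000 > 0,
      (.data$cover_2010 - .data$cover_2000) / .data$cover_2000, NA_real_))

  zero_ids <- cov %>%
    group_by(.data$population_id) %>%
    summarise(all_zero = all(is.na(.data$tree_cover_km2) |
                               .data$tree_cover_km2 == 0),
              any_obs = any(!is.na(.data$tree_cover_km2)),
              .groups = "drop") %>%
    filter(.data$all_zero, .data$any_obs) %>%
    pull(.data$population_id)
  zero_ids <- intersect(zero_ids, out$population_id)
  if (length(zero_ids) > 0) {
    inform(sprintf(
      "removing %d population(s) with zero tree cover in all years",
      length(zero_ids)))
    out <- filter(out, !.data$population_id %in% zero_ids)
  }
  attr(out, "zero_cover") <- zero_ids
  select(out, "population_id", "mean_tree_cover", "mean_bare_ground",
         "cover_trend", "cover_2000", "cover_2010", "loss_area",
         "prop_change_2000_2010")
}

#' Assemble the predictor matrix for the mixed models
#'
#' Joins responses with cover covariates and population-level pressures,
#' imputes missing body mass by genus, then family, then order mean (when a
#' `taxonomy` table is supplied), log10-transforms body mass, and z-scores
#' every continuous predictor over the populations present (mean 0, SD 1).
#' The exploitation flag stays binary and the response stays unscaled.
#'
#' @param responses Output of [windowed_response()].
#' @param cover_covs Output of [derive_cover_covariates()].
#' @param cov Raw covariate tibble (body mass, roads, HPD, travel time).
#' @param taxonomy Optional tibble `species_id`, `genus`, `family`,
#'   `order_name` enabling rank-walk body-mass imputation.
#' @return Tibble of one row per population: ids and tags, `avg_rate`, the
#'   binary `exploitation`, and z-scored `mean_tree_cover`,
#'   `mean_bare_ground`, `cover_trend`, `cover_2000`, `loss_area`,
#'   `prop_change_2000_2010`, `log_body_mass`, `road_density`, `hpd`,
#'   `travel_time`.
#' @export
prepare_predictors <- function(responses, cover_covs, cov, taxonomy = NULL) {
  statics <- cov %>%
    group_by(.data$population_id) %>%
    summarise(body_mass_g = .data$body_mass_g[1],
              road_density = .data$road_density_km[1],
              hpd = .data$hpd[1],
              travel_time = .data$travel_time_min[1], .groups = "drop")
  dat <- responses %>%
    dplyr::inner_join(cover_covs, by = "population_id") %>%
    left_join(statics, by = "population_id")

  # Body mass rank-walk imputation: genus -> family -> order means.
  if (!is.null(taxonomy) && any(is.na(dat$body_mass_g))) {
    dat <- left_join(dat, distinct(taxonomy, .data$species_id, .data$family,
                                   .data$order_name),
                     by = "species_id")
    for (rank in c("genus", "family", "order_name")) {
      rank_mean <- dat %>%
        filter(!is.na(.data$body_mass_g)) %>%
        group_by(.data[[rank]]) %>%
        summarise(.rank_mass = mean(.data$body_mass_g), .groups = "drop")
      dat <- left_join(dat, rank_mean, by = rank) %>%
        mutate(body_mass_g = dplyr::coalesce(.data$body_mass_g,
                                             .data$.rank_mass)) %>%
        select(-".rank_mass")
    }
    dat <- select(dat, -"family", -"order_name")
  }
  dat <- mutate(dat, log_body_mass = log10(.data$body_mass_g)) %>%
    select(-"body_mass_g")

  continuous <- c("mean_tree_cover", "mean_bare_ground", "cover_trend",
                  "cover_2000", "loss_area", "prop_change_2000_2010",
                  "log_body_mass", "road_density", "hpd", "travel_time")
  for (p in continuous) {
    x <- dat[[p]]
    if (sum(!is.na(x)) > 1 && sd(x, na.rm = TRUE) > 0) {
      dat[[p]] <- (x - mean(x, na.rm = TRUE)) / sd(x, na.rm = TRUE)
    }
  }
  dat
}

#' Univariate mixed-effects model comparison
#'
#' Fits `response ~ predictor + (1 | group)` by maximum likelihood and
#' compares its AIC with the null model `response ~ 1 + (1 | group)` on the
#' same (case-wise complete) rows. The predictor is deemed significant when
#' it lowers the AIC by at least 2 (`delta_aic = aic_null - aic_model >= 2`).
#' A singular fit (zero random-effect variance) is flagged but still
#' compared.
#'
#' @param data Model frame (see [prepare_predictors()]), or any data frame
#'   with the named columns.
#' @param predictor Name of the fixed-effect column.
#' @param response Name of the response column (default `"avg_rate"`).
#' @param group Name of the random-intercept grouping column (default
#'   `"location_id"`).
#' @return One-row tibble of class `lpi_model_comparison`: `predictor`,
#'   `n_populations`, `n_locations`, `coefficient`, `se`, `z`, `aic_model`,
#'   `aic_null`, `delta_aic`, `significant`, `singular`; the fitted models
#'   ride along in attributes `"model"` and `"null"`.
#' @export
fit_univariate_mixed <- function(data, predictor, response = "avg_rate",
                                 group = "location_id") {
  d <- data[stats::complete.cases(data[, c(response, predictor, group)]), ]
  if (dplyr::n_distinct(d[[group]]) < 2) {
    abort("fit_univariate_mixed() needs at least 2 grouping levels")
  }
  if (dplyr::n_distinct(d[[predictor]]) < 2) {
    abort(sprintf("predictor '%s' is constant over the complete cases",
                  predictor))
  }
  f_mod <- stats::as.formula(sprintf("%s ~ %s + (1 | %s)", response,
                                     predictor, group))
  f_null <- stats::as.formula(sprintf("%s ~ 1 + (1 | %s)", response, group))
  ctrl <- lme4::lmerControl(check.conv.singular = "ignore",
                            calc.derivs = FALSE)
  mod <- lme4::lmer(f_mod, data = d, REML = FALSE, control = ctrl)
  null <- lme4::lmer(f_null, data = d, REML = FALSE, control = ctrl)
  beta <- lme4::fixef(mod)[[2]]
  se <- sqrt(diag(as.matrix(vcov(mod))))[2]
  aic_model <- AIC(mod)
  aic_null <- AIC(null)
  out <- tibble::tibble(
    predictor = predictor,
    n_populations = nrow(d),
    n_locations = dplyr::n_distinct(d[[group]]),
    coefficient = beta,
    se = unname(se),
    z = beta / unname(se),
    aic_model = aic_model,
    aic_null = aic_null,
    delta_aic = aic_null - aic_model,
    significant = (aic_null - aic_model) >= 2,
    singular = lme4::isSingular(mod) || lme4::isSingular(null))
  attr(out, "model") <- mod
  attr(out, "null") <- null
  class(out) <- c("lpi_model_comparison", class(out))
  out
}

#' Fit the full univariate model battery
#'
#' One AIC comparison per predictor, with per-model case-wise deletion so a
#' missing value in one covariate never touches another predictor's fit.
#'
#' @inheritParams fit_univariate_mixed
#' @param predictors Character vector of predictor columns.
#' @return Tibble with one [fit_univariate_mixed()] row per predictor.
#' @export
fit_correlate_models <- function(data, predictors, response = "avg_rate",
                                 group = "location_id") {
  purrr::map(predictors, function(p) {
    row <- fit_univariate_mixed(data, p, response = response, group = group)
    tibble::as_tibble(row)
  }) %>%
    bind_rows()
}

#' Genus-level influence diagnostics
#'
#' Checks whether any single genus drives a predictor's apparent effect:
#' the predictor is fitted in a univariate mixed model with genus as the
#' random effect, then refitted once per genus with that genus excluded. A
#' genus is flagged when dropping it moves the fixed effect's z across the
#' +-1.96 threshold in either direction relative to the full fit: a
#' non-significant effect becoming significant, a significant one vanishing,
#' or a significant effect flipping sign (which crosses both thresholds).
#'
#' @param data Model frame with a `genus` column.
#' @param predictor Name of the fixed-effect column.
#' @param response Name of the response column (default `"avg_rate"`).
#' @return Tibble `genus`, `n_excluded`, `z_full`, `z_excluded`, `flagged`,
#'   one row per genus (processing order irrelevant).
#' @export
genus_influence <- function(data, predictor, response = "avg_rate") {
  d <- data[stats::complete.cases(data[, c(response, predictor, "genus")]), ]
  genera <- sort(unique(d$genus))
  if (length(genera) < 3) {
    abort("genus_influence() needs at least 3 genera")
  }
  full <- fit_univariate_mixed(d, predictor, response = response,
                               group = "genus")
  z_full <- full$z
  rows <- purrr::map(genera, function(g) {
    sub <- filter(d, .data$genus != g)
    if (dplyr::n_distinct(sub$genus) < 2 ||
        dplyr::n_distinct(sub[[predictor]]) < 2) {
      warn(sprintf("skipping genus '%s': exclusion leaves a degenerate fit", g))
      return(tibble::tibble(genus = g, n_excluded = sum(d$genus == g),
                            z_full = z_full, z_excluded = NA_real_,
                            flagged = NA))
    }
    fit <- fit_univariate_mixed(sub, predictor, response = response,
                                group = "genus")
    crossed <- (abs(z_full) >= 1.96) != (abs(fit$z) >= 1.96) ||
      (abs(z_full) >= 1.96 && abs(fit$z) >= 1.96 &&
         sign(z_full) != sign(fit$z))
    tibble::tibble(genus = g, n_excluded = sum(d$genus == g),
                   z_full = z_full, z_excluded = fit$z,
                   flagged = crossed)
  })
  bind_rows(rows)
}
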