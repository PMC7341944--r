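# Rates + matching metadata for a hand-built response fixture.
rates_fixture <- function(population_id, years, rate, location_id = "L1",
                          genus = "Genus1") {
  list(rates = tibble::tibble(population_id = population_id,
                              year = as.integer(years), rate = rate),
       pop = make_pop_table(population_id, range(years), c(1, 2),
                           location_id = location_id, genus = genus))
}

test_that("the 2-year/5-year-span rule filters windowed responses", {
  short <- rates_fixture("P1", 1990:1991, c(-0.1, -0.1))
  expect_message(resp <- windowed_response(short$rates, short$pop, "song"),
                 "fail")
  expect_equal(nrow(resp), 0)
  expect_equal(attr(resp, "excluded"), "P1")

  ok <- rates_fixture("P2", 2000:2010, rep(-0.05, 11))
  resp2 <- windowed_response(ok$rates, ok$pop, c(1982, 2016))
  expect_equal(resp2$avg_rate, -0.05)
  expect_equal(resp2$n_years, 11L)
})

test_that("rates outside the window are discarded before averaging", {
  # rate years 1981-1990; the song window keeps 1982-1990 only
  fix <- rates_fixture("P1", 1981:1990, c(10, rep(0, 9)) / 10)
  resp <- windowed_response(fix$rates, fix$pop, "song")
  expect_equal(resp$first_year, 1982L)
  expect_equal(resp$last_year, 1990L)
  expect_equal(resp$avg_rate, 0)   # the 1981 rate of 1.0 never enters
})

make_cover_table <- function(population_id, years, cover,
                             bare = 5, loss = 0, c2000 = 50, c2010 = 45,
                             mass = 1000, roads = 10, hpd = 100, tt = 200) {
  tibble::tibble(population_id = population_id, year = as.integer(years),
                 tree_cover_km2 = cover, bare_ground_km2 = bare,
                 loss_km2 = loss, cover_2000_km2 = c2000,
                 cover_2010_km2 = c2010, body_mass_g = mass,
                 road_density_km = roads, hpd = hpd, travel_time_min = tt)
}

test_that("cover smoothing reproduces noiseless series and damps noise", {
  years <- 1982:2016
  lin <- 60 - (60 - 25) / 34 * (years - 1982)
  sm <- smooth_cover_series(make_cover_table("P1", years, lin))
  expect_equal(sm$fitted_cover, lin, tolerance = 1e-4)

  const <- smooth_cover_series(make_cover_table("P1", years, rep(40, 35)))
  expect_equal(const$fitted_cover, rep(40, 35), tolerance = 1e-6)

  set.seed(5)
  spiky <- rep(50, 35) + runif(35, -20, 20)
  sm_spiky <- smooth_cover_series(make_cover_table("P1", years, spiky))
  expect_lt(var(sm_spiky$fitted_cover), var(spiky))
})

test_that("cover covariates recover slopes, sums and proportional change", {
  years <- 1989:2011
  cov <- make_cover_table("P1", years, 60 - 0.5 * (years - 1989))
  resp <- tibble::tibble(population_id = "P1", first_year = 1995L,
                         last_year = 2010L)
  cc <- derive_cover_covariates(smooth_cover_series(cov), cov, resp)
  expect_equal(cc$cover_trend, -0.5, tolerance = 1e-3)
  expect_equal(cc$prop_change_2000_2010, (45 - 50) / 50)
  # mean over the lagged window 1994-2009
  expect_equal(cc$mean_tree_cover, mean(60 - 0.5 * (1994:2009 - 1989)),
               tolerance = 1e-3)

  flat <- make_cover_table("P1", years, rep(44, length(years)),
                           c2000 = 44, c2010 = 44)
  cc_flat <- derive_cover_covariates(smooth_cover_series(flat), flat, resp)
  expect_equal(cc_flat$cover_trend, 0, tolerance = 1e-8)
  expect_equal(cc_flat$prop_change_2000_2010, 0)

  lossy <- make_cover_table("P1", 1999:2005, rep(30, 7),
                            loss = c(0, 0, 1.2, 0.8, 0, 0, 0))
  resp2 <- tibble::tibble(population_id = "P1", first_year = 2000L,
                          last_year = 2004L)
  cc2 <- derive_cover_covariates(smooth_cover_series(lossy), lossy, resp2)
  expect_equal(cc2$loss_area, 2)
})

test_that("populations with zero cover in every year are removed", {
  cov <- dplyr::bind_rows(
    make_cover_table("P1", 1990:2000, rep(0, 11)),
    make_cover_table("P2", 1990:2000, rep(30, 11)))
  resp <- tibble::tibble(population_id = c("P1", "P2"),
                         first_year = 1992L, last_year = 1999L)
  expect_message(
    cc <- derive_cover_covariates(smooth_cover_series(cov), cov, resp),
    "zero tree cover")
  expect_equal(cc$population_id, "P2")
  expect_equal(attr(cc, "zero_cover"), "P1")
})

test_that("body mass is imputed up the taxonomy and predictors z-scored", {
  resp <- tibble::tibble(
    population_id = c("P1", "P2", "P3"),
    species_id = c("SpA", "SpB", "SpC"),
    genus = c("G1", "G1", "G2"),
    taxon_group = "birds", biome_group = "temperate", specialist = TRUE,
    location_id = c("L1", "L2", "L3"),
    exploitation = c(TRUE, FALSE, FALSE),
    first_year = 2000L, last_year = 2010L, n_years = 11L,
    avg_rate = c(-0.02, 0.01, 0))
  cov <- dplyr::bind_rows(
    make_cover_table("P1", 1999:2010, rep(30, 12), mass = 1000),
    make_cover_table("P2", 1999:2010, rep(35, 12), mass = NA),
    make_cover_table("P3", 1999:2010, rep(40, 12), mass = 250))
  cc <- derive_cover_covariates(smooth_cover_series(cov), cov, resp)
  taxonomy <- tibble::tibble(species_id = c("SpA", "SpB", "SpC"),
                             family = "F1", order_name = "O1")
  dat <- prepare_predictors(resp, cc, cov, taxonomy = taxonomy)

  # SpB inherits its genus mean (only G1 donor: 1000 g); log10 then z-score
  logmass <- log10(c(1000, 1000, 250))
  expect_equal(dat$log_body_mass,
               (logmass - mean(logmass)) / sd(logmass))
  expect_equal(mean(dat$log_body_mass), 0, tolerance = 1e-12)
  expect_equal(sd(dat$log_body_mass), 1, tolerance = 1e-12)
  expect_type(dat$exploitation, "logical")   # binary predictor left alone
})

test_that("AIC comparison finds perfect signal and ignores pure noise", {
  set.seed(14)
  d <- simulate_mixed_responses(n = 300, n_locations = 60, delta = 0,
                                seed = 14)
  d$strong <- 2 * d$avg_rate + rnorm(nrow(d), 0, 0.005)
  perfect <- fit_univariate_mixed(d, "strong")
  expect_gt(perfect$delta_aic, 100)
  expect_true(perfect$significant)

  d$noise <- rnorm(nrow(d))
  null_fit <- fit_univariate_mixed(d, "noise")
  expect_lt(null_fit$delta_aic, 2)
  expect_false(null_fit$significant)
  expect_equal(null_fit$n_locations, dplyr::n_distinct(d$location_id))

  d$const <- 1
  expect_error(fit_univariate_mixed(d, "const"), "constant")
})

test_that("missing values in one predictor never perturb another's fit", {
  d <- simulate_mixed_responses(n = 200, n_locations = 40, seed = 77)
  set.seed(78)
  d$pred_a <- rnorm(200)
  d$pred_b <- rnorm(200)
  fit_b_before <- fit_correlate_models(d, "pred_b")
  d$pred_a[sample(200, 60)] <- NA
  fits <- fit_correlate_models(d, c("pred_a", "pred_b"))
  expect_equal(fits[fits$predictor == "pred_b", ]$aic_model,
               fit_b_before$aic_model, tolerance = 1e-12)
  expect_equal(fits[fits$predictor == "pred_a", ]$n_populations, 140L)
})

test_that("homogeneous data flag no genus as influential", {
  d <- simulate_mixed_responses(n = 240, n_locations = 48, delta = 0,
                                seed = 501)
  set.seed(502)
  d$x <- rnorm(nrow(d))
  gi <- genus_influence(d, "x")
  expect_equal(sum(gi$flagged, na.rm = TRUE), 0)
  expect_equal(nrow(gi), dplyr::n_distinct(d$genus))
})

test_that("a Gyps-like genus with anomalous declines is flagged", {
  # 24 clean genera carry a real negative effect of x; one genus crashed by
  # an unmodelled driver (poisoning) distorts the pooled slope enough to
  # mask it. Excluding that genus restores significance.
  set.seed(55)
  clean <- simulate_mixed_responses(n = 240, n_locations = 48, delta = 0,
                                    seed = 55)
  clean$x <- rnorm(nrow(clean))
  clean$avg_rate <- clean$avg_rate - 0.015 * clean$x
  gyps <- tibble::tibble(
    population_id = sprintf("PG%03d", 1:30),
    location_id = sprintf("LG%02d", rep(1:10, each = 3)),
    genus = "Gyps", exploitation = FALSE,
    x = rnorm(30),
    avg_rate = -0.5 + 0.3 * x + rnorm(30, 0, 0.05))
  d <- dplyr::bind_rows(clean, gyps)
  gi <- genus_influence(d, "x")
  expect_true(gi$flagged[gi$genus == "Gyps"])
  expect_equal(gi$genus[which(gi$flagged)], "Gyps")

  # flag set is invariant to row order
  gi2 <- genus_influence(d[sample(nrow(d)), ], "x")
  expect_equal(dplyr::arrange(gi2, genus)$flagged,
               dplyr::arrange(gi, genus)$flagged)
})
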