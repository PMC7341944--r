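full_richness <- function(counts = 100) {
  tidyr::expand_grid(realm = c("Nearctic", "Palaearctic", "Neotropical",
                               "Afrotropical", "IndoPacific"),
                     taxon_group = c("birds", "mammals", "herptiles")) |>
    dplyr::mutate(species_count = counts)
}

test_that("taxon weights within a realm are richness proportions", {
  rich <- tibble::tibble(realm = "Nearctic",
                         taxon_group = c("birds", "mammals", "herptiles"),
                         species_count = c(300, 100, 100))
  wt <- compute_weights(rich, rich[, c("realm", "taxon_group")])
  expect_equal(wt$taxon_weight[match(c("birds", "mammals", "herptiles"),
                                     wt$taxon_group)],
               c(0.6, 0.2, 0.2))
  expect_equal(sum(wt$weight), 1)
})

test_that("a missing subset renormalizes its realm over the available taxa", {
  # 5 realms x 3 taxa minus Palaearctic herptiles = 14 subsets
  subsets <- full_richness() |>
    dplyr::filter(!(realm == "Palaearctic" & taxon_group == "herptiles")) |>
    dplyr::select(realm, taxon_group)
  wt <- compute_weights(full_richness(), subsets)
  expect_equal(nrow(wt), 14)
  pal <- dplyr::filter(wt, realm == "Palaearctic")
  expect_setequal(pal$taxon_group, c("birds", "mammals"))
  expect_equal(sum(pal$taxon_weight), 1)
  expect_equal(pal$taxon_weight, c(0.5, 0.5))
  # weights sum to 1 at both levels
  expect_equal(sum(dplyr::distinct(wt, realm, realm_weight)$realm_weight), 1)
  expect_equal(sum(wt$weight), 1)
})

test_that("equal richness gives equal weights; absent richness is fatal", {
  wt <- compute_weights(full_richness(),
                        full_richness()[, c("realm", "taxon_group")])
  expect_true(all(abs(wt$weight - 1 / 15) < 1e-12))
  expect_error(
    compute_weights(dplyr::filter(full_richness(), realm != "Nearctic"),
                    full_richness()[, c("realm", "taxon_group")]),
    "Nearctic")
})

test_that("species trends average population rates year by year", {
  pop <- dplyr::bind_rows(
    make_pop_table("P1", 2000:2001, c(1, 1), species_id = "S1"),
    make_pop_table("P2", 2000:2001, c(1, 1), species_id = "S1"),
    make_pop_table("P3", 2000:2001, c(1, 1), species_id = "S1"))
  rates <- tibble::tibble(population_id = c("P1", "P2", "P3"),
                          year = 2001L, rate = c(-0.3, -0.3, 0.3))
  sp <- species_trends(rates, pop)
  expect_equal(nrow(sp), 1)
  expect_equal(sp$rate, -0.1)
  expect_equal(sp$n_populations, 3L)

  # opposite population trends cancel
  rates2 <- dplyr::mutate(rates, rate = c(-0.1, 0.1, 0))
  expect_equal(species_trends(rates2, pop)$rate, 0)

  # a single-population species passes through unchanged
  solo <- make_pop_table("P9", 2000:2002, c(1, 1, 1), species_id = "S9")
  rates9 <- tibble::tibble(population_id = "P9", year = 2001:2002,
                           rate = c(0.05, -0.02))
  expect_equal(species_trends(rates9, solo)$rate, c(0.05, -0.02))
})

test_that("subset rates average species and drop empty years", {
  sp <- dplyr::bind_rows(
    make_species_trends("S1", 2001:2002, c(-0.02, -0.02)),
    make_species_trends("S2", 2001, 0))   # S2's data end in 2001
  sub <- subset_annual_rates(sp)
  expect_equal(sub$rate[sub$year == 2001], -0.01)
  expect_equal(sub$n_species[sub$year == 2001], 2L)
  # after S2 leaves, the mean is over the remaining species only
  expect_equal(sub$rate[sub$year == 2002], -0.02)
  expect_equal(sub$n_species[sub$year == 2002], 1L)
})

test_that("chaining reproduces closed forms", {
  wt <- compute_weights(one_subset_richness(),
                        one_subset_richness()[, c("realm", "taxon_group")])

  # all-zero rates give a flat index
  flat <- tibble::tibble(realm = "Nearctic", taxon_group = "birds",
                         year = 1971:2014, rate = 0, n_species = 3L)
  expect_equal(chain_index(flat, wt)$index, rep(1, 45))

  # constant decline log10(0.983) for 44 steps lands on 0.983^44 ~ 0.470
  dec <- dplyr::mutate(flat, rate = log10(0.983))
  idx <- chain_index(dec, wt)
  expect_equal(tail(idx$index, 1), 0.983^44, tolerance = 1e-12)
  expect_equal(tail(idx$index, 1), 0.47, tolerance = 0.01)

  # two equally weighted subsets with opposite rates cancel exactly
  rich2 <- tibble::tibble(realm = "Nearctic",
                          taxon_group = c("birds", "mammals"),
                          species_count = c(50, 50))
  wt2 <- compute_weights(rich2, rich2[, c("realm", "taxon_group")])
  sub2 <- dplyr::bind_rows(
    tibble::tibble(realm = "Nearctic", taxon_group = "birds",
                   year = 1971:2014, rate = 0.1, n_species = 1L),
    tibble::tibble(realm = "Nearctic", taxon_group = "mammals",
                   year = 1971:2014, rate = -0.1, n_species = 1L))
  expect_equal(chain_index(sub2, wt2)$index, rep(1, 45), tolerance = 1e-12)
})

test_that("an empty baseline step is fatal with actionable advice", {
  wt <- compute_weights(one_subset_richness(),
                        one_subset_richness()[, c("realm", "taxon_group")])
  late <- tibble::tibble(realm = "Nearctic", taxon_group = "birds",
                         year = 1990:2014, rate = 0, n_species = 1L)
  expect_error(chain_index(late, wt), "baseline")
})

test_that("a single population chains to 10^cumsum of its capped rates", {
  set.seed(3)
  pop <- make_pop_table("P1", 1970:2014, exp(cumsum(rnorm(45, -0.01, 0.3))))
  rates <- annual_log_rates(fit_population_model(adjust_zeros(pop)))
  sp <- species_trends(rates, pop)
  wt <- compute_weights(one_subset_richness(),
                        one_subset_richness()[, c("realm", "taxon_group")])
  idx <- chain_index(subset_annual_rates(sp), wt)
  expect_equal(idx$index[-1], 10^cumsum(rates$rate), tolerance = 1e-9)
})

test_that("the index is invariant to input row order", {
  sc <- small_scenario()
  gp <- generate_populations(sc, seed = 21)
  rich <- generate_richness(sc)
  i1 <- forest_index(gp$populations, rich, bootstrap = 0)
  set.seed(99)
  shuffled <- gp$populations[sample(nrow(gp$populations)), ]
  i2 <- forest_index(shuffled, rich, bootstrap = 0)
  expect_equal(i1$index$index, i2$index$index, tolerance = 1e-12)
})

test_that("populations sharing one true rate recover lambda^(T-1)", {
  sc <- forest_scenario(n_populations = 150, n_species = 90,
                        mu_rate = log10(0.96), sigma_obs = 0.03,
                        p_missing = 0.1)
  gp <- generate_populations(sc, seed = 5)
  fi <- forest_index(gp$populations, generate_richness(sc), bootstrap = 0)
  expect_equal(tail(fi$index$index, 1), 0.96^44, tolerance = 0.1)
})

test_that("bootstrap bands are reproducible, ordered, and collapse for
           identical species", {
  sp <- dplyr::bind_rows(
    make_species_trends("S1", 1971:2014, rep(-0.005, 44)),
    make_species_trends("S2", 1971:2014, rep(-0.005, 44)),
    make_species_trends("S3", 1971:2014, rep(-0.005, 44)))
  wt <- compute_weights(one_subset_richness(),
                        one_subset_richness()[, c("realm", "taxon_group")])
  ci <- bootstrap_index_ci(sp, wt, B = 100, seed = 1)
  expect_equal(ci$ci_low, ci$ci_high)  # identical species: zero width

  sp2 <- dplyr::bind_rows(
    make_species_trends("S1", 1971:2014, rep(-0.01, 44)),
    make_species_trends("S2", 1971:2014, rep(0.002, 44)),
    make_species_trends("S3", 1971:2014, rep(-0.004, 44)))
  ci_a <- bootstrap_index_ci(sp2, wt, B = 150, seed = 42)
  ci_b <- bootstrap_index_ci(sp2, wt, B = 150, seed = 42)
  expect_identical(ci_a, ci_b)
  expect_true(all(ci_a$ci_low <= ci_a$ci_high))
})
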