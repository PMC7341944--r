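Package: forestlpi
Title: Forest Specialist Composite Abundance Index and Correlates of
    Population Change
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds Living-Planet-style composite abundance indices for
    forest specialist vertebrates from long-format population time series:
    per-population trend fitting (smoothing splines or linear regression on
    log10 abundance), capped annual log10 growth rates, species- and
    subset-level aggregation, diversity weighting proportional to forest
    species richness by biogeographic realm and taxonomic group, chained
    index construction with species-level bootstrap confidence bands, and
    disaggregation diagnostics (percent of species declining, group mean
    rates, dataset turnover). Also fits univariate mixed-effects models
    relating windowed average rates of population change to tree-cover
    trends and below-canopy pressures with an AIC decision rule and
    genus-level influence diagnostics, and ships a synthetic-data generator
    emulating Living Planet Database extracts with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    lme4,
    mgcv,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
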