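---
title: "Methods: composite index construction and correlates of forest vertebrate population change"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: composite index construction and correlates of forest vertebrate population change}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(forestlpi)
```

`forestlpi` builds a chained, diversity-weighted composite abundance index
for forest specialist vertebrates and fits mixed-effects models relating
population change to tree-cover change and below-canopy pressures. This
vignette records the modelling choices, their rationale, and what the
package's simulation-based validation does and does not demonstrate.

## Population trend model

Each monitored population contributes a time series of non-negative
abundance observations in arbitrary but internally consistent survey units
(counts, densities, nest counts, ...). Only ratios of abundance ever enter
the index, so the unit cancels; this is why rescaling a series by any
positive constant leaves all downstream results unchanged (a property the
test suite asserts).

Log₁₀ abundance is regressed on year and predicted at every integer year of
the observed span:

* **Spline path** (≥ 6 observations): `mgcv::gam` with a thin-plate basis of
  dimension ⌈n/2⌉ and smoothness chosen by generalized cross-validation.
  Tying the basis dimension to the number of observations keeps short
  series from overfitting while letting multi-decade series bend. If the
  smoother fails, the fit falls back to the linear path with a warning.
* **Linear path** (2–5 observations): ordinary least squares.

No prediction is made outside the observed span; the chaining step handles
series that start late or end early. On exactly log-linear data the two
paths agree to numerical tolerance, which the suite uses as an oracle
equivalence check.

**Zeros.** A series containing a zero cannot be logged, so when any
observation is zero, 1% of the mean of the non-zero observations is added
to *every* observation of that series before logging. Adding the constant
to all observations (not just the zeros) biases level, not trend, and the
index only uses trend. All-zero series carry no trend information and are
excluded with a diagnostic.

**Annual rates.** The chain element is
`d_t = fitted_log10(t) − fitted_log10(t−1)`, capped at |d_t| ≤ 1 (at most a
ten-fold change in one year). The cap guards the composite against single
anomalous series; it is configurable, and with the cap disabled the rates
telescope exactly to the fitted total log change of the span.

## Aggregation and weighting

Rates are averaged arithmetically: populations → species (within a
realm × taxon subset), species → subset. A species or subset contributes to
a year exactly when at least one member has a rate that year.

The aggregation hierarchy is five biogeographic realms (Nearctic,
Palaearctic, Neotropical, Afrotropical, IndoPacific) × three taxonomic
groups (birds, mammals, herptiles). Weights are proportional to forest
species richness at two levels: realms by their total forest species count,
and groups within a realm by their count, renormalized over the groups that
actually have time-series data in that realm (e.g. with no Palaearctic
herptile data, Palaearctic weight splits over birds and mammals, giving 14
populated subsets). Every chain year the weights are renormalized again
over the subsets with data *that year*, rather than carrying a silent last
value forward; a year in which no subset has data holds the index flat. The
suite checks that weights sum to one at every level and year via scenarios
whose index must stay exactly on a closed-form trajectory under staggered
coverage.

The index itself is `I_baseline = 1`, `I_t = I_{t−1} · 10^{d̄_t}` with
baseline 1970 and final year 2014 by default (both configurable). Starting
the chain requires data in the first step; the error message says to move
the baseline if not.

**Confidence bands** resample species with replacement within each subset
and rechain, B = 1000 by default, reporting per-year 2.5/97.5 percentile
envelopes. Species (not populations) are the resampling unit because
species are the exchangeable unit of the aggregation; percentile (rather
than bias-corrected) intervals were chosen for transparency and because
the interval is reported as a range around a ratio-scale index. A subset
with one species contributes no resampling variance — the band collapses
there and a warning is raised.

## Diagnostics

Composite indices move both with population status and with data turnover,
so three disaggregations accompany the index:

* **Percent declining**: share of species with annual rate < 0 per year.
  Exact zeros are counted in their own bin — "declining" is strictly
  negative — so declining + increasing + zero shares sum to one. The
  species level (not population level) is used, consistent with reporting
  "percentage of all species".
* **Group mean rates**: per-species overall rates (mean of a species'
  annual rates) summarised by taxon, realm or biome group with standard
  errors (sample SD / √n; undefined and reported `NA` for n = 1).
* **Turnover**: species whose data series first (enter) or last (leave)
  rate-year falls in a window, split by the sign of their overall rate.
  Summed over disjoint windows covering the span, every species enters and
  leaves exactly once.

## Correlates of population change

The response is a population's mean annual rate inside the analysis window
of the tree-cover dataset: 1982–2016 for the long-term fractional-cover
("song") analysis, 2000–2015 for the high-resolution ("hansen") analysis.
After windowing, populations must retain ≥ 2 rate-years spread over at
least a 5-year period (last − first ≥ 4); the rule is applied to fitted
rate-years because trend fitting precedes windowing in the pipeline.

Tree-cover series within each population's 5 km buffer are smoothed with
the same spline/linear contract as the populations (untransformed scale,
fitted values clipped to [0, π·5² km²]) and paired with population data
under a 1-year lag — cover in year t is matched to population data in year
t + 1, reflecting that habitat change precedes the population response.
Derived covariates: mean fitted cover and mean bare ground over the lagged
study period, the cover trend (OLS slope of fitted cover on year, km²/yr),
cover in 2000, summed annual loss over the study period (clipped to the
analysis window), and proportional 2000–2010 change (undefined and flagged
when cover in 2000 is zero). Populations with zero cover in every year are
removed.

Pressure covariates: a binary flag for exploitation as the primary threat;
body mass, log₁₀-transformed after rank-walk imputation (genus mean, then
family, then order); road length in the buffer; human population density;
travel time to the nearest city. Continuous predictors are z-scored over
the included populations so coefficients read as response change per SD;
the binary flag and the response are left unscaled.

Each predictor is tested alone in a random-intercept model
`avg_rate ~ predictor + (1 | location)` — locations, not populations, are
the independent units, since multiple populations are often monitored at
one site. Fits use maximum likelihood, not REML, because AIC comparisons
across models differing in fixed effects require ML. A predictor is deemed
significant when ΔAIC = AIC(null) − AIC(model) ≥ 2. Singular fits (zero
random-effect variance) are flagged but still compared. Deletion of
incomplete cases is per-model, so missingness in one covariate never
perturbs another's fit. Multivariate follow-up models are deliberately not
automated: the battery is univariate by design, and combining predictors
is left to the analyst once univariate evidence exists.

**Influence.** For each predictor, a companion model with genus as the
random effect is refitted once per genus with that genus excluded. A genus
is flagged when exclusion moves the fixed effect's z across ±1.96 in either
direction — a non-significant effect becoming significant, a significant
one vanishing, or a significant effect flipping sign (which crosses both
thresholds). The sign-flip clause matters: a genus crashing for reasons
outside the model (the *Gyps* vulture poisoning collapse is the canonical
case) can drag a pooled slope to the opposite significant sign, and a rule
watching only |z| would miss it.

## Synthetic data: what it emulates and what it does not

The generator produces the three input tables with known ground truth. Its
defaults are the reference conditions used throughout validation: 455
populations of 268 species spread over the 14 subsets, spans of 10–44 years
inside 1970–2014 with uniformly drawn start years, 20% of interior survey
years missing (endpoints always kept, preserving the span), a common true
annual multiplicative change of 0.983, and multiplicative lognormal
observation noise with σ = 0.05 on the natural-log scale. Under those
conditions the pipeline's mean final index over 10 seeded replicates lands
on 0.983⁴⁴ ≈ 0.47 — i.e. the 53% headline decline — and the analogous run
at 0.988 reproduces a 41% decline. Cover series are linear location-level
trends plus AR(1) noise (φ = 0.6, σ = 2 km²), clipped to the buffer area,
with losses derived as year-on-year cover decreases; noise-free settings
recover the injected slope exactly. Richness defaults are plausible forest
species counts (tropical realms richest, birds the largest class); their
absolute scale is irrelevant because only richness *proportions* enter the
weights.

Ground truth (true rate per population, true slope per location) is written
as sidecar tables, so recovery tests never reach into the generator's
internals.

What the generator does **not** emulate: temporal autocorrelation and
observation error correlated across populations, species-level trend
heterogeneity within subsets (available via `sigma_rate` but off by
default), non-stationary trends (recoveries, collapses), spatial structure
beyond shared locations, and the strong geographic sampling bias of real
monitoring data. Passing recovery tests therefore demonstrates that the
*estimator machinery* is unbiased and correctly plumbed under known
conditions — not that real-data indices are free of the turnover and
representation artefacts the diagnostics module exists to surface.

## Numerical choices and degenerate inputs

* log base 10 throughout; the cap default 1 (ten-fold annual change).
* Spline basis ⌈n/2⌉, GCV smoothing; smoother non-convergence falls back
  to OLS with a warning.
* Bootstrap: B ≥ 100 enforced, seeded generator, percentile bands.
* Populations with < 2 observation years, all-zero series, windowed
  responses failing the 2-year/5-year rule, and zero-cover populations are
  excluded, counted, and reported via attributes and log messages so that
  input = used + rejected reconciles at every stage.
* Constant predictors are a fatal error for their model only; groups of
  size one report `NA` standard errors; a genus whose exclusion leaves
  fewer than two genera is skipped with a warning.

## Problem sizes used in validation

The test suite runs the full pipeline at the reference size (455
populations, 10 replicates) for the headline recovery checks, and smaller
scenarios (40–150 populations) for structural and property checks; the
mixed-model power and size characterisation uses 200 replicates of n = 500
populations across 100 locations, where the ΔAIC ≥ 2 rule detects an
injected exploitation shift of −0.02 log₁₀ units/yr with high power while
false-alarming on a small minority of null replicates. These sizes were
chosen to keep Monte-Carlo error well below the tolerances being asserted.

## Known limitations

* The GAM family/basis and the exact smoothing behaviour of the original
  rlpi tooling are not public; the spline contract here is a declared
  choice, and small differences in fitted trajectories are expected at
  series edges.
* The index treats population rates as exchangeable within species, and
  species within subsets; no phylogenetic or spatial covariance is
  modelled.
* Windowed loss summation uses the population's study period clipped to
  the analysis window; annual loss outside the window is ignored even when
  the source dataset extends further.
* The correlates analysis is associational. Location random intercepts
  absorb shared site effects, but no causal ordering of tree-cover change
  and population change is identified.
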