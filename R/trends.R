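#' Adjust zero abundances before log-transformation
#'
#' Abundance series that touch zero cannot be logged directly. Following the
#' usual composite-index convention, if any observation in a population's
#' series equals zero, 1% of the mean of the non-zero observations is added
#' to *every* observation of that series; series without zeros pass through
#' unchanged. All-zero series carry no trend information and are dropped
#' with a message.
#'
#' @param pop Population tibble (see [read_population_table()]).
#' @return The same tibble with `abundance` adjusted and a new
#'   `zero_adjustment` column (0 for untouched series); attribute
#'   `"all_zero"` lists dropped population ids.
#' @export
adjust_zeros <- function(pop) {
  adj <- pop %>%
    group_by(.data$population_id) %>%
    mutate(zero_adjustment = if (any(.data$abundance == 0)) {
      if (all(.data$abundance == 0)) NA_real_
      else 0.01 * mean(.data$abundance[.data$abundance > 0])
    } else 0) %>%
    ungroup()
  all_zero <- unique(adj$population_id[is.na(adj$zero_adjustment)])
  if (length(all_zero) > 0) {
    inform(sprintf("dropping %d all-zero population(s)", length(all_zero)))
    adj <- filter(adj, !is.na(.data$zero_adjustment))
  }
  adj <- mutate(adj, abundance = .data$abundance + .data$zero_adjustment)
  attr(adj, "all_zero") <- all_zero
  adj
}

# Fit one population's log10 abundance on year and predict on every integer
# year of the observed span. Spline path (>= 6 observations): thin-plate
# smoother with basis dimension ceiling(n/2) and GCV smoothness selection;
# linear path (2-5 observations): ordinary least squares. No extrapolation
# beyond the observed span.
fit_one_series <- function(year, log10_abundance) {
  n <- length(year)
  grid <- seq(min(year), max(year))
  use_gam <- n >= 6
  fitted <- NULL
  method <- "linear"
  if (use_gam) {
    k <- max(3L, as.integer(ceiling(n / 2)))
    fit <- tryCatch(
      mgcv::gam(log10_abundance ~ s(year, k = k), method = "GCV.Cp"),
      error = function(e) NULL, warning = function(w) NULL)
    if (!is.null(fit)) {
      fitted <- as.numeric(predict(fit, newdata = data.frame(year = grid)))
      method <- "gam"
    }
  }
  if (is.null(fitted)) {
    if (use_gam && method == "linear") {
      warn("smoother failed to converge; falling back to linear fit")
    }
    fit <- lm(log10_abundance ~ year)
    fitted <- as.numeric(predict(fit, newdata = data.frame(year = grid)))
  }
  tibble::tibble(year = as.integer(grid), fitted_log10 = fitted,
                 method = method)
}

#' Fit annual trend models to population time series
#'
#' For each population, regresses log10 abundance on year and predicts a
#' fitted log10 abundance for every integer year between its first and last
#' observation. Populations with at least 6 observation years get a
#' penalised-spline smoother (basis dimension `ceiling(n/2)`, smoothness by
#' generalized cross-validation); populations with 2-5 years get an ordinary
#' least-squares line. A smoother that fails to converge falls back to the
#' linear path with a warning. Zeros must already be handled (see
#' [adjust_zeros()]).
#'
#' @param pop Population tibble with strictly positive `abundance`.
#' @return Tibble with columns `population_id`, `year`, `fitted_log10`,
#'   `method` (`"gam"` or `"linear"`), one row per population-year of the
#'   fitted span (no gaps).
#' @export
fit_population_model <- function(pop) {
  if (any(pop$abundance <= 0)) {
    abort("fit_population_model() needs positive abundances; run adjust_zeros() first")
  }
  pop %>%
    group_by(.data$population_id) %>%
    group_modify(~ fit_one_series(.x$year, log10(.x$abundance))) %>%
    ungroup()
}

#' Annual capped log10 growth rates
#'
#' The chain element of the composite index: for each population and year,
#' `d_t = fitted_log10(t) - fitted_log10(t - 1)`, clipped to `[-cap, cap]`.
#' The default cap of 1 limits any single annual step to a ten-fold change.
#'
#' @param fitted Output of [fit_population_model()].
#' @param cap Symmetric bound on `|d_t|` in log10 units (default 1).
#' @return Tibble `population_id`, `year`, `rate`; one row per year in
#'   `(first + 1)..last` of each population's fitted span. The cap is kept
#'   in the `"cap"` attribute.
#' @export
annual_log_rates <- function(fitted, cap = 1) {
  stopifnot(cap > 0)
  rates <- fitted %>%
    group_by(.data$population_id) %>%
    arrange(.data$year, .by_group = TRUE) %>%
    mutate(rate = .data$fitted_log10 - dplyr::lag(.data$fitted_log10)) %>%
    ungroup() %>%
    filter(!is.na(.data$rate)) %>%
    mutate(rate = pmin(pmax(.data$rate, -cap), cap)) %>%
    select("population_id", "year", "rate")
  attr(rates, "cap") <- cap
  rates
}
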