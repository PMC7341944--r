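#' Tidy a forest index
#'
#' @param x A `forest_index` object.
#' @param ... Unused.
#' @return Tibble `year`, `index`, `ci_low`, `ci_high`, `n_species`.
#' @export
tidy.forest_index <- function(x, ...) {
  x$index
}

#' One-row summary of a forest index
#'
#' @param x A `forest_index` object.
#' @param ... Unused.
#' @return Tibble with `baseline_year`, `final_year`, `final_index`,
#'   `pct_change` (100 * (final - 1), negative for decline), `ci_low`,
#'   `ci_high`, `n_populations`, `n_species`, `n_subsets`.
#' @export
glance.forest_index <- function(x, ...) {
  final <- tail(x$index, 1)
  tibble::tibble(
    baseline_year = x$meta$baseline_year,
    final_year = x$meta$final_year,
    final_index = final$index,
    pct_change = 100 * (final$index - 1),
    ci_low = final$ci_low,
    ci_high = final$ci_high,
    n_populations = x$meta$n_populations,
    n_species = x$meta$n_species,
    n_subsets = nrow(x$weights))
}

#' Tidy a mixed-model comparison
#'
#' @param x An `lpi_model_comparison` object.
#' @param ... Unused.
#' @return The comparison row as a plain tibble.
#' @export
tidy.lpi_model_comparison <- function(x, ...) {
  out <- x
  attr(out, "model") <- NULL
  attr(out, "null") <- NULL
  class(out) <- class(tibble::tibble())
  out
}

#' Plot a forest index with its confidence band
#'
#' @param object A `forest_index` object.
#' @param ... Unused.
#' @return A ggplot: index line with the bootstrap ribbon and the baseline
#'   at 1.
#' @export
autoplot.forest_index <- function(object, ...) {
  dat <- object$index
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$year, y = .data$index))
  if (!all(is.na(dat$ci_low))) {
    p <- p + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$ci_low, ymax = .data$ci_high),
      fill = "forestgreen", alpha = 0.25)
  }
  p +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_line(colour = "forestgreen", linewidth = 0.8) +
    ggplot2::labs(x = "Year",
                  y = sprintf("Index (%d = 1)", object$meta$baseline_year)) +
    ggplot2::theme_minimal()
}

#' Plot group mean rates of change with standard errors
#'
#' @param summary Output of [group_mean_rates()].
#' @return A ggplot: point estimate with +-1 SE error bars per group.
#' @export
plot_group_rates <- function(summary) {
  ggplot2::ggplot(summary,
                  ggplot2::aes(x = .data$group, y = .data$mean_rate)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$mean_rate - .data$se,
      ymax = .data$mean_rate + .data$se)) +
    ggplot2::labs(x = NULL, y = "Mean annual rate (log10 units / yr)") +
    ggplot2::theme_minimal()
}

#' Plot average population rates against tree-cover trend
#'
#' @param data Model frame from [prepare_predictors()].
#' @return A ggplot scatter of `avg_rate` on `cover_trend` coloured by
#'   taxonomic group.
#' @export
plot_rate_vs_cover <- function(data) {
  ggplot2::ggplot(data, ggplot2::aes(x = .data$cover_trend,
                                     y = .data$avg_rate,
                                     colour = .data$taxon_group)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(x = "Tree-cover trend (SD units)",
                  y = "Average rate of change (log10 units / yr)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
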