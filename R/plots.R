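#' Bar chart of lives saved by period of care and outcome
#'
#' Mirrors the conventional presentation of deterministic lives-saved
#' results: total impact in the report year stacked by the period in which
#' the contributing interventions are delivered.
#'
#' @param summary A `global_summary` from [aggregate_impacts()].
#' @return A ggplot object.
#' @export
plot_lives_saved <- function(summary) {
  stopifnot(inherits(summary, "global_summary"))
  df <- summary$period_shares[summary$period_shares$outcome != "overall", ]
  df$period <- factor(df$period, c("antenatal", "childbirth", "postnatal"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$outcome, y = .data$averted,
                                   fill = .data$period)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = sprintf("Deaths averted in %d", summary$year),
                  fill = "Period of care") +
    ggplot2::theme_minimal()
}

#' Boxplot of per-country percent declines in mortality rates
#'
#' Distribution across countries of the percent change in MMR, NMR and SBR
#' between the counterfactual and scale-up scenarios at endline.
#'
#' @param summary A `global_summary` from [aggregate_impacts()].
#' @return A ggplot object.
#' @export
plot_rate_declines <- function(summary) {
  stopifnot(inherits(summary, "global_summary"))
  ggplot2::ggplot(summary$country_declines,
                  ggplot2::aes(x = .data$rate, y = .data$decline)) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = NULL,
                  y = sprintf("%% decline, %d vs counterfactual",
                              summary$year)) +
    ggplot2::theme_minimal()
}
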