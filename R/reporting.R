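## Reporting module: global totals, period shares, percent declines and
## sensitivity ranges across quartile-bound runs.

#' Percent decline of a rate between baseline and endline
#'
#' `(baseline - endline) / baseline * 100`; negative when the endline
#' exceeds the baseline (reported as such, never clipped).
#'
#' @param baseline_rate,endline_rate Positive baseline rate and endline rate.
#' @return Percent decline (vectorized).
#' @export
percent_decline <- function(baseline_rate, endline_rate) {
  if (any(baseline_rate <= 0)) {
    stop("baseline rate must be positive", call. = FALSE)
  }
  (baseline_rate - endline_rate) / baseline_rate * 100
}

#' Aggregate country impact results into a global summary
#'
#' Sums lives saved across countries per outcome for the report year,
#' computes the share of impact delivered by antenatal, childbirth and
#' postnatal interventions (from the per-intervention attribution joined to
#' the registry's period labels; "overall" pools the three outcomes by raw
#' count), the aggregate percent decrease in deaths per outcome, and the
#' cross-country distribution (quartiles and mean) of percent declines in
#' MMR, NMR and SBR.
#'
#' @param results List of [country_impact()] results, one per country.
#' @param year Report year (default 2020, the endline).
#' @param registry Indicator registry (for period labels).
#' @return An object of class `global_summary`: list with `year`,
#'   `n_countries`, `totals` (outcome, lives_saved), `period_shares`
#'   (outcome incl. "overall", period, share), `aggregate_decline`
#'   (outcome, pct), `rate_declines` (rate, q25, median, q75, mean).
#' @export
aggregate_impacts <- function(results, year = 2020,
                              registry = indicator_registry()) {
  ids <- vapply(results, `[[`, "", "country_id")
  if (anyDuplicated(ids)) {
    stop("duplicate country in results: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  ls_all <- dplyr::bind_rows(lapply(results, function(r) {
    dplyr::mutate(r$lives_saved, country_id = r$country_id)
  }))
  ls_yr <- ls_all[ls_all$year == year, ]
  totals <- dplyr::summarise(dplyr::group_by(ls_yr, .data$outcome),
                             lives_saved = sum(.data$lives_saved),
                             .groups = "drop")

  att <- dplyr::bind_rows(lapply(results, `[[`, "attribution"))
  att <- att[att$year == year, ]
  iv <- registry_interventions(registry)
  att$period <- iv$period[match(att$intervention_id, iv$intervention_id)]
  by_outcome <- att |>
    dplyr::group_by(.data$outcome, .data$period) |>
    dplyr::summarise(averted = sum(.data$deaths_averted), .groups = "drop_last") |>
    dplyr::mutate(share = .data$averted / sum(.data$averted)) |>
    dplyr::ungroup()
  overall <- att |>
    dplyr::group_by(.data$period) |>
    dplyr::summarise(averted = sum(.data$deaths_averted), .groups = "drop") |>
    dplyr::mutate(outcome = "overall", share = .data$averted / sum(.data$averted))
  period_shares <- dplyr::bind_rows(by_outcome, overall)[
    c("outcome", "period", "averted", "share")]

  deaths_all <- dplyr::bind_rows(lapply(results, `[[`, "deaths"))
  agg <- deaths_all[deaths_all$year == year, ] |>
    dplyr::group_by(.data$scenario, .data$outcome) |>
    dplyr::summarise(deaths = sum(.data$deaths), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "scenario", values_from = "deaths")
  scen <- setdiff(names(agg), c("outcome", "counterfactual"))[1]
  aggregate_decline <- tibble::tibble(
    outcome = agg$outcome,
    pct = percent_decline(agg$counterfactual, agg[[scen]]))

  decl <- dplyr::bind_rows(lapply(results, function(r) {
    base <- r$rates[r$rates$scenario == "counterfactual" &
                      r$rates$year == year, ]
    end <- r$rates[r$rates$scenario != "counterfactual" &
                     r$rates$year == year, ]
    tibble::tibble(country_id = r$country_id,
                   rate = c("MMR", "NMR", "SBR"),
                   decline = percent_decline(
                     unlist(base[c("MMR", "NMR", "SBR")]),
                     unlist(end[c("MMR", "NMR", "SBR")])))
  }))
  rate_declines <- decl |>
    dplyr::group_by(.data$rate) |>
    dplyr::summarise(q25 = stats::quantile(.data$decline, 0.25, type = 7),
                     median = stats::median(.data$decline),
                     q75 = stats::quantile(.data$decline, 0.75, type = 7),
                     mean = mean(.data$decline), .groups = "drop")

  structure(list(year = year, n_countries = length(results), totals = totals,
                 period_shares = period_shares,
                 aggregate_decline = aggregate_decline,
                 rate_declines = rate_declines,
                 country_declines = decl),
            class = "global_summary")
}

#' @export
print.global_summary <- function(x, ...) {
  cat("<global_summary>", x$n_countries, "countries, year", x$year, "\n")
  for (i in seq_len(nrow(x$totals))) {
    cat(sprintf("  %s lives saved: %s\n", x$totals$outcome[i],
                format(round(x$totals$lives_saved[i]), big.mark = ",")))
  }
  cb <- x$period_shares[x$period_shares$outcome == "overall" &
                          x$period_shares$period == "childbirth", ]
  if (nrow(cb)) cat(sprintf("  childbirth share of impact: %.0f%%\n",
                            100 * cb$share))
  invisible(x)
}

#' Sensitivity range across quartile-bound runs
#'
#' Combines the lives-saved totals of the q25-, median- and q75-bound
#' pipeline runs into `(low, central, high)` triples per outcome. The
#' quartile bounds act on imputed *baselines*; because the scale-up target
#' (the utilization cap) is fixed, a lower baseline leaves more room for
#' improvement and yields *more* lives saved. The low impact bound is
#' therefore the q75-baseline run and the high bound the q25-baseline run.
#' Ordering is verified, not assumed: a crossed triple (possible through
#' cap-rule interactions) is flagged with a warning and reported as-is,
#' never silently reordered.
#'
#' @param runs Named list of `global_summary` objects with elements `q25`,
#'   `median`, `q75`.
#' @return Tibble `outcome`, `low`, `central`, `high`, `crossed`, plus a
#'   `formatted` column `"central (low-high)"`.
#' @export
sensitivity_range <- function(runs) {
  stopifnot(all(c("q25", "median", "q75") %in% names(runs)))
  get_tot <- function(run, nm) {
    stats::setNames(run$totals$lives_saved, run$totals$outcome)
  }
  lo <- get_tot(runs$q75)
  ce <- get_tot(runs$median)
  hi <- get_tot(runs$q25)
  oc <- names(ce)
  out <- tibble::tibble(outcome = oc, low = unname(lo[oc]),
                        central = unname(ce[oc]), high = unname(hi[oc]))
  out$crossed <- !(out$low <= out$central + 1e-9 &
                     out$central <= out$high + 1e-9)
  if (any(out$crossed)) {
    warning("crossed sensitivity bounds for: ",
            paste(out$outcome[out$crossed], collapse = ", "),
            " (possible cap-rule interaction)", call. = FALSE)
  }
  out$formatted <- format_range(out$central, out$low, out$high)
  out
}

#' Format a central estimate with its range
#'
#' Mirrors the conventional reporting shape `"central (low-high)"`, e.g.
#' `"86,000 (77,800-92,400)"`.
#'
#' @param central,low,high Numeric vectors.
#' @param digits Significant digits for rounding (default 3).
#' @return Character vector.
#' @export
format_range <- function(central, low, high, digits = 3) {
  f <- function(x) format(signif(x, digits), big.mark = ",",
                          scientific = FALSE, trim = TRUE)
  sprintf("%s (%s-%s)", f(central), f(low), f(high))
}

#' Render a human-readable text report
#'
#' @param ranges Tibble from [sensitivity_range()].
#' @param central Central-run `global_summary`.
#' @return Character vector of report lines.
#' @export
report_text <- function(ranges, central) {
  lines <- c(
    sprintf("Projected impact in %d across %d countries (central run, with",
            central$year, central$n_countries),
    "q25-q75 sensitivity bounds on imputed baselines):", "")
  lab <- c(maternal = "maternal lives saved",
           neonatal = "neonatal lives saved",
           stillbirth = "stillbirths prevented")
  for (i in seq_len(nrow(ranges))) {
    lines <- c(lines, sprintf("  %-26s %s",
                              lab[ranges$outcome[i]], ranges$formatted[i]))
  }
  lines <- c(lines, "", "Aggregate percent decrease in deaths:")
  ad <- central$aggregate_decline
  for (i in seq_len(nrow(ad))) {
    lines <- c(lines, sprintf("  %-12s %.1f%%", ad$outcome[i], ad$pct[i]))
  }
  lines <- c(lines, "", "Mean percent decline in rates across countries:")
  rd <- central$rate_declines
  for (i in seq_len(nrow(rd))) {
    lines <- c(lines, sprintf("  %-4s %.1f%% (cross-country IQR %.1f-%.1f)",
                              rd$rate[i], rd$mean[i], rd$q25[i], rd$q75[i]))
  }
  cb <- central$period_shares[central$period_shares$outcome == "overall", ]
  lines <- c(lines, "", "Share of impact by period of care (all outcomes pooled):")
  for (i in seq_len(nrow(cb))) {
    lines <- c(lines, sprintf("  %-12s %.1f%%", cb$period[i], 100 * cb$share[i]))
  }
  lines
}
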