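## Scenario module: quartile baselines across linked countries, proxy
## imputation for unlinked countries, and linear scale-up trajectories
## capped at country-specific utilization.

#' Sample quartiles of a set of coverage values
#'
#' Order-statistic quantiles with linear interpolation between order
#' statistics (the `type = 7` convention of [stats::quantile()]).
#'
#' @param values Non-empty numeric vector of proportions in \[0, 1\].
#' @return Named numeric vector `c(q25, median, q75)`.
#' @examples
#' sample_quantiles(c(0.1, 0.2, 0.3, 0.4, 0.5))  # 0.2, 0.3, 0.4
#' @export
sample_quantiles <- function(values) {
  if (length(values) == 0L) stop("values must be non-empty", call. = FALSE)
  chk_prop(values, "values")
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  c(q25 = q[1], median = q[2], q75 = q[3])
}

#' Assemble a complete baseline table with quantile-proxy imputation
#'
#' Linked countries keep their measured effective-coverage values. For every
#' intervention, the 25th/50th/75th percentiles across linked countries are
#' computed; countries without a linked estimate receive the quantile named
#' by `bound` as a proxy, with provenance recorded. Measured `NA` values in
#' linked countries (interventions not assessable under the survey type)
#' are filled the same way.
#'
#' @param linked An effective-coverage tibble (rows from
#'   [estimate_country_baseline()], possibly several countries).
#' @param unlinked_countries Character vector of country ids without a
#'   linked dataset.
#' @param bound Which quantile to impute: `"median"` (central), `"q25"`
#'   (lower sensitivity bound) or `"q75"` (upper bound).
#' @param registry Indicator registry.
#' @return An object of class `baseline_table`: a list with `baselines`
#'   (tibble `country_id`, `intervention_id`, `period`, `coverage`,
#'   `provenance`), `quantiles` (tibble `intervention_id`, `q25`, `median`,
#'   `q75`, `n_linked`) and `bound`.
#' @export
impute_baselines <- function(linked, unlinked_countries,
                             bound = c("median", "q25", "q75"),
                             registry = indicator_registry()) {
  bound <- match.arg(bound)
  linked <- tibble::as_tibble(linked)
  stopifnot(all(c("country_id", "intervention_id", "coverage") %in%
                  names(linked)))
  iv <- registry_interventions(registry)
  qs <- dplyr::group_by(linked[!is.na(linked$coverage), ],
                        .data$intervention_id)
  qs <- dplyr::summarise(
    qs,
    q25 = sample_quantiles(.data$coverage)[["q25"]],
    median = sample_quantiles(.data$coverage)[["median"]],
    q75 = sample_quantiles(.data$coverage)[["q75"]],
    n_linked = dplyr::n(), .groups = "drop")
  missing_iv <- setdiff(iv$intervention_id, qs$intervention_id)
  if (length(missing_iv)) {
    stop("no linked observation for intervention(s): ",
         paste(missing_iv, collapse = ", "), call. = FALSE)
  }
  proxy_val <- stats::setNames(qs[[bound]], qs$intervention_id)
  proxy_prov <- paste0(sub("^median$", "median", bound), "_proxy")

  filled_linked <- dplyr::mutate(
    linked,
    provenance = ifelse(is.na(.data$coverage), proxy_prov, .data$provenance),
    coverage = ifelse(is.na(.data$coverage),
                      unname(proxy_val[.data$intervention_id]),
                      .data$coverage))
  unlinked <- tidyr::expand_grid(country_id = unlinked_countries,
                                 intervention_id = iv$intervention_id)
  unlinked <- dplyr::mutate(
    unlinked,
    period = iv$period[match(.data$intervention_id, iv$intervention_id)],
    coverage = unname(proxy_val[.data$intervention_id]),
    provenance = proxy_prov)
  structure(list(baselines = dplyr::bind_rows(filled_linked, unlinked),
                 quantiles = qs, bound = bound),
            class = "baseline_table")
}

#' @export
print.baseline_table <- function(x, ...) {
  cat("<baseline_table>", dplyr::n_distinct(x$baselines$country_id),
      "countries x", nrow(x$quantiles), "interventions, bound =", x$bound, "\n")
  invisible(x)
}

#' Country-specific 2020 coverage target ("utilization cap")
#'
#' The target an intervention's coverage is raised to by 2020: the ANC4+
#' proportion for antenatal interventions and the facility-delivery
#' proportion for childbirth and postnatal interventions, taken from the
#' country's most recent household survey.
#'
#' @param intervention_id One of the registry's intervention ids.
#' @param profile A [utilization_profile()].
#' @param registry Indicator registry.
#' @return Target proportion in \[0, 1\].
#' @export
target_for <- function(intervention_id, profile,
                       registry = indicator_registry()) {
  stopifnot(inherits(profile, "utilization_profile"))
  def <- indicator_definition(intervention_id, registry)
  period_utilization(profile, def$period[1])
}

#' Linear scale-up trajectory from baseline to a capped target
#'
#' Annual coverage interpolated linearly from the baseline in the start year
#' to the target in the end year. When the target does not exceed the
#' baseline (a proxy baseline can exceed a low utilization cap), coverage is
#' held constant at the baseline: scale-up never lowers coverage.
#'
#' @param baseline,target Proportions in \[0, 1\].
#' @param start_year,end_year Calendar years, `end_year > start_year`.
#' @param scenario_label Label attached to the trajectory.
#' @return Tibble `year`, `coverage`, `scenario`.
#' @examples
#' build_trajectory(0.4, 0.6)  # 0.40 0.45 0.50 0.55 0.60
#' @export
build_trajectory <- function(baseline, target, start_year = 2016,
                             end_year = 2020, scenario_label = "scale_up") {
  chk_prop(baseline, "baseline"); chk_prop(target, "target")
  if (end_year <= start_year) {
    stop("end_year must exceed start_year", call. = FALSE)
  }
  years <- seq(start_year, end_year)
  cov <- if (target > baseline) {
    baseline + (target - baseline) * (years - start_year) /
      (end_year - start_year)
  } else {
    rep(baseline, length(years))
  }
  tibble::tibble(year = years, coverage = cov, scenario = scenario_label)
}

#' Counterfactual trajectory: coverage frozen at baseline
#'
#' @param baseline Proportion in \[0, 1\].
#' @param start_year,end_year Calendar years.
#' @return Tibble `year`, `coverage`, `scenario = "counterfactual"`.
#' @export
counterfactual_trajectory <- function(baseline, start_year = 2016,
                                      end_year = 2020) {
  chk_prop(baseline, "baseline")
  tibble::tibble(year = seq(start_year, end_year), coverage = baseline,
                 scenario = "counterfactual")
}

#' Build all coverage trajectories for a baseline table
#'
#' For every country and intervention, a counterfactual trajectory (constant
#' at baseline) and a scale-up trajectory reaching the country's utilization
#' cap in the end year.
#'
#' @param baseline_table A `baseline_table` from [impute_baselines()].
#' @param profiles Named list of [utilization_profile()] objects keyed by
#'   country id (must cover every country in the table).
#' @param registry Indicator registry.
#' @param start_year,end_year Calendar years of the projection.
#' @return Tibble `country_id`, `intervention_id`, `scenario`, `year`,
#'   `coverage`.
#' @export
build_country_trajectories <- function(baseline_table, profiles,
                                       registry = indicator_registry(),
                                       start_year = 2016, end_year = 2020) {
  stopifnot(inherits(baseline_table, "baseline_table"))
  bl <- baseline_table$baselines
  missing_p <- setdiff(unique(bl$country_id), names(profiles))
  if (length(missing_p)) {
    stop("no utilization profile for country(s): ",
         paste(missing_p, collapse = ", "), call. = FALSE)
  }
  ## vectorized over all (country, intervention) rows at once
  anc4 <- vapply(profiles, `[[`, 0.0, "anc4_plus")
  hfd <- vapply(profiles, `[[`, 0.0, "hfd")
  tgt <- ifelse(bl$period == "antenatal", anc4[bl$country_id],
                hfd[bl$country_id])
  years <- seq(start_year, end_year)
  k <- length(years)
  n <- nrow(bl)
  base_rep <- rep(bl$coverage, each = k)
  tgt_rep <- rep(tgt, each = k)
  frac <- rep((years - start_year) / (end_year - start_year), times = n)
  su_cov <- base_rep + pmax(tgt_rep - base_rep, 0) * frac
  shell <- tibble::tibble(
    country_id = rep(bl$country_id, each = k),
    intervention_id = rep(bl$intervention_id, each = k),
    year = rep(years, times = n))
  dplyr::bind_rows(
    dplyr::mutate(shell, scenario = "scale_up", coverage = su_cov),
    dplyr::mutate(shell, scenario = "counterfactual", coverage = base_rep)
  )[c("country_id", "intervention_id", "scenario", "year", "coverage")]
}
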