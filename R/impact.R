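## Deterministic cause-specific mortality engine. The residual-ratio
## construction: observed baseline deaths already reflect baseline coverage,
## so deaths under any coverage level c scale by residual(c) / residual(c0),
## where the residual multiplies (1 - efficacy * AF * coverage) across
## interventions acting on the cause. The multiplicative structure precludes
## double counting across interventions.

#' Residual mortality fraction for one cause
#'
#' The fraction of a cause's deaths remaining after the combined effect of
#' all interventions acting on it:
#' `prod_i (1 - efficacy_i * affected_fraction_i * coverage_i)`.
#'
#' @param cause_entries Efficacy rows (`intervention_id`, `efficacy`,
#'   `affected_fraction`) for one (outcome, cause).
#' @param coverage Named numeric vector of coverage proportions by
#'   intervention id; must cover every entry's intervention.
#' @return Residual fraction in (0, 1\]; 1 for an empty entry set.
#' @examples
#' residual(data.frame(intervention_id = "a", efficacy = 0.5,
#'                     affected_fraction = 1), c(a = 0.6))  # 0.7
#' @export
residual <- function(cause_entries, coverage) {
  if (NROW(cause_entries) == 0L) return(1.0)
  missing_iv <- setdiff(cause_entries$intervention_id, names(coverage))
  if (length(missing_iv)) {
    stop("no coverage value for intervention(s): ",
         paste(missing_iv, collapse = ", "), call. = FALSE)
  }
  cov <- coverage[cause_entries$intervention_id]
  chk_prop(cov, "coverage")
  prod(1 - cause_entries$efficacy * cause_entries$affected_fraction * cov)
}

coverage_matrix <- function(trajectories) {
  wide <- tidyr::pivot_wider(trajectories[c("intervention_id", "year",
                                            "coverage")],
                             names_from = "intervention_id",
                             values_from = "coverage")
  m <- as.matrix(wide[setdiff(names(wide), "year")])
  rownames(m) <- wide$year
  m
}

## named coverage vector for one row of a coverage matrix (a plain matrix
## subset drops names when there is a single intervention)
cov_row <- function(m, j) stats::setNames(m[j, ], colnames(m))

#' Project cause-specific deaths under a coverage scenario
#'
#' For each cause and year, deaths are the baseline envelope scaled by the
#' ratio of the residual at that year's coverage to the residual at baseline
#' coverage. Causes not acted on by any configured intervention are carried
#' through unchanged.
#'
#' @param trajectories Tibble `intervention_id`, `year`, `coverage` for one
#'   country and one scenario.
#' @param epi An [epi_profile()] giving the baseline (start-year) envelope.
#' @param config Efficacy matrix (see [default_efficacy_matrix()]).
#' @param baseline_coverage Named numeric vector of baseline coverage by
#'   intervention, consistent with the envelope.
#' @return Tibble `outcome`, `cause`, `year`, `deaths`.
#' @export
deaths_under <- function(trajectories, epi, config, baseline_coverage) {
  stopifnot(inherits(epi, "epi_profile"))
  validate_efficacy_matrix(config)
  covm <- coverage_matrix(trajectories)
  years <- as.numeric(rownames(covm))
  env <- epi$deaths
  deaths <- numeric(nrow(env) * length(years))
  for (k in seq_len(nrow(env))) {
    entries <- config[config$outcome == env$outcome[k] &
                        config$cause == env$cause[k], , drop = FALSE]
    if (nrow(entries) == 0L) {
      ratio <- rep(1.0, length(years))
    } else {
      r0 <- residual(entries, baseline_coverage)
      if (r0 <= 0) {
        stop("baseline residual is zero for ", env$outcome[k], "/",
             env$cause[k], ": full prevention at baseline contradicts a ",
             "positive observed envelope", call. = FALSE)
      }
      ratio <- vapply(seq_along(years), function(j) {
        residual(entries, cov_row(covm, j)) / r0
      }, 0.0)
    }
    deaths[(k - 1L) * length(years) + seq_along(years)] <-
      env$deaths[k] * ratio
  }
  tibble::tibble(outcome = rep(env$outcome, each = length(years)),
                 cause = rep(env$cause, each = length(years)),
                 year = rep(years, times = nrow(env)),
                 deaths = deaths)
}

#' Lives saved: counterfactual minus scenario deaths
#'
#' @param counterfactual_deaths,scenario_deaths Death tibbles from
#'   [deaths_under()] for the same country, envelope and config.
#' @return Tibble `outcome`, `year`, `lives_saved` (nonnegative under
#'   nondecreasing coverage).
#' @export
lives_saved <- function(counterfactual_deaths, scenario_deaths) {
  key <- c("outcome", "cause", "year")
  a <- dplyr::arrange(counterfactual_deaths, .data$outcome, .data$cause,
                      .data$year)
  b <- dplyr::arrange(scenario_deaths, .data$outcome, .data$cause, .data$year)
  if (!identical(a[key], b[key])) {
    stop("mismatched outcome/cause/year structure between scenarios",
         call. = FALSE)
  }
  d <- dplyr::mutate(a, lives_saved = .data$deaths - b$deaths)
  dplyr::summarise(dplyr::group_by(d, .data$outcome, .data$year),
                   lives_saved = sum(.data$lives_saved), .groups = "drop")
}

#' Allocate one cause's deaths averted across interventions
#'
#' The joint deaths averted (residual-ratio form) for one cause are
#' allocated proportionally to each intervention's single-intervention
#' impact: the deaths it would avert if only its own coverage changed. The
#' allocations sum exactly to the joint total; when no single-intervention
#' impact is positive, all allocations are zero.
#'
#' @param cause_entries Efficacy rows for one (outcome, cause).
#' @param coverage_0,coverage_t Named baseline and scenario coverage vectors.
#' @param cause_deaths_0 Baseline deaths from this cause.
#' @return Named numeric vector of deaths averted by intervention.
#' @export
attribute_by_intervention <- function(cause_entries, coverage_0, coverage_t,
                                      cause_deaths_0) {
  if (NROW(cause_entries) == 0L) return(stats::setNames(numeric(0), NULL))
  r0 <- residual(cause_entries, coverage_0)
  joint <- cause_deaths_0 * (1 - residual(cause_entries, coverage_t) / r0)
  ids <- cause_entries$intervention_id
  s <- vapply(ids, function(id) {
    cov_i <- coverage_0
    cov_i[id] <- coverage_t[id]
    cause_deaths_0 * (1 - residual(cause_entries, cov_i) / r0)
  }, 0.0)
  if (sum(s) <= 0) return(stats::setNames(rep(0, length(ids)), ids))
  stats::setNames(joint * s / sum(s), ids)
}

#' Standard mortality rates from an outcome death vector
#'
#' Maternal mortality ratio per 100,000 live births, neonatal mortality rate
#' per 1,000 live births, stillbirth rate per 1,000 total births
#' (live births plus stillbirths).
#'
#' @param deaths_by_outcome Named numeric vector with elements `maternal`,
#'   `neonatal`, `stillbirth`.
#' @param epi An [epi_profile()] supplying the denominators.
#' @return Named numeric vector `c(MMR, NMR, SBR)`.
#' @export
mortality_rates <- function(deaths_by_outcome, epi) {
  stopifnot(inherits(epi, "epi_profile"))
  if (epi$live_births <= 0 || epi$total_births <= 0) {
    stop("birth denominators must be positive", call. = FALSE)
  }
  c(MMR = unname(deaths_by_outcome["maternal"]) / epi$live_births * 1e5,
    NMR = unname(deaths_by_outcome["neonatal"]) / epi$live_births * 1e3,
    SBR = unname(deaths_by_outcome["stillbirth"]) / epi$total_births * 1e3)
}

#' Full impact computation for one country
#'
#' Runs the mortality engine for the counterfactual and scale-up scenarios,
#' computes lives saved, attributes them to individual interventions
#' (proportional allocation of the joint residual-ratio impact, summed over
#' causes) and derives MMR/NMR/SBR per scenario-year. Birth and death
#' envelopes are held constant over the projection.
#'
#' @param trajectories Tibble `intervention_id`, `scenario`, `year`,
#'   `coverage` for one country, containing a `"counterfactual"` and one
#'   scale-up scenario.
#' @param epi Baseline [epi_profile()].
#' @param config Efficacy matrix.
#' @param scenario_label Name of the scale-up scenario in `trajectories`.
#' @return An object of class `impact_result`: list with `country_id`,
#'   `deaths` (scenario x outcome x cause x year), `lives_saved`
#'   (outcome x year), `attribution` (intervention x outcome x year
#'   `deaths_averted`), `rates` (scenario x year MMR/NMR/SBR).
#' @export
country_impact <- function(trajectories, epi, config,
                           scenario_label = "scale_up") {
  stopifnot(inherits(epi, "epi_profile"))
  cf_traj <- trajectories[trajectories$scenario == "counterfactual", ]
  su_traj <- trajectories[trajectories$scenario == scenario_label, ]
  if (nrow(cf_traj) == 0L || nrow(su_traj) == 0L) {
    stop("trajectories must contain 'counterfactual' and '", scenario_label,
         "' scenarios", call. = FALSE)
  }
  start_year <- min(cf_traj$year)
  covm0 <- coverage_matrix(cf_traj); cov0 <- cov_row(covm0, as.character(start_year))
  cf <- deaths_under(cf_traj, epi, config, cov0)
  su <- deaths_under(su_traj, epi, config, cov0)
  ls <- lives_saved(cf, su)

  covm <- coverage_matrix(su_traj)
  years <- as.numeric(rownames(covm))
  env <- epi$deaths
  a_iv <- a_oc <- list(); a_yr <- a_val <- list()
  for (k in seq_len(nrow(env))) {
    entries <- config[config$outcome == env$outcome[k] &
                        config$cause == env$cause[k], , drop = FALSE]
    if (nrow(entries) == 0L) next
    for (j in seq_along(years)) {
      a <- attribute_by_intervention(entries, cov0, cov_row(covm, j),
                                     env$deaths[k])
      i <- length(a_iv) + 1L
      a_iv[[i]] <- names(a)
      a_oc[[i]] <- rep(env$outcome[k], length(a))
      a_yr[[i]] <- rep(years[j], length(a))
      a_val[[i]] <- unname(a)
    }
  }
  attribution <- if (length(a_iv)) {
    dplyr::summarise(
      dplyr::group_by(
        tibble::tibble(intervention_id = unlist(a_iv),
                       outcome = unlist(a_oc), year = unlist(a_yr),
                       deaths_averted = unlist(a_val)),
        .data$intervention_id, .data$outcome, .data$year),
      deaths_averted = sum(.data$deaths_averted), .groups = "drop")
  } else {
    tibble::tibble(intervention_id = character(), outcome = character(),
                   year = numeric(), deaths_averted = numeric())
  }

  deaths_all <- dplyr::bind_rows(
    dplyr::mutate(cf, scenario = "counterfactual"),
    dplyr::mutate(su, scenario = scenario_label))
  rates <- deaths_all |>
    dplyr::group_by(.data$scenario, .data$year, .data$outcome) |>
    dplyr::summarise(deaths = sum(.data$deaths), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "outcome", values_from = "deaths") |>
    dplyr::mutate(
      MMR = .data$maternal / epi$live_births * 1e5,
      NMR = .data$neonatal / epi$live_births * 1e3,
      SBR = .data$stillbirth / epi$total_births * 1e3) |>
    dplyr::select("scenario", "year", "MMR", "NMR", "SBR")

  structure(list(country_id = epi$country_id, deaths = deaths_all,
                 lives_saved = ls, attribution = attribution, rates = rates,
                 scenario_label = scenario_label),
            class = "impact_result")
}

#' @export
print.impact_result <- function(x, ...) {
  yr <- max(x$lives_saved$year)
  tot <- x$lives_saved[x$lives_saved$year == yr, ]
  cat("<impact_result>", x$country_id, "- lives saved in", yr, ":\n")
  for (i in seq_len(nrow(tot))) {
    cat(sprintf("  %s: %.1f\n", tot$outcome[i], tot$lives_saved[i]))
  }
  invisible(x)
}
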