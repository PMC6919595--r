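## Linking module: build readiness indicators from facility records and
## combine stratum readiness with utilization into effective coverage.

period_utilization <- function(profile, period) {
  switch(period,
         antenatal = profile$anc4_plus,
         childbirth = ,
         postnatal = profile$hfd,
         stop("unknown period: ", period, call. = FALSE))
}

#' Evaluate whether one facility is ready for an intervention
#'
#' Readiness is a strict conjunction: the facility must have every applicable
#' required component. Components flagged SPA-only are excluded from the
#' requirement set when the record comes from a SARA survey.
#'
#' @param record A single facility record: a named logical vector, or a
#'   one-row data frame with one column per component code.
#' @param definition One indicator definition (registry rows for one
#'   intervention, see [indicator_definition()]).
#' @param survey_type `"SPA"` or `"SARA"`.
#' @return `TRUE` if all applicable components are present; `NA` if the
#'   indicator has no applicable components under this survey type (the
#'   intervention cannot be assessed).
#' @examples
#' def <- indicator_definition("neonatal_resuscitation")
#' rec <- c(staff_trained_nn_resuscitation = FALSE, newborn_bag_mask = TRUE,
#'          impac_guidelines = TRUE)
#' evaluate_readiness(rec, def, "SPA")   # FALSE: staff training missing
#' evaluate_readiness(rec, def, "SARA")  # TRUE: SPA-only component exempt
#' @export
evaluate_readiness <- function(record, definition,
                               survey_type = c("SPA", "SARA")) {
  survey_type <- match.arg(survey_type)
  if (is.data.frame(record)) {
    stopifnot(nrow(record) == 1L)
    record <- unlist(record[setdiff(names(record),
                                    c("facility_id", "stratum", "weight"))])
  }
  comps <- applicable_components(definition, survey_type)
  if (length(comps) == 0L) return(NA)
  missing_c <- setdiff(comps, names(record))
  if (length(missing_c)) {
    stop("facility record is missing component(s): ",
         paste(missing_c, collapse = ", "), call. = FALSE)
  }
  vals <- as.logical(record[comps])
  if (anyNA(vals)) {
    stop("missing value for component(s): ",
         paste(comps[is.na(vals)], collapse = ", "), call. = FALSE)
  }
  all(vals)
}

#' Weighted facility readiness by stratum
#'
#' For each stratum present in the survey, the survey-weighted proportion of
#' facilities that are fully ready for the intervention (weights normalized
#' within stratum).
#'
#' @param survey A [facility_survey()] object.
#' @param definition One indicator definition.
#' @return Named numeric vector of readiness proportions by stratum, or
#'   `NULL` if the indicator cannot be assessed under the survey type.
#' @export
readiness_by_stratum <- function(survey, definition) {
  stopifnot(inherits(survey, "facility_survey"))
  rec <- survey$records
  comps <- applicable_components(definition, survey$survey_type)
  if (length(comps) == 0L) return(NULL)
  missing_c <- setdiff(comps, names(rec))
  if (length(missing_c)) {
    stop("facility survey is missing component column(s): ",
         paste(missing_c, collapse = ", "), call. = FALSE)
  }
  vals <- as.matrix(rec[comps])
  if (anyNA(vals)) {
    bad <- comps[colSums(is.na(vals)) > 0]
    stop("missing values in component(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  ready <- rowSums(!vals) == 0L
  strata <- unique(rec$stratum)
  out <- vapply(strata, function(s) {
    idx <- rec$stratum == s
    w <- rec$weight[idx]
    if (sum(w) <= 0) stop("stratum ", s, " has zero total weight", call. = FALSE)
    sum(w * ready[idx]) / sum(w)
  }, 0.0)
  names(out) <- strata
  out
}

#' Population-level effective coverage for one intervention
#'
#' Multiplies stratum readiness by the share of care contacts occurring in
#' each stratum, then by the utilization cap for the intervention's period:
#' `U * sum_s share_s * readiness_s`, where `U` is ANC4+ for antenatal
#' interventions and facility delivery (HFD) for childbirth and postnatal
#' interventions. The result can never exceed the utilization cap.
#'
#' @param readiness Named numeric vector of readiness proportions by stratum.
#' @param profile A [utilization_profile()].
#' @param period `"antenatal"`, `"childbirth"` or `"postnatal"`.
#' @return Effective coverage proportion in \[0, 1\].
#' @examples
#' prof <- utilization_profile("X", anc4_plus = 0.6, hfd = 1,
#'                             stratum_shares = c(hospital = 0.7,
#'                                                health_center = 0.3))
#' effective_coverage(c(hospital = 0.8, health_center = 0.5), prof,
#'                    "childbirth")  # 0.71
#' @export
effective_coverage <- function(readiness, profile,
                               period = c("antenatal", "childbirth",
                                          "postnatal")) {
  period <- match.arg(period)
  stopifnot(inherits(profile, "utilization_profile"))
  shares <- profile$stratum_shares
  uncovered <- names(shares)[shares > 0 & !names(shares) %in% names(readiness)]
  if (length(uncovered)) {
    stop("no readiness estimate for stratum(s) with nonzero share: ",
         paste(uncovered, collapse = ", "), call. = FALSE)
  }
  u <- period_utilization(profile, period)
  val <- u * sum(shares * readiness[names(shares)])
  chk_prop(val, "effective coverage", tol = 1e-12)
  min(1, max(0, val))
}

#' Check the facility/household survey link-validity rule
#'
#' A facility survey and a household survey may be linked only if their
#' fieldwork years are separated by two years or less. Multi-year household
#' fieldwork is represented by its fractional midpoint (2008-2009 -> 2008.5).
#'
#' @param facility_year,household_year Calendar years (fractional allowed).
#' @return `TRUE` iff `abs(facility_year - household_year) <= 2`.
#' @export
validate_link <- function(facility_year, household_year) {
  stopifnot(is.finite(facility_year), is.finite(household_year))
  abs(facility_year - household_year) <= 2
}

#' Estimate baseline effective coverage for one linked country
#'
#' Applies the full linking chain for every intervention in the registry:
#' facility readiness by stratum (strict component conjunction, SPA-only
#' exemptions under SARA), multiplied by the household survey's stratum
#' shares and utilization cap. Interventions whose indicator has no
#' applicable components under the survey type are reported with `NA`
#' coverage (flagged absent) rather than fabricated as fully ready.
#'
#' @param pair A [survey_pair()]; the link-validity rule must hold.
#' @param registry Indicator registry.
#' @return An effective-coverage tibble: `country_id`, `intervention_id`,
#'   `period`, `coverage` (proportion or `NA` when absent), `provenance`
#'   (`"linked"`).
#' @export
estimate_country_baseline <- function(pair, registry = indicator_registry()) {
  stopifnot(inherits(pair, "survey_pair"))
  fy <- pair$facility_survey$survey_year
  hy <- pair$household_survey$survey_year
  if (!validate_link(fy, hy)) {
    stop(sprintf(paste0("surveys cannot be linked: year gap %.1f exceeds ",
                        "2 years (facility %.1f, household %.1f)"),
                 abs(fy - hy), fy, hy), call. = FALSE)
  }
  iv <- registry_interventions(registry)
  cov <- vapply(iv$intervention_id, function(id) {
    def <- indicator_definition(id, registry)
    r <- readiness_by_stratum(pair$facility_survey, def)
    if (is.null(r)) return(NA_real_)
    effective_coverage(r, pair$household_survey, def$period[1])
  }, 0.0)
  tibble::tibble(country_id = pair$household_survey$country_id,
                 intervention_id = iv$intervention_id,
                 period = iv$period,
                 coverage = unname(cov),
                 provenance = "linked")
}

#' Ground-truth effective coverage implied by a synthetic country
#'
#' Closed-form target for parameter-recovery checks: for each intervention,
#' `U * sum_s share_s * readiness_prob[i, s]` with `U` the period's
#' utilization cap. Uses the ground-truth utilization, not the (possibly
#' noisy) emitted household survey.
#'
#' @param truth A [ground_truth()] object.
#' @param registry Indicator registry.
#' @return Tibble `intervention_id`, `period`, `coverage`.
#' @export
true_effective_coverage <- function(truth, registry = indicator_registry()) {
  stopifnot(inherits(truth, "ground_truth"))
  iv <- registry_interventions(registry)
  shares <- truth$stratum_shares
  cov <- vapply(seq_len(nrow(iv)), function(i) {
    u <- if (iv$period[i] == "antenatal") truth$anc4_plus else truth$hfd
    p <- truth$readiness_prob[iv$intervention_id[i], names(shares)]
    u * sum(shares * p)
  }, 0.0)
  tibble::tibble(intervention_id = iv$intervention_id, period = iv$period,
                 coverage = cov)
}
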