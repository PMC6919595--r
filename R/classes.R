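#' @importFrom rlang .data
NULL

#' Default facility strata
#'
#' Facility-type strata used throughout the package when none are supplied:
#' hospitals, health centers and clinics, mirroring the hospital/lower-level
#' distinction of facility-survey designs.
#' @return Character vector of stratum labels.
#' @export
default_strata <- function() c("hospital", "health_center", "clinic")

chk_prop <- function(x, what, tol = 0) {
  if (any(!is.finite(x)) || any(x < -tol) || any(x > 1 + tol)) {
    stop(what, " must lie in [0, 1]", call. = FALSE)
  }
  invisible(x)
}

#' Construct a ground-truth parameter set for one synthetic country
#'
#' The ground truth fixes every quantity the downstream pipeline estimates:
#' per-intervention, per-stratum readiness probabilities; utilization
#' (ANC4+ and facility delivery); shares of care contacts by facility
#' stratum; and the epidemiological envelope (births, stillbirths and
#' cause-specific maternal/neonatal death counts).
#'
#' @param country_id Identifier for the country.
#' @param readiness_prob Numeric matrix, interventions x strata, of
#'   probabilities that a facility is fully ready for each intervention.
#'   Rownames are intervention ids, colnames stratum labels.
#' @param anc4_plus Proportion of pregnant women attending 4+ antenatal visits.
#' @param hfd Proportion of births delivered in a health facility.
#' @param stratum_shares Named numeric vector of care-contact shares by
#'   stratum; must sum to 1.
#' @param live_births,stillbirths Annual counts (nonnegative integers).
#' @param deaths Named numeric vector of baseline annual deaths per outcome:
#'   `maternal`, `neonatal` (the stillbirth envelope is `stillbirths`).
#' @param cause_fractions Named list with elements `maternal`, `neonatal`,
#'   `stillbirth`, each a named numeric vector of cause fractions summing to 1.
#' @return An object of class `ground_truth`.
#' @export
ground_truth <- function(country_id, readiness_prob, anc4_plus, hfd,
                         stratum_shares, live_births, stillbirths,
                         deaths, cause_fractions) {
  stopifnot(is.matrix(readiness_prob), !is.null(rownames(readiness_prob)),
            !is.null(colnames(readiness_prob)))
  chk_prop(readiness_prob, "readiness_prob")
  chk_prop(anc4_plus, "anc4_plus"); chk_prop(hfd, "hfd")
  chk_prop(stratum_shares, "stratum_shares")
  if (abs(sum(stratum_shares) - 1) > 1e-9) {
    stop("stratum_shares must sum to 1", call. = FALSE)
  }
  counts <- c(live_births = live_births, stillbirths = stillbirths, deaths)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("births and death envelopes must be nonnegative integers", call. = FALSE)
  }
  stopifnot(all(c("maternal", "neonatal") %in% names(deaths)),
            all(c("maternal", "neonatal", "stillbirth") %in% names(cause_fractions)))
  for (oc in names(cause_fractions)) {
    cf <- cause_fractions[[oc]]
    chk_prop(cf, paste0("cause_fractions$", oc))
    if (abs(sum(cf) - 1) > 1e-9) {
      stop("cause fractions for ", oc, " must sum to 1", call. = FALSE)
    }
  }
  structure(
    list(country_id = country_id, readiness_prob = readiness_prob,
         anc4_plus = anc4_plus, hfd = hfd, stratum_shares = stratum_shares,
         live_births = as.double(live_births),
         stillbirths = as.double(stillbirths),
         deaths = deaths, cause_fractions = cause_fractions),
    class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("<ground_truth> country", x$country_id, "\n")
  cat("  interventions:", nrow(x$readiness_prob),
      " strata:", paste(colnames(x$readiness_prob), collapse = ", "), "\n")
  cat(sprintf("  ANC4+ %.2f, HFD %.2f; live births %s, stillbirths %s\n",
              x$anc4_plus, x$hfd, format(x$live_births, big.mark = ","),
              format(x$stillbirths, big.mark = ",")))
  invisible(x)
}

#' Construct a facility survey object
#'
#' @param records Tibble/data frame with columns `facility_id`, `stratum`,
#'   `weight` (positive survey weight) and one logical (or 0/1) column per
#'   assessed component code.
#' @param survey_type `"SPA"` or `"SARA"`.
#' @param survey_year Calendar year of fieldwork (fractional midpoints allowed).
#' @return An object of class `facility_survey`.
#' @export
facility_survey <- function(records, survey_type = c("SPA", "SARA"),
                            survey_year) {
  survey_type <- match.arg(survey_type)
  records <- tibble::as_tibble(records)
  need <- c("facility_id", "stratum", "weight")
  missing_cols <- setdiff(need, names(records))
  if (length(missing_cols)) {
    stop("facility records missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(records$weight)) || any(records$weight <= 0)) {
    stop("survey weights must be strictly positive", call. = FALSE)
  }
  comp_cols <- setdiff(names(records), need)
  for (cc in comp_cols) records[[cc]] <- as.logical(records[[cc]])
  if (!is.finite(survey_year) || survey_year < 2000 || survey_year > 2030) {
    stop("survey_year outside plausible range [2000, 2030]", call. = FALSE)
  }
  structure(list(records = records, survey_type = survey_type,
                 survey_year = as.double(survey_year)),
            class = "facility_survey")
}

#' @export
print.facility_survey <- function(x, ...) {
  cat("<facility_survey>", x$survey_type, x$survey_year, "-",
      nrow(x$records), "facilities,",
      length(setdiff(names(x$records), c("facility_id", "stratum", "weight"))),
      "components\n")
  invisible(x)
}

#' Construct a household utilization profile
#'
#' @param country_id Country identifier.
#' @param anc4_plus Proportion attending 4+ antenatal visits, in \[0, 1\].
#' @param hfd Proportion of births delivered in a facility, in \[0, 1\].
#' @param stratum_shares Named numeric vector of care-contact shares by
#'   facility stratum, summing to 1. Defaults to a single national stratum.
#' @param survey_year Calendar year (fractional midpoint for multi-year
#'   fieldwork, e.g. 2008.5 for 2008-2009).
#' @return An object of class `utilization_profile`.
#' @export
utilization_profile <- function(country_id, anc4_plus, hfd,
                                stratum_shares = c(national = 1),
                                survey_year = 2016) {
  chk_prop(anc4_plus, "anc4_plus"); chk_prop(hfd, "hfd")
  chk_prop(stratum_shares, "stratum_shares")
  if (abs(sum(stratum_shares) - 1) > 1e-9) {
    stop("stratum_shares must sum to 1", call. = FALSE)
  }
  if (!is.finite(survey_year) || survey_year < 2000 || survey_year > 2030) {
    stop("survey_year outside plausible range [2000, 2030]", call. = FALSE)
  }
  structure(list(country_id = country_id, anc4_plus = anc4_plus, hfd = hfd,
                 stratum_shares = stratum_shares,
                 survey_year = as.double(survey_year)),
            class = "utilization_profile")
}

#' @export
print.utilization_profile <- function(x, ...) {
  cat(sprintf("<utilization_profile> %s (%.1f): ANC4+ %.2f, HFD %.2f\n",
              x$country_id, x$survey_year, x$anc4_plus, x$hfd))
  invisible(x)
}

#' Construct an epidemiological profile for one country-year
#'
#' @param country_id Country identifier.
#' @param year Calendar year of the envelope.
#' @param live_births Annual live births.
#' @param stillbirths Annual stillbirths; total births are
#'   `live_births + stillbirths`.
#' @param deaths Tibble with columns `outcome` (`maternal`, `neonatal`,
#'   `stillbirth`), `cause` and `deaths` (annual count; stillbirth "deaths"
#'   are the stillbirths themselves split by cause).
#' @return An object of class `epi_profile`.
#' @export
epi_profile <- function(country_id, year, live_births, stillbirths, deaths) {
  deaths <- tibble::as_tibble(deaths)
  stopifnot(all(c("outcome", "cause", "deaths") %in% names(deaths)))
  if (any(deaths$deaths < 0) || live_births < 0 || stillbirths < 0) {
    stop("counts must be nonnegative", call. = FALSE)
  }
  if (anyDuplicated(deaths[c("outcome", "cause")])) {
    stop("duplicate outcome/cause rows in death envelope", call. = FALSE)
  }
  structure(list(country_id = country_id, year = year,
                 live_births = as.double(live_births),
                 stillbirths = as.double(stillbirths),
                 total_births = as.double(live_births + stillbirths),
                 deaths = deaths),
            class = "epi_profile")
}

#' @export
print.epi_profile <- function(x, ...) {
  tot <- stats::aggregate(deaths ~ outcome, data = x$deaths, FUN = sum)
  cat("<epi_profile>", x$country_id, x$year, "- live births",
      format(x$live_births, big.mark = ","), "\n")
  for (i in seq_len(nrow(tot))) {
    cat(sprintf("  %s deaths: %s\n", tot$outcome[i],
                format(round(tot$deaths[i]), big.mark = ",")))
  }
  invisible(x)
}

#' Pair a facility survey with a household survey
#'
#' A valid pair requires the two surveys' fieldwork years to lie within two
#' years of each other (see [validate_link()]).
#'
#' @param facility_survey A [facility_survey()] object.
#' @param household_survey A [utilization_profile()] object.
#' @return An object of class `survey_pair`.
#' @export
survey_pair <- function(facility_survey, household_survey) {
  stopifnot(inherits(facility_survey, "facility_survey"),
            inherits(household_survey, "utilization_profile"))
  structure(list(facility_survey = facility_survey,
                 household_survey = household_survey),
            class = "survey_pair")
}

#' @export
print.survey_pair <- function(x, ...) {
  cat(sprintf("<survey_pair> %s: %s %.1f / household %.1f (gap %.1f y)\n",
              x$household_survey$country_id, x$facility_survey$survey_type,
              x$facility_survey$survey_year, x$household_survey$survey_year,
              abs(x$facility_survey$survey_year - x$household_survey$survey_year)))
  invisible(x)
}
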