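## Synthetic survey and envelope generators. Every generator takes an explicit
## seed (no implicit global randomness) and is deterministic given its inputs.

clamp01 <- function(x) pmin(1, pmax(0, x))

req_seed <- function(seed) {
  if (missing(seed) || is.null(seed) || !is.finite(seed)) {
    stop("an explicit integer seed is required", call. = FALSE)
  }
  as.integer(seed)
}

## Largest-remainder allocation of n facilities to strata, at least one
## facility in every stratum with nonzero share.
allocate_strata <- function(n, shares) {
  shares <- shares / sum(shares)
  raw <- n * shares
  alloc <- floor(raw)
  rem <- n - sum(alloc)
  if (rem > 0) {
    ord <- order(raw - alloc, decreasing = TRUE)
    alloc[ord[seq_len(rem)]] <- alloc[ord[seq_len(rem)]] + 1L
  }
  short <- which(shares > 0 & alloc == 0)
  for (s in short) {
    donor <- which.max(alloc)
    if (alloc[donor] > 1L) { alloc[donor] <- alloc[donor] - 1L; alloc[s] <- 1L }
  }
  alloc
}

#' Generate a synthetic facility survey from ground truth
#'
#' Emulates an SPA/SARA component checklist. For each facility and each
#' intervention, the intervention's binding component is drawn Bernoulli with
#' the ground-truth readiness probability for the facility's stratum, and all
#' other components are present. The probability that a facility has every
#' required component therefore equals the ground-truth readiness exactly,
#' giving a closed-form target for parameter-recovery tests.
#'
#' SARA surveys do not record SPA-only components, so those columns are
#' omitted when `survey_type = "SARA"`.
#'
#' @param truth A [ground_truth()] object.
#' @param n_facilities Number of facility records to generate (>= 1).
#' @param survey_type `"SPA"` or `"SARA"`.
#' @param seed Integer seed (required).
#' @param survey_year Calendar year attached to the survey.
#' @param registry Indicator registry; defaults to [indicator_registry()].
#' @param weight_dist `"unit"` for weights of 1, or `"gamma"` for
#'   gamma-distributed weights with mean 1 (shape 5) to exercise weighted
#'   estimation.
#' @return A [facility_survey()] object.
#' @export
generate_facility_survey <- function(truth, n_facilities,
                                     survey_type = c("SPA", "SARA"), seed,
                                     survey_year = 2014,
                                     registry = indicator_registry(),
                                     weight_dist = c("unit", "gamma")) {
  survey_type <- match.arg(survey_type)
  weight_dist <- match.arg(weight_dist)
  seed <- req_seed(seed)
  stopifnot(inherits(truth, "ground_truth"), n_facilities >= 1)
  strata <- names(truth$stratum_shares)
  unknown <- setdiff(strata, colnames(truth$readiness_prob))
  if (length(unknown)) {
    stop("unknown stratum label(s) in ground truth: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  ivs <- registry_interventions(registry)$intervention_id
  missing_iv <- setdiff(ivs, rownames(truth$readiness_prob))
  if (length(missing_iv)) {
    stop("ground truth lacks readiness probabilities for: ",
         paste(missing_iv, collapse = ", "), call. = FALSE)
  }
  set.seed(seed)
  alloc <- allocate_strata(as.integer(n_facilities), truth$stratum_shares)
  stratum <- rep(strata, alloc)
  n <- length(stratum)
  weight <- if (weight_dist == "unit") rep(1, n) else stats::rgamma(n, 5, 5)
  comps <- registry_components(registry, survey_type)
  rec <- tibble::tibble(
    facility_id = sprintf("%s_f%04d", truth$country_id, seq_len(n)),
    stratum = stratum, weight = weight)
  for (cc in comps) rec[[cc]] <- rep(TRUE, n)
  binding <- registry[registry$binding, , drop = FALSE]
  for (i in seq_len(nrow(binding))) {
    comp <- binding$component[i]
    if (!comp %in% comps) next  # SPA-only binding component under SARA
    p <- truth$readiness_prob[binding$intervention_id[i], stratum]
    rec[[comp]] <- stats::runif(n) < p
  }
  facility_survey(rec, survey_type, survey_year)
}

#' Generate a synthetic household utilization survey from ground truth
#'
#' Reproduces the ground-truth ANC4+ and facility-delivery proportions,
#' optionally perturbed with truncated Gaussian sampling noise; stratum
#' shares are emitted exactly (renormalized).
#'
#' @param truth A [ground_truth()] object.
#' @param seed Integer seed (required).
#' @param noise_sd Standard deviation of the Gaussian noise added to the
#'   utilization proportions before truncation to \[0, 1\]. Default 0
#'   (exact reproduction).
#' @param survey_year Calendar year (fractional midpoint allowed).
#' @return A [utilization_profile()] object.
#' @export
generate_household_survey <- function(truth, seed, noise_sd = 0,
                                      survey_year = 2015) {
  seed <- req_seed(seed)
  stopifnot(inherits(truth, "ground_truth"), noise_sd >= 0)
  set.seed(seed)
  anc4 <- clamp01(truth$anc4_plus + stats::rnorm(1, 0, noise_sd))
  hfd <- clamp01(truth$hfd + stats::rnorm(1, 0, noise_sd))
  shares <- truth$stratum_shares / sum(truth$stratum_shares)
  utilization_profile(truth$country_id, anc4, hfd, shares, survey_year)
}

#' Build the epidemiological envelope implied by a ground truth
#'
#' Deterministic: splits the baseline maternal and neonatal death envelopes
#' and the stillbirth count across causes using the ground-truth cause
#' fractions.
#'
#' @param truth A [ground_truth()] object.
#' @param year Envelope year (default 2016, the baseline year).
#' @return An [epi_profile()] object.
#' @export
generate_epi_profile <- function(truth, year = 2016) {
  stopifnot(inherits(truth, "ground_truth"))
  env <- c(maternal = unname(truth$deaths["maternal"]),
           neonatal = unname(truth$deaths["neonatal"]),
           stillbirth = unname(truth$stillbirths))
  deaths <- dplyr::bind_rows(lapply(names(env), function(oc) {
    cf <- truth$cause_fractions[[oc]]
    tibble::tibble(outcome = oc, cause = names(cf),
                   deaths = unname(env[oc] * cf))
  }))
  epi_profile(truth$country_id, year, truth$live_births, truth$stillbirths,
              deaths)
}

## Typical cause-of-death profiles used as Dirichlet centres when drawing
## random ground truths (illustrative, not country estimates).
default_cause_profile <- function() {
  list(
    maternal = c(haemorrhage = 0.27, hypertensive_disorders = 0.14,
                 sepsis = 0.11, obstructed_labour = 0.09,
                 other_maternal = 0.39),
    neonatal = c(prematurity = 0.35, intrapartum = 0.24,
                 sepsis_pneumonia = 0.16, tetanus = 0.02, congenital = 0.11,
                 other_neonatal = 0.12),
    stillbirth = c(antepartum_stillbirth = 0.55, intrapartum_stillbirth = 0.45)
  )
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha)
  g / sum(g)
}

## Draw one random ground truth from the current RNG stream (internal; the
## public entry point is generate_country_set, which seeds the stream).
random_ground_truth <- function(country_id, registry = indicator_registry(),
                                strata = default_strata()) {
  ivs <- registry_interventions(registry)$intervention_id
  base <- stats::rbeta(length(ivs), 2, 2)
  mult <- seq(1, 0.65, length.out = length(strata))
  p <- outer(base, mult)
  p[p > 1] <- 1; p[p < 0] <- 0
  dimnames(p) <- list(ivs, strata)
  shares <- rdirichlet1(seq(5, 2, length.out = length(strata)))
  names(shares) <- strata
  anc4 <- stats::rbeta(1, 3, 2)       # centred on the observed 60% average
  hfd <- stats::rbeta(1, 3.3, 1.7)    # centred on the observed 66% average
  lb <- round(stats::runif(1, 5e4, 3e6))
  nmr <- stats::runif(1, 0.020, 0.040)
  mmr <- stats::runif(1, 150, 800) / 1e5
  sbr <- stats::runif(1, 0.012, 0.030)
  sb <- round(sbr * lb / (1 - sbr))
  prof <- default_cause_profile()
  cf <- lapply(prof, function(w) {
    x <- rdirichlet1(100 * w); names(x) <- names(w); x
  })
  ground_truth(country_id, p, anc4, hfd, shares,
               live_births = lb, stillbirths = sb,
               deaths = c(maternal = round(mmr * lb), neonatal = round(nmr * lb)),
               cause_fractions = cf)
}

#' Generate a multi-country synthetic study set
#'
#' Produces `n_linked` countries carrying both a facility survey and a
#' household survey whose fieldwork years differ by at most two years
#' (a valid link), plus `n_unlinked` countries carrying only household
#' utilization and epidemiological envelopes, mirroring a study design in
#' which most countries lack a usable facility-household survey pair.
#'
#' @param n_linked Number of countries with a linked survey pair (>= 1).
#' @param n_unlinked Number of countries without a facility survey.
#' @param seed Integer seed (required); the only source of randomness.
#' @param n_facilities Facilities per linked country's facility survey.
#' @param registry Indicator registry.
#' @param strata Stratum labels.
#' @param noise_sd Household-survey sampling noise (see
#'   [generate_household_survey()]).
#' @param weight_dist Facility weight scheme (see
#'   [generate_facility_survey()]).
#' @return A list of length `n_linked + n_unlinked`; each element is a list
#'   with `truth` ([ground_truth()]), `utilization`
#'   ([utilization_profile()]), `epi` ([epi_profile()]), `linked` (logical)
#'   and, for linked countries, `pair` (a [survey_pair()]).
#' @examples
#' set1 <- generate_country_set(2, 3, seed = 7, n_facilities = 40)
#' sum(vapply(set1, `[[`, NA, "linked"))
#' @export
generate_country_set <- function(n_linked, n_unlinked, seed,
                                 n_facilities = 200,
                                 registry = indicator_registry(),
                                 strata = default_strata(),
                                 noise_sd = 0,
                                 weight_dist = c("unit", "gamma")) {
  weight_dist <- match.arg(weight_dist)
  seed <- req_seed(seed)
  if (n_linked + n_unlinked < 1) {
    stop("at least one country is required", call. = FALSE)
  }
  if (n_linked < 1) {
    stop("at least one linked country is required (baselines for unlinked ",
         "countries are imputed from linked ones)", call. = FALSE)
  }
  set.seed(seed)
  n_tot <- n_linked + n_unlinked
  linked <- c(rep(TRUE, n_linked), rep(FALSE, n_unlinked))
  out <- vector("list", n_tot)
  for (i in seq_len(n_tot)) {
    cid <- sprintf("C%03d", i)
    truth <- random_ground_truth(cid, registry, strata)
    child <- sample.int(2147483646L, 3L)
    if (linked[i]) {
      stype <- sample(c("SPA", "SARA"), 1L)
      fyear <- sample(2007:2016, 1L)
      hyear <- fyear + sample(seq(-2, 2, by = 0.5), 1L)
      hyear <- min(max(hyear, 2000), 2030)
      fs <- generate_facility_survey(truth, n_facilities, stype,
                                     seed = child[1], survey_year = fyear,
                                     registry = registry,
                                     weight_dist = weight_dist)
      hh <- generate_household_survey(truth, seed = child[2],
                                      noise_sd = noise_sd,
                                      survey_year = hyear)
      out[[i]] <- list(truth = truth, utilization = hh,
                       epi = generate_epi_profile(truth),
                       linked = TRUE, pair = survey_pair(fs, hh))
    } else {
      hh <- generate_household_survey(truth, seed = child[2],
                                      noise_sd = noise_sd,
                                      survey_year = sample(2010:2016, 1L))
      out[[i]] <- list(truth = truth, utilization = hh,
                       epi = generate_epi_profile(truth),
                       linked = FALSE, pair = NULL)
    }
  }
  names(out) <- vapply(out, function(x) x$truth$country_id, "")
  out
}
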