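test_that("readiness is a strict conjunction over applicable components", {
  reg <- indicator_registry()
  full <- all_present_record(reg)
  for (id in registry_interventions(reg)$intervention_id) {
    def <- indicator_definition(id, reg)
    expect_true(evaluate_readiness(full, def, "SPA"), label = id)
    # knock out each required component in turn
    for (cc in def$component) {
      rec <- full
      rec[cc] <- FALSE
      expect_false(evaluate_readiness(rec, def, "SPA"),
                   label = paste(id, "missing", cc))
    }
  }
})

test_that("missing IMPAC guidelines fail neonatal resuscitation readiness", {
  rec <- all_present_record()
  rec["impac_guidelines"] <- FALSE
  def <- indicator_definition("neonatal_resuscitation")
  expect_false(evaluate_readiness(rec, def, "SPA"))
})

test_that("SPA-only components are exempt under SARA", {
  rec <- all_present_record()
  rec["staff_trained_nn_resuscitation"] <- FALSE
  def <- indicator_definition("neonatal_resuscitation")
  expect_false(evaluate_readiness(rec, def, "SPA"))
  expect_true(evaluate_readiness(rec, def, "SARA"))
  rec2 <- all_present_record()
  rec2["staff_trained_amtsl"] <- FALSE
  expect_true(evaluate_readiness(rec2, indicator_definition("amtsl"), "SARA"))
})

test_that("missing component values are reported by name", {
  rec <- all_present_record()
  rec <- rec[setdiff(names(rec), "newborn_bag_mask")]
  def <- indicator_definition("neonatal_resuscitation")
  expect_error(evaluate_readiness(rec, def, "SPA"), "newborn_bag_mask")
})

test_that("weighted stratum readiness matches direct computation", {
  def <- indicator_definition("antibiotics_pprom")
  mk <- function(az, w, stratum = "hospital") {
    tibble::tibble(facility_id = paste0("f", seq_along(az)),
                   stratum = stratum, weight = w,
                   azithromycin = az, impac_guidelines = TRUE)
  }
  # 4 ready of 5 equal-weight hospitals
  sv <- facility_survey(mk(c(TRUE, TRUE, TRUE, TRUE, FALSE), rep(1, 5)),
                        "SPA", 2014)
  expect_equal(readiness_by_stratum(sv, def)[["hospital"]], 0.8)
  # weights (3, 1) with ready flags (TRUE, FALSE)
  sv2 <- facility_survey(mk(c(TRUE, FALSE), c(3, 1)), "SPA", 2014)
  expect_equal(readiness_by_stratum(sv2, def)[["hospital"]], 0.75)
  # all ready -> 1 in every stratum
  sv3 <- facility_survey(mk(rep(TRUE, 4), rep(2, 4),
                            stratum = rep(c("hospital", "clinic"), 2)),
                         "SPA", 2014)
  expect_true(all(readiness_by_stratum(sv3, def) == 1))
})

test_that("readiness equals brute-force enumeration on small surveys", {
  reg <- indicator_registry()
  comps <- registry_components(reg, "SPA")
  set.seed(404)
  for (trial in 1:10) {
    n <- sample(3:20, 1)
    rec <- tibble::tibble(
      facility_id = paste0("f", seq_len(n)),
      stratum = sample(c("hospital", "clinic"), n, replace = TRUE),
      weight = stats::runif(n, 0.2, 3))
    for (cc in comps) rec[[cc]] <- sample(c(TRUE, FALSE), n, TRUE, c(.8, .2))
    sv <- facility_survey(rec, "SPA", 2012)
    for (id in sample(registry_interventions(reg)$intervention_id, 5)) {
      def <- indicator_definition(id, reg)
      expect_equal(readiness_by_stratum(sv, def),
                   oracle_readiness(rec, def$component),
                   tolerance = 1e-12, label = paste("trial", trial, id))
    }
  }
})

test_that("adding a component never decreases readiness (monotonicity)", {
  reg <- indicator_registry()
  comps <- registry_components(reg, "SPA")
  set.seed(17)
  rec <- tibble::tibble(facility_id = paste0("f", 1:12),
                        stratum = rep(c("hospital", "clinic"), 6),
                        weight = stats::runif(12, 0.5, 2))
  for (cc in comps) rec[[cc]] <- sample(c(TRUE, FALSE), 12, TRUE)
  sv <- facility_survey(rec, "SPA", 2012)
  before <- lapply(registry_interventions(reg)$intervention_id, function(id) {
    readiness_by_stratum(sv, indicator_definition(id, reg))
  })
  rec2 <- rec
  flip <- which(!rec2[[comps[3]]])[1]
  rec2[[comps[3]]][flip] <- TRUE
  sv2 <- facility_survey(rec2, "SPA", 2012)
  after <- lapply(registry_interventions(reg)$intervention_id, function(id) {
    readiness_by_stratum(sv2, indicator_definition(id, reg))
  })
  for (i in seq_along(before)) {
    expect_true(all(after[[i]] >= before[[i]] - 1e-12))
  }
})

test_that("effective coverage composes readiness, shares and utilization", {
  prof <- utilization_profile("X", anc4_plus = 0.6, hfd = 1.0,
                              stratum_shares = c(hospital = 0.7,
                                                 health_center = 0.3))
  r <- c(hospital = 0.8, health_center = 0.5)
  expect_equal(effective_coverage(r, prof, "childbirth"), 0.71)
  # perfect readiness: coverage equals the utilization cap
  expect_equal(effective_coverage(c(hospital = 1, health_center = 1), prof,
                                  "antenatal"), 0.6)
  # zero utilization: zero coverage
  prof0 <- utilization_profile("X", 0.5, 0,
                               stratum_shares = c(hospital = 1))
  expect_equal(effective_coverage(c(hospital = 0.9), prof0, "childbirth"), 0)
  # a stratum with nonzero share but no readiness estimate is an error
  expect_error(effective_coverage(c(hospital = 0.8), prof, "childbirth"),
               "health_center")
})

test_that("link validity follows the two-year rule", {
  expect_true(validate_link(2014, 2014))
  expect_true(validate_link(2010, 2008.5))
  expect_false(validate_link(2016, 2013))
  expect_true(validate_link(2013, 2015))
})

test_that("country baseline hits the utilization caps at perfect readiness", {
  truth <- make_test_truth(p = 1, anc4 = 0.6, hfd = 0.66)
  fs <- generate_facility_survey(truth, 30, "SPA", seed = 2,
                                 survey_year = 2014)
  hh <- generate_household_survey(truth, seed = 3, survey_year = 2015)
  est <- estimate_country_baseline(survey_pair(fs, hh))
  expect_equal(est$coverage[est$period == "antenatal"], rep(0.6, 8))
  expect_equal(est$coverage[est$period != "antenatal"], rep(0.66, 11))
  expect_true(all(est$provenance == "linked"))
})

test_that("invalid links are refused with the year gap reported", {
  truth <- make_test_truth()
  fs <- generate_facility_survey(truth, 10, "SPA", seed = 2,
                                 survey_year = 2016)
  hh <- generate_household_survey(truth, seed = 3, survey_year = 2013)
  expect_error(estimate_country_baseline(survey_pair(fs, hh)), "3\\.0")
})

test_that("linked estimation recovers ground-truth coverage within 3 SE", {
  set.seed(31)
  n_iv <- 19
  pm <- matrix(stats::runif(n_iv * 2, 0.2, 0.9), ncol = 2)
  truth <- make_test_truth(
    p = `dimnames<-`(pm, list(registry_interventions()$intervention_id,
                              c("hospital", "health_center"))),
    shares = c(hospital = 0.55, health_center = 0.45))
  n_fac <- 2000
  fs <- generate_facility_survey(truth, n_fac, "SPA", seed = 77,
                                 survey_year = 2014)
  hh <- generate_household_survey(truth, seed = 78, survey_year = 2015)
  est <- estimate_country_baseline(survey_pair(fs, hh))
  tru <- true_effective_coverage(truth)
  n_by <- table(fs$records$stratum)
  for (i in seq_len(nrow(est))) {
    se <- coverage_se(truth, est$intervention_id[i], est$period[i], n_by)
    expect_lt(abs(est$coverage[i] - tru$coverage[i]), 3 * se + 1e-12)
  }
  # and coverage never exceeds the period's utilization cap
  cap <- ifelse(est$period == "antenatal", truth$anc4_plus, truth$hfd)
  expect_true(all(est$coverage <= cap + 1e-12))
})

test_that("indicators with no applicable components are flagged absent", {
  reg <- indicator_registry()
  # make hygienic cord care entirely SPA-only
  reg$spa_only[reg$intervention_id == "hygienic_cord_care"] <- TRUE
  def <- reg[reg$intervention_id == "hygienic_cord_care", ]
  expect_identical(evaluate_readiness(all_present_record(reg), def, "SARA"),
                   NA)
  truth <- make_test_truth()
  fs <- generate_facility_survey(truth, 20, "SARA", seed = 4,
                                 survey_year = 2014, registry = reg)
  hh <- generate_household_survey(truth, seed = 5, survey_year = 2015)
  est <- estimate_country_baseline(survey_pair(fs, hh), reg)
  expect_true(is.na(est$coverage[est$intervention_id == "hygienic_cord_care"]))
  expect_false(anyNA(est$coverage[est$intervention_id != "hygienic_cord_care"]))
})
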