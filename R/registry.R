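#' Readiness indicator registry for the 19 maternal and newborn interventions
#'
#' Returns the uniform indicator definitions used to construct facility
#' readiness: for each of the 19 interventions (8 antenatal, 7 childbirth,
#' 4 postnatal), the minimum set of structural components (staff training,
#' guidelines, equipment, medicines and commodities) that must all be present
#' for a facility to be considered ready to deliver that intervention.
#'
#' Components assessed only in SPA surveys carry `spa_only = TRUE`; when a
#' SARA survey is evaluated these components are dropped from the requirement
#' set. Exactly one component per intervention is flagged `binding`: the
#' synthetic-data generator draws that component with the ground-truth
#' readiness probability and the remaining components as always present, so
#' the conjunction probability equals the ground truth exactly.
#'
#' Component codes are a fixed controlled vocabulary, one code per checklist
#' line item. Line items that recur verbatim across interventions (ANC staff
#' training, ANC guidelines, IMPAC guidelines) share a code; the uterotonic
#' item is coded separately for AMTSL and induction so readiness indicators
#' stay statistically independent across interventions in generated data.
#'
#' @return A tibble with one row per (intervention, component): columns
#'   `intervention_id`, `intervention_label`, `period` (one of `"antenatal"`,
#'   `"childbirth"`, `"postnatal"`), `component` (code), `component_label`,
#'   `spa_only` (logical), `binding` (logical).
#' @examples
#' reg <- indicator_registry()
#' dplyr::count(dplyr::distinct(reg, intervention_id, period), period)
#' @export
indicator_registry <- function() {
  def <- function(id, label, period, comps) {
    tibble::tibble(
      intervention_id = id,
      intervention_label = label,
      period = period,
      component = vapply(comps, `[[`, "", 1L),
      component_label = vapply(comps, `[[`, "", 2L),
      spa_only = vapply(comps, function(x) isTRUE(x$spa_only), NA),
      binding = vapply(comps, function(x) isTRUE(x$binding), NA)
    )
  }
  c_ <- function(code, label, spa_only = FALSE, binding = FALSE) {
    list(code, label, spa_only = spa_only, binding = binding)
  }
  anc_staff <- c_("anc_staff_trained",
                  "At least one staff member trained in at least one aspect of ANC")
  anc_guide <- c_("anc_guidelines", "Reported availability of ANC guidelines")
  impac <- c_("impac_guidelines", "Observed availability of guidelines for IMPAC")

  reg <- dplyr::bind_rows(
    ## -- Antenatal care ---------------------------------------------------
    def("tetanus_toxoid", "Tetanus toxoid vaccination", "antenatal", list(
      c_("tt_vaccine", "At least one valid unexpired unit of tetanus toxoid vaccine",
         binding = TRUE),
      anc_staff, anc_guide)),
    def("iptp_malaria", "Intermittent preventive treatment of malaria in pregnancy",
        "antenatal", list(
      c_("sp_tablets", "At least one valid unexpired unit of sulphadoxine/pyrimethamine",
         binding = TRUE),
      anc_staff, anc_guide)),
    def("syphilis_detection", "Syphilis detection and treatment", "antenatal", list(
      c_("syphilis_test", "At least one valid syphilis test (RDT, RPR or VDRL)",
         binding = TRUE),
      c_("penicillin_injectable",
         "At least one valid unexpired unit of injectable penicillin"),
      anc_staff, anc_guide)),
    def("iron_supplementation", "Iron supplementation in pregnancy", "antenatal", list(
      c_("iron_folate_tablets",
         "At least one valid unexpired unit of iron or iron-folic acid tablets",
         binding = TRUE),
      anc_staff, anc_guide)),
    def("hypertension_mgmt", "Hypertensive disorder case management", "antenatal", list(
      c_("urine_protein_dipstick", "At least one valid dipstick for urine protein",
         binding = TRUE),
      c_("bp_apparatus", "At least one functioning blood pressure apparatus"),
      c_("oral_antihypertensive",
         "At least one valid unexpired unit of amlodipine/nifedipine/methyldopa"),
      anc_staff, anc_guide)),
    def("diabetes_mgmt", "Diabetes case management", "antenatal", list(
      c_("glucometer_with_strips", "At least one glucometer and glucometer test strips",
         binding = TRUE),
      c_("urine_glucose_dipstick", "At least one valid dipstick for urine glucose"),
      anc_staff, anc_guide)),
    def("malaria_case_mgmt", "Malaria case management", "antenatal", list(
      c_("malaria_diagnostics",
         "At least one RDT kit, or smear microscopy with slides and stain"),
      c_("act_treatment",
         "At least one valid unexpired unit of artemisinin-based combination therapy",
         binding = TRUE),
      anc_staff, anc_guide)),
    def("mgso4_preeclampsia", "MgSO4 management of pre-eclampsia", "antenatal", list(
      c_("mgso4_unit", "At least one valid unexpired unit of magnesium sulfate",
         binding = TRUE),
      anc_staff, anc_guide)),

    ## -- Childbirth care --------------------------------------------------
    def("clean_birth_practices", "Clean birth practices", "childbirth", list(
      impac,
      c_("infection_prevention_guidelines",
         "Guidelines on standard precautions for infection prevention"),
      c_("hand_hygiene_supplies",
         "Soap and running water, or gloves, or alcohol-based hand rub",
         binding = TRUE),
      c_("functional_sterilizer",
         "Functional dry-heat sterilizer or autoclave"))),
    def("labour_delivery_mgmt", "Labor and delivery management", "childbirth", list(
      c_("blank_partographs", "Availability of blank partographs", binding = TRUE),
      c_("delivery_pack", "Delivery pack or the full set of individual instruments"),
      c_("delivery_bed", "Availability of a delivery bed"),
      c_("delivery_light", "Functional spotlight source or flashlight"),
      impac)),
    def("neonatal_resuscitation", "Neonatal resuscitation", "childbirth", list(
      c_("staff_trained_nn_resuscitation",
         "Staff trained for neonatal resuscitation in past 2 years", spa_only = TRUE),
      c_("newborn_bag_mask", "Functional newborn bag and mask", binding = TRUE),
      impac)),
    def("antibiotics_pprom", "Antibiotics for pPRoM", "childbirth", list(
      c_("azithromycin", "At least one valid unexpired unit of azithromycin",
         binding = TRUE),
      impac)),
    def("mgso4_eclampsia", "Management of eclampsia with MgSO4", "childbirth", list(
      c_("injectable_mgso4",
         "At least one valid unit of injectable magnesium sulfate where stocked",
         binding = TRUE),
      impac)),
    def("amtsl", "Active management of the third stage of labor", "childbirth", list(
      c_("staff_trained_amtsl", "Staff trained in AMTSL in past 2 years",
         spa_only = TRUE),
      c_("uterotonic_amtsl",
         "At least one valid unit of injectable uterotonic or oral misoprostol",
         binding = TRUE),
      impac)),
    def("labour_induction", "Induction of labor for pregnancies lasting 41+ weeks",
        "childbirth", list(
      c_("uterotonic_induction",
         "At least one valid unit of injectable uterotonic or oral misoprostol",
         binding = TRUE),
      impac)),

    ## -- Postnatal care ---------------------------------------------------
    def("hygienic_cord_care", "Hygienic cord care", "postnatal", list(
      c_("chlorhexidine", "At least one valid unexpired unit of chlorhexidine",
         spa_only = TRUE, binding = TRUE),
      impac)),
    def("thermal_care", "Thermal care for premature babies", "postnatal", list(
      c_("thermal_care_practice",
         "Routinely observed drying/wrapping or skin-to-skin of newborns",
         spa_only = TRUE, binding = TRUE),
      impac)),
    def("kangaroo_mother_care", "Kangaroo Mother Care for premature babies",
        "postnatal", list(
      c_("staff_trained_kmc", "Staff trained in Kangaroo Mother Care in past 2 years",
         spa_only = TRUE, binding = TRUE),
      impac)),
    def("neonatal_sepsis_abx",
        "Case management of neonatal sepsis/pneumonia with injectable antibiotics",
        "postnatal", list(
      c_("injectable_antibiotics_newborn",
         "Procaine benzylpenicillin, or gentamicin and ceftriaxone", binding = TRUE),
      impac))
  )
  reg
}

#' Interventions covered by the registry
#'
#' @param registry A registry tibble from [indicator_registry()].
#' @return Tibble with one row per intervention: `intervention_id`,
#'   `intervention_label`, `period`.
#' @export
registry_interventions <- function(registry = indicator_registry()) {
  dplyr::distinct(registry, .data$intervention_id, .data$intervention_label,
                  .data$period)
}

#' Extract one indicator definition
#'
#' @param intervention_id Identifier of one of the 19 interventions.
#' @inheritParams registry_interventions
#' @return The registry rows for that intervention (a tibble).
#' @export
indicator_definition <- function(intervention_id, registry = indicator_registry()) {
  stopifnot(length(intervention_id) == 1L)
  def <- registry[registry$intervention_id == intervention_id, , drop = FALSE]
  if (nrow(def) == 0L) {
    stop("unknown intervention: ", intervention_id, call. = FALSE)
  }
  def
}

#' Components an indicator requires under a given survey type
#'
#' SARA surveys do not assess SPA-only components, so those are excluded from
#' the requirement set when `survey_type = "SARA"`.
#'
#' @param definition One indicator definition (rows of the registry for a
#'   single intervention).
#' @param survey_type `"SPA"` or `"SARA"`.
#' @return Character vector of component codes (possibly empty).
#' @export
applicable_components <- function(definition, survey_type = c("SPA", "SARA")) {
  survey_type <- match.arg(survey_type)
  stopifnot(length(unique(definition$intervention_id)) == 1L)
  if (survey_type == "SARA") {
    definition$component[!definition$spa_only]
  } else {
    definition$component
  }
}

#' Validate a registry tibble
#'
#' Checks structural invariants: 19 interventions split 8/7/4 across the
#' antenatal/childbirth/postnatal periods, non-empty component sets, and
#' exactly one binding component per intervention with no binding component
#' shared between interventions.
#'
#' @inheritParams registry_interventions
#' @return The registry, invisibly; errors on violation.
#' @export
validate_registry <- function(registry) {
  iv <- registry_interventions(registry)
  if (nrow(iv) != 19L) {
    stop("registry must define exactly 19 interventions, found ", nrow(iv),
         call. = FALSE)
  }
  counts <- table(iv$period)
  expected <- c(antenatal = 8L, childbirth = 7L, postnatal = 4L)
  if (!identical(as.integer(counts[names(expected)]), unname(expected))) {
    stop("registry period split must be 8 antenatal / 7 childbirth / 4 postnatal",
         call. = FALSE)
  }
  n_binding <- tapply(registry$binding, registry$intervention_id, sum)
  if (any(n_binding != 1L)) {
    stop("each intervention must have exactly one binding component",
         call. = FALSE)
  }
  bind_comps <- registry$component[registry$binding]
  if (anyDuplicated(bind_comps)) {
    stop("binding components must be unique to their intervention", call. = FALSE)
  }
  shared_binding <- intersect(bind_comps, registry$component[!registry$binding])
  if (length(shared_binding)) {
    stop("binding component also required elsewhere: ",
         paste(shared_binding, collapse = ", "), call. = FALSE)
  }
  invisible(registry)
}

#' All component codes a survey of a given type must record
#'
#' @inheritParams registry_interventions
#' @param survey_type `"SPA"` or `"SARA"`.
#' @return Character vector of component codes.
#' @export
registry_components <- function(registry = indicator_registry(),
                                survey_type = c("SPA", "SARA")) {
  survey_type <- match.arg(survey_type)
  if (survey_type == "SARA") registry <- registry[!registry$spa_only, , drop = FALSE]
  unique(registry$component)
}
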