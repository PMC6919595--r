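#' Illustrative intervention-efficacy configuration
#'
#' One row per (intervention, outcome, cause) pathway: the proportional
#' reduction in cause-specific deaths achieved at full coverage (`efficacy`)
#' and the share of that cause's deaths the intervention can act upon
#' (`affected_fraction`). The topology follows the standard antenatal /
#' childbirth / postnatal impact pathways for maternal deaths, neonatal
#' deaths and stillbirths (e.g. active management of the third stage of
#' labor acts on maternal haemorrhage, neonatal resuscitation on
#' intrapartum-related neonatal deaths, magnesium sulfate on hypertensive
#' disorders and stillbirth, syphilis detection on stillbirth and neonatal
#' causes).
#'
#' The numeric values are illustrative defaults for synthetic experiments;
#' they are NOT the effectiveness values used by the Lives Saved Tool, which
#' ships its own evidence-reviewed database. Supply your own matrix (same
#' columns) to model real settings.
#'
#' @return Tibble `intervention_id`, `outcome`, `cause`, `efficacy`,
#'   `affected_fraction`.
#' @export
default_efficacy_matrix <- function() {
  e <- function(iid, outcome, cause, eff, af) {
    tibble::tibble(intervention_id = iid, outcome = outcome, cause = cause,
                   efficacy = eff, affected_fraction = af)
  }
  dplyr::bind_rows(
    ## antenatal
    e("tetanus_toxoid", "neonatal", "tetanus", 0.88, 0.90),
    e("iptp_malaria", "stillbirth", "antepartum_stillbirth", 0.20, 0.25),
    e("iptp_malaria", "neonatal", "prematurity", 0.15, 0.20),
    e("syphilis_detection", "stillbirth", "antepartum_stillbirth", 0.50, 0.10),
    e("syphilis_detection", "neonatal", "sepsis_pneumonia", 0.40, 0.05),
    e("syphilis_detection", "neonatal", "prematurity", 0.30, 0.05),
    e("iron_supplementation", "maternal", "other_maternal", 0.20, 0.15),
    e("hypertension_mgmt", "maternal", "hypertensive_disorders", 0.30, 0.70),
    e("hypertension_mgmt", "stillbirth", "antepartum_stillbirth", 0.20, 0.15),
    e("diabetes_mgmt", "stillbirth", "antepartum_stillbirth", 0.10, 0.05),
    e("diabetes_mgmt", "neonatal", "other_neonatal", 0.10, 0.05),
    e("malaria_case_mgmt", "maternal", "other_maternal", 0.30, 0.10),
    e("malaria_case_mgmt", "stillbirth", "antepartum_stillbirth", 0.15, 0.10),
    e("mgso4_preeclampsia", "maternal", "hypertensive_disorders", 0.40, 0.50),
    e("mgso4_preeclampsia", "stillbirth", "antepartum_stillbirth", 0.15, 0.10),
    ## childbirth
    e("clean_birth_practices", "maternal", "sepsis", 0.25, 0.80),
    e("clean_birth_practices", "neonatal", "sepsis_pneumonia", 0.20, 0.60),
    e("clean_birth_practices", "neonatal", "tetanus", 0.30, 0.40),
    e("labour_delivery_mgmt", "maternal", "obstructed_labour", 0.50, 0.80),
    e("labour_delivery_mgmt", "maternal", "haemorrhage", 0.20, 0.30),
    e("labour_delivery_mgmt", "stillbirth", "intrapartum_stillbirth", 0.45, 0.70),
    e("labour_delivery_mgmt", "neonatal", "intrapartum", 0.25, 0.40),
    e("neonatal_resuscitation", "neonatal", "intrapartum", 0.40, 0.75),
    e("antibiotics_pprom", "neonatal", "prematurity", 0.10, 0.30),
    e("antibiotics_pprom", "neonatal", "sepsis_pneumonia", 0.15, 0.20),
    e("mgso4_eclampsia", "maternal", "hypertensive_disorders", 0.50, 0.60),
    e("mgso4_eclampsia", "stillbirth", "intrapartum_stillbirth", 0.10, 0.10),
    e("amtsl", "maternal", "haemorrhage", 0.50, 0.66),
    e("labour_induction", "stillbirth", "antepartum_stillbirth", 0.20, 0.10),
    e("labour_induction", "neonatal", "intrapartum", 0.10, 0.10),
    ## postnatal
    e("hygienic_cord_care", "neonatal", "sepsis_pneumonia", 0.30, 0.50),
    e("hygienic_cord_care", "neonatal", "tetanus", 0.25, 0.30),
    e("thermal_care", "neonatal", "prematurity", 0.20, 0.50),
    e("kangaroo_mother_care", "neonatal", "prematurity", 0.35, 0.40),
    e("neonatal_sepsis_abx", "neonatal", "sepsis_pneumonia", 0.65, 0.70)
  )
}

#' Validate an efficacy configuration
#'
#' Checks that efficacies and affected fractions are proportions, their
#' product lies in \[0, 1\], and no (intervention, outcome, cause) pathway
#' appears more than once.
#'
#' @param config Efficacy tibble (see [default_efficacy_matrix()]).
#' @return The config, invisibly; errors on violation.
#' @export
validate_efficacy_matrix <- function(config) {
  config <- tibble::as_tibble(config)
  need <- c("intervention_id", "outcome", "cause", "efficacy",
            "affected_fraction")
  missing_cols <- setdiff(need, names(config))
  if (length(missing_cols)) {
    stop("efficacy matrix missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  chk_prop(config$efficacy, "efficacy")
  chk_prop(config$affected_fraction, "affected_fraction")
  chk_prop(config$efficacy * config$affected_fraction,
           "efficacy * affected_fraction")
  if (anyDuplicated(config[c("intervention_id", "outcome", "cause")])) {
    stop("duplicate (intervention, outcome, cause) pathway in efficacy matrix",
         call. = FALSE)
  }
  invisible(config)
}
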