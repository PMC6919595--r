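## CSV and JSON interchange. Dialect: UTF-8, comma-separated, header row,
## '.' decimal. Readers validate schemas and report offending rows.

stop_rows <- function(bad, msg, file) {
  if (any(bad)) {
    stop(msg, " in ", basename(file), " at row(s): ",
         paste(utils::head(which(bad), 10), collapse = ", "), call. = FALSE)
  }
}

need_cols <- function(df, cols, file) {
  missing_c <- setdiff(cols, names(df))
  if (length(missing_c)) {
    stop("file ", basename(file), " is missing column(s): ",
         paste(missing_c, collapse = ", "), call. = FALSE)
  }
}

#' Write / read a facility survey CSV
#'
#' Columns: `facility_id`, `stratum`, `weight`, `survey_type`, `survey_year`,
#' then one 0/1 column per component code.
#'
#' @param survey A [facility_survey()] object.
#' @param path Output CSV path.
#' @return `path`, invisibly (writer); a [facility_survey()] (reader).
#' @export
write_facility_survey <- function(survey, path) {
  stopifnot(inherits(survey, "facility_survey"))
  rec <- survey$records
  comp <- setdiff(names(rec), c("facility_id", "stratum", "weight"))
  out <- rec
  for (cc in comp) out[[cc]] <- as.integer(out[[cc]])
  out <- dplyr::mutate(out, survey_type = survey$survey_type,
                       survey_year = survey$survey_year,
                       .after = "weight")
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_facility_survey
#' @export
read_facility_survey <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need_cols(df, c("facility_id", "stratum", "weight", "survey_type",
                  "survey_year"), path)
  stop_rows(!is.finite(df$weight) | df$weight <= 0,
            "non-positive survey weight", path)
  stype <- unique(df$survey_type)
  syear <- unique(df$survey_year)
  stopifnot(length(stype) == 1L, length(syear) == 1L)
  comp <- setdiff(names(df), c("facility_id", "stratum", "weight",
                               "survey_type", "survey_year"))
  for (cc in comp) {
    stop_rows(!df[[cc]] %in% c(0L, 1L), paste0("non-binary value in ", cc),
              path)
  }
  facility_survey(df[c("facility_id", "stratum", "weight", comp)],
                  stype, syear)
}

#' Write / read household utilization profiles as CSV
#'
#' Long format, one row per (country, stratum): `country_id`, `anc4_plus`,
#' `hfd`, `survey_year`, `stratum`, `stratum_share`.
#'
#' @param profiles Named list of [utilization_profile()] objects.
#' @param path CSV path.
#' @return `path` invisibly (writer); named list of profiles (reader).
#' @export
write_utilization_profiles <- function(profiles, path) {
  rows <- dplyr::bind_rows(lapply(profiles, function(p) {
    tibble::tibble(country_id = p$country_id, anc4_plus = p$anc4_plus,
                   hfd = p$hfd, survey_year = p$survey_year,
                   stratum = names(p$stratum_shares),
                   stratum_share = unname(p$stratum_shares))
  }))
  readr::write_csv(rows, path)
  invisible(path)
}

#' @rdname write_utilization_profiles
#' @export
read_utilization_profiles <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need_cols(df, c("country_id", "anc4_plus", "hfd", "survey_year", "stratum",
                  "stratum_share"), path)
  stop_rows(df$anc4_plus < 0 | df$anc4_plus > 1, "anc4_plus outside [0,1]",
            path)
  stop_rows(df$hfd < 0 | df$hfd > 1, "hfd outside [0,1]", path)
  out <- lapply(split(df, df$country_id), function(d) {
    utilization_profile(d$country_id[1], d$anc4_plus[1], d$hfd[1],
                        stats::setNames(d$stratum_share, d$stratum),
                        d$survey_year[1])
  })
  out[order(names(out))]
}

#' Write / read epidemiological profiles as CSV
#'
#' Long format: `country_id`, `year`, `outcome`, `cause`, `count`. Birth
#' denominators travel as `outcome = "births"` rows with causes
#' `live_births` and `stillbirths`.
#'
#' @param profiles Named list of [epi_profile()] objects.
#' @param path CSV path.
#' @return `path` invisibly (writer); named list of profiles (reader).
#' @export
write_epi_profiles <- function(profiles, path) {
  rows <- dplyr::bind_rows(lapply(profiles, function(p) {
    dplyr::bind_rows(
      tibble::tibble(country_id = p$country_id, year = p$year,
                     outcome = "births",
                     cause = c("live_births", "stillbirths"),
                     count = c(p$live_births, p$stillbirths)),
      tibble::tibble(country_id = p$country_id, year = p$year,
                     outcome = p$deaths$outcome, cause = p$deaths$cause,
                     count = p$deaths$deaths))
  }))
  readr::write_csv(rows, path)
  invisible(path)
}

#' @rdname write_epi_profiles
#' @export
read_epi_profiles <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need_cols(df, c("country_id", "year", "outcome", "cause", "count"), path)
  stop_rows(!is.finite(df$count) | df$count < 0, "negative count", path)
  out <- lapply(split(df, df$country_id), function(d) {
    den <- d[d$outcome == "births", ]
    lb <- den$count[den$cause == "live_births"]
    sb <- den$count[den$cause == "stillbirths"]
    dd <- d[d$outcome != "births", ]
    epi_profile(d$country_id[1], d$year[1], lb, sb,
                tibble::tibble(outcome = dd$outcome, cause = dd$cause,
                               deaths = dd$count))
  })
  out[order(names(out))]
}

#' Write / read an efficacy matrix as CSV
#'
#' Columns: `intervention_id`, `outcome`, `cause`, `efficacy`,
#' `affected_fraction`.
#'
#' @param config Efficacy tibble.
#' @param path CSV path.
#' @return `path` invisibly (writer); validated tibble (reader).
#' @export
write_efficacy_matrix <- function(config, path) {
  validate_efficacy_matrix(config)
  readr::write_csv(tibble::as_tibble(config), path)
  invisible(path)
}

#' @rdname write_efficacy_matrix
#' @export
read_efficacy_matrix <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_efficacy_matrix(df)
  df
}

#' Serialize ground truths to JSON
#'
#' Stores every ground-truth parameter of a synthetic country set so tests
#' and audits can compare pipeline estimates against the generating values.
#'
#' @param countries Output of [generate_country_set()].
#' @param path JSON path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(countries, path) {
  payload <- lapply(countries, function(cc) {
    t <- cc$truth
    list(country_id = t$country_id,
         linked = cc$linked,
         readiness_prob = as.data.frame(t$readiness_prob),
         anc4_plus = t$anc4_plus, hfd = t$hfd,
         stratum_shares = as.list(t$stratum_shares),
         live_births = t$live_births, stillbirths = t$stillbirths,
         deaths = as.list(t$deaths),
         cause_fractions = lapply(t$cause_fractions, as.list))
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write a synthetic country set to a dataset directory
#'
#' Produces `utilization.csv`, `epi.csv`, one `facility_<country>.csv` per
#' linked country, `ground_truth.json` and a `manifest.csv` tying them
#' together.
#'
#' @param countries Output of [generate_country_set()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic_dataset <- function(countries, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  profiles <- lapply(countries, `[[`, "utilization")
  names(profiles) <- names(countries)
  write_utilization_profiles(profiles, file.path(dir, "utilization.csv"))
  epis <- lapply(countries, `[[`, "epi")
  names(epis) <- names(countries)
  write_epi_profiles(epis, file.path(dir, "epi.csv"))
  manifest <- tibble::tibble(country_id = names(countries),
                             linked = vapply(countries, `[[`, NA, "linked"),
                             facility_file = NA_character_)
  for (i in seq_along(countries)) {
    cc <- countries[[i]]
    if (isTRUE(cc$linked)) {
      f <- paste0("facility_", cc$truth$country_id, ".csv")
      write_facility_survey(cc$pair$facility_survey, file.path(dir, f))
      manifest$facility_file[i] <- f
    }
  }
  readr::write_csv(manifest, file.path(dir, "manifest.csv"))
  write_ground_truth(countries, file.path(dir, "ground_truth.json"))
  invisible(dir)
}

#' Read a synthetic dataset directory back into a country set
#'
#' Reconstructs the list structure [run_pipeline()] consumes (survey pairs
#' for linked countries, utilization and epi profiles for all). Ground
#' truths are not re-loaded; they are test metadata, not pipeline inputs.
#'
#' @param dir Dataset directory written by [write_synthetic_dataset()].
#' @return List of country records (`utilization`, `epi`, `linked`, `pair`).
#' @export
read_country_set <- function(dir) {
  manifest <- readr::read_csv(file.path(dir, "manifest.csv"),
                              show_col_types = FALSE, progress = FALSE)
  profiles <- read_utilization_profiles(file.path(dir, "utilization.csv"))
  epis <- read_epi_profiles(file.path(dir, "epi.csv"))
  out <- lapply(seq_len(nrow(manifest)), function(i) {
    cid <- manifest$country_id[i]
    rec <- list(truth = NULL, utilization = profiles[[cid]],
                epi = epis[[cid]], linked = manifest$linked[i], pair = NULL)
    if (isTRUE(manifest$linked[i])) {
      fs <- read_facility_survey(file.path(dir, manifest$facility_file[i]))
      rec$pair <- survey_pair(fs, profiles[[cid]])
    }
    rec
  })
  names(out) <- manifest$country_id
  out
}
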