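#' Extract fall-injury episodes
#'
#' Retains episodes with (i) a principal external-cause mechanism
#' indicating a fall (W00-W19), (ii) age at admission of 65+ years and
#' (iii) a principal diagnosis indicating an injury (S00 to T75 or T79;
#' the range excludes injuries due to medical care procedures).
#' Episodes with malformed codes are excluded with a message, never an
#' error.
#'
#' @param episodes episode table.
#' @param min_age minimum age at admission (years).
#' @return the retained episode rows.
#' @export
extract_fall_injury_episodes <- function(episodes, min_age = 65) {
  dx_ok <- is_fall_injury_dx(episodes$principal_diagnosis)
  mech_ok <- is_fall_mechanism(episodes$ext_mechanism)
  malformed <- !icd_valid(icd_strip(episodes$principal_diagnosis)) |
    !icd_valid(icd_strip(episodes$ext_mechanism))
  if (any(malformed)) {
    message(sum(malformed), " episode(s) with malformed codes excluded")
  }
  keep <- dx_ok & mech_ok & episodes$age_at_admission >= min_age
  keep[is.na(keep)] <- FALSE
  episodes[keep, , drop = FALSE]
}

#' Retain hip-fracture principal diagnoses
#'
#' Keeps episodes whose principal diagnosis lies in S72.0-S72.2
#' (fractures of the femoral neck, pertrochanteric and subtrochanteric
#' region); S72.3 and beyond are excluded.
#'
#' @param episodes episode table.
#' @return the retained episode rows.
#' @export
hip_fracture_filter <- function(episodes) {
  episodes[is_hip_fracture_dx(episodes$principal_diagnosis), , drop = FALSE]
}

#' Shipped case-selection scenarios
#'
#' Returns the flag bundle for one of the six shipped selection
#' scenarios: the linked-data reference standard, the unlinked base
#' case, and its four unlinked variants S1-S4.  All six require a
#' hip-fracture principal diagnosis and admission from private
#' residence/accommodation; they differ in their exclusion criteria:
#' \describe{
#'   \item{base}{excludes in-hospital deaths and readmissions within 30
#'     days of discharge.}
#'   \item{S1}{base, but in-hospital deaths are kept.}
#'   \item{S2}{base plus exclusion of readmissions within 120 days.}
#'   \item{S3}{S2 plus exclusion of revision-procedure-only,
#'     non-acute-care and non-emergency episodes.}
#'   \item{S4}{S3, but in-hospital deaths are kept (the same criteria as
#'     the reference standard).}
#'   \item{reference}{person-level selection on linked data: emergency
#'     acute admissions without revision-only procedures, discharge
#'     status disregarded, with the 120-day clearance period and the
#'     external-cause disagreement rule separating incident events.}
#' }
#'
#' @param name one of `"reference"`, `"base"`, `"S1"`, `"S2"`, `"S3"`,
#'   `"S4"`.
#' @return an object of class `scenario_spec`.
#' @export
scenario_spec <- function(name) {
  specs <- shipped_scenario_specs()
  if (!name %in% names(specs)) {
    stop("unknown scenario '", name, "'; shipped scenarios are: ",
         paste(names(specs), collapse = ", "), call. = FALSE)
  }
  specs[[name]]
}

#' @rdname scenario_spec
#' @export
shipped_scenarios <- function() names(shipped_scenario_specs())

shipped_scenario_specs <- function() {
  base_spec <- function(name, ...) {
    flags <- list(
      name = name,
      require_hip_fracture_dx = TRUE,
      require_private_residence = TRUE,
      exclude_inhospital_death = FALSE,
      exclude_readmit_30d = FALSE,
      exclude_readmit_120d = FALSE,
      exclude_revision_only = FALSE,
      exclude_nonacute = FALSE,
      exclude_nonemergency = FALSE,
      use_person_linkage = FALSE,
      use_external_cause_rule = FALSE
    )
    flags[names(list(...))] <- list(...)
    structure(flags, class = "scenario_spec")
  }
  list(
    reference = base_spec("reference",
                          exclude_readmit_30d = TRUE,
                          exclude_readmit_120d = TRUE,
                          exclude_revision_only = TRUE,
                          exclude_nonacute = TRUE,
                          exclude_nonemergency = TRUE,
                          use_person_linkage = TRUE,
                          use_external_cause_rule = TRUE),
    base = base_spec("base",
                     exclude_inhospital_death = TRUE,
                     exclude_readmit_30d = TRUE),
    S1 = base_spec("S1",
                   exclude_readmit_30d = TRUE),
    S2 = base_spec("S2",
                   exclude_inhospital_death = TRUE,
                   exclude_readmit_30d = TRUE,
                   exclude_readmit_120d = TRUE),
    S3 = base_spec("S3",
                   exclude_inhospital_death = TRUE,
                   exclude_readmit_30d = TRUE,
                   exclude_readmit_120d = TRUE,
                   exclude_revision_only = TRUE,
                   exclude_nonacute = TRUE,
                   exclude_nonemergency = TRUE),
    S4 = base_spec("S4",
                   exclude_readmit_30d = TRUE,
                   exclude_readmit_120d = TRUE,
                   exclude_revision_only = TRUE,
                   exclude_nonacute = TRUE,
                   exclude_nonemergency = TRUE)
  )
}

# procedure list non-empty and every code in the revision set
revision_only <- function(procedure_codes,
                          revision_codes = hip_revision_codes()) {
  vapply(procedure_codes, function(x) {
    codes <- parse_codes(x)
    length(codes) > 0 && all(codes %in% revision_codes)
  }, TRUE, USE.NAMES = FALSE)
}

incident_case_table <- function(episodes, person_id,
                                age_bands = c(65, 70, 75, 80, 85)) {
  tibble::tibble(
    index_episode_id = episodes$episode_id,
    person_id = person_id,
    admission_date = episodes$admission_date,
    fiscal_year = fiscal_year(episodes$admission_date),
    age_band = as.character(age_band(episodes$age_at_admission, age_bands)),
    sex = episodes$sex
  )
}

#' Identify incident cases from unlinked (episode-level) data
#'
#' Applies one unlinked scenario's inclusion and exclusion flags to an
#' extracted episode table.  Readmission exclusions use the only person
#' identification unlinked data offer: the (hospital, hospital patient
#' id) pair, available for readmissions to the *same public* hospital
#' only; readmissions to a different hospital, or involving a private
#' hospital, are undetectable.  The gap is the episode's admission date
#' minus the latest earlier discharge of the same pseudo-person at that
#' hospital, in whole days; the episode is excluded when
#' `0 <= gap <= window` (windows inclusive).
#'
#' @param episodes extracted episode table (see
#'   [extract_fall_injury_episodes()]); all episodes participate in
#'   readmission detection, whatever their own labels.
#' @param spec a [scenario_spec()] with `use_person_linkage = FALSE`, or
#'   a scenario name.
#' @param readmit_window_30,readmit_window_120 inclusive window lengths
#'   in days.
#' @param revision_codes the hip revision procedure code set.
#' @param age_bands reporting age bands for the incident table.
#' @return list with `incidents` (one row per identified incident case)
#'   and `labels` (tibble `episode_id`, `incident`: one boolean per
#'   input episode).
#' @export
select_unlinked_scenario <- function(episodes, spec,
                                     readmit_window_30 = 30,
                                     readmit_window_120 = 120,
                                     revision_codes = hip_revision_codes(),
                                     age_bands = c(65, 70, 75, 80, 85)) {
  if (is.character(spec)) spec <- scenario_spec(spec)
  stopifnot(inherits(spec, "scenario_spec"))
  if (isTRUE(spec$use_person_linkage)) {
    stop("scenario '", spec$name, "' requires person linkage; use ",
         "select_reference_standard()", call. = FALSE)
  }

  incl <- rep(TRUE, nrow(episodes))
  if (spec$require_hip_fracture_dx) {
    incl <- incl & is_hip_fracture_dx(episodes$principal_diagnosis)
  }
  if (spec$require_private_residence) {
    incl <- incl & episodes$admission_source == "private_residence"
  }
  if (spec$exclude_inhospital_death) {
    incl <- incl & episodes$discharge_status != "died_in_hospital"
  }
  if (spec$exclude_nonacute) incl <- incl & episodes$care_type == "acute"
  if (spec$exclude_nonemergency) {
    incl <- incl & episodes$admission_category == "emergency"
  }
  if (spec$exclude_revision_only) {
    incl <- incl & !revision_only(episodes$procedure_codes, revision_codes)
  }

  if (spec$exclude_readmit_30d || spec$exclude_readmit_120d) {
    gap <- readmission_gap(episodes,
                           is_hip_fracture_dx(episodes$principal_diagnosis))
    if (spec$exclude_readmit_30d) {
      incl <- incl & !(!is.na(gap) & gap >= 0 & gap <= readmit_window_30)
    }
    if (spec$exclude_readmit_120d) {
      incl <- incl & !(!is.na(gap) & gap >= 0 & gap <= readmit_window_120)
    }
  }

  pseudo <- ifelse(episodes$hospital_sector == "public",
                   paste(episodes$hospital_id, episodes$hospital_patient_id,
                         sep = "/"),
                   episodes$episode_id)
  list(
    incidents = incident_case_table(episodes[incl, , drop = FALSE],
                                    pseudo[incl], age_bands),
    labels = tibble::tibble(episode_id = episodes$episode_id,
                            incident = incl)
  )
}

# days from the latest earlier discharge of the same (public hospital,
# hospital patient id) pseudo-person to this admission; NA when no
# detectable prior episode exists.  Candidates and priors are both
# restricted to `eligible` rows (the hip-fracture episodes the scenario
# selects among): a readmission is only recognisable as such when an
# earlier record for the same condition exists at that hospital.
readmission_gap <- function(episodes, eligible = rep(TRUE, nrow(episodes))) {
  gap <- rep(NA_real_, nrow(episodes))
  public <- episodes$hospital_sector == "public" & eligible
  if (!any(public)) return(gap)
  df <- data.frame(
    row = which(public),
    pseudo = paste(episodes$hospital_id[public],
                   episodes$hospital_patient_id[public], sep = "/"),
    adm = as.numeric(episodes$admission_date[public]),
    dis = as.numeric(episodes$discharge_date[public])
  )
  df <- df[order(df$pseudo, df$adm, df$dis, df$row), ]
  grp_first <- !duplicated(df$pseudo)
  prev_dis <- c(NA, utils::head(cummax_by_group(df$dis, grp_first), -1))
  prev_dis[grp_first] <- NA
  gap[df$row] <- df$adm - prev_dis
  gap
}

# running maximum restarting at each group boundary
cummax_by_group <- function(x, grp_first) {
  out <- x
  for (i in seq_along(x)[-1]) {
    if (!grp_first[i]) out[i] <- max(out[i - 1], x[i])
  }
  out
}

#' Identify incident cases from linked (person-level) data
#'
#' The reference-standard selector.  Qualifying episodes are emergency
#' admissions for acute care with a hip-fracture principal diagnosis
#' (S72.0-S72.2), admission source private residence/accommodation and
#' no revision-only procedure list; discharge status is disregarded.
#' Within each person, qualifying episodes are ordered by admission
#' date; the first founds the person's first incident event.  A later
#' qualifying episode founds a new incident if and only if its admission
#' is at least `clearance_days` after the current incident chain's last
#' discharge AND its principal external-cause triple (mechanism, place,
#' activity) differs from the current incident's in all three
#' components.  Every other hip-fracture episode of the person extends
#' the current chain (its discharge advances the clearance anchor).
#'
#' @param episodes extracted episode table.
#' @param person_assignment tibble (`episode_id`, `person_id`) covering
#'   every episode, e.g. a [link_records()] result or the truth
#'   partition.
#' @param clearance_days minimum gap between incidents (days).
#' @param use_external_cause_rule require the external-cause triple to
#'   differ? (Disabling reproduces the clearance-only sensitivity
#'   analysis.)
#' @param revision_codes,age_bands see [select_unlinked_scenario()].
#' @return list with `incidents` and `labels` as in
#'   [select_unlinked_scenario()].
#' @export
select_reference_standard <- function(episodes, person_assignment,
                                      clearance_days = 120,
                                      use_external_cause_rule = TRUE,
                                      revision_codes = hip_revision_codes(),
                                      age_bands = c(65, 70, 75, 80, 85)) {
  person <- stats::setNames(person_assignment$person_id,
                            person_assignment$episode_id)[episodes$episode_id]
  if (anyNA(person)) {
    stop(sum(is.na(person)), " episode(s) assigned to no person",
         call. = FALSE)
  }

  hip <- is_hip_fracture_dx(episodes$principal_diagnosis)
  qualifying <- hip &
    episodes$admission_source == "private_residence" &
    episodes$care_type == "acute" &
    episodes$admission_category == "emergency" &
    !revision_only(episodes$procedure_codes, revision_codes)

  incident <- rep(FALSE, nrow(episodes))
  ord <- order(person, episodes$admission_date, episodes$discharge_date,
               episodes$episode_id)
  hip_rows <- ord[hip[ord]]

  cur_person <- ""
  anchor <- -Inf
  cur_triple <- c("", "", "")
  for (i in hip_rows) {
    if (person[i] != cur_person) {
      cur_person <- person[i]
      anchor <- -Inf
      cur_triple <- c("", "", "")
      has_incident <- FALSE
    }
    adm <- as.numeric(episodes$admission_date[i])
    triple <- c(episodes$ext_mechanism[i], episodes$ext_place[i],
                episodes$ext_activity[i])
    founds <- FALSE
    if (qualifying[i]) {
      if (!has_incident) {
        founds <- TRUE
      } else if (adm - anchor >= clearance_days &&
                 (!use_external_cause_rule || all(triple != cur_triple))) {
        founds <- TRUE
      }
    }
    if (founds) {
      incident[i] <- TRUE
      has_incident <- TRUE
      anchor <- as.numeric(episodes$discharge_date[i])
      cur_triple <- triple
    } else if (has_incident) {
      anchor <- max(anchor, as.numeric(episodes$discharge_date[i]))
    }
  }

  list(
    incidents = incident_case_table(episodes[incident, , drop = FALSE],
                                    unname(person[incident]), age_bands),
    labels = tibble::tibble(episode_id = episodes$episode_id,
                            incident = incident)
  )
}
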