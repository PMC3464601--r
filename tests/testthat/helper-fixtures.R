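# Hand-built episode rows with sensible defaults, for constructing small
# deterministic fixtures in tests.
make_episodes <- function(...) {
  rows <- list(...)
  defaults <- list(
    episode_id = NA_character_,
    hospital_id = "H001",
    hospital_sector = "public",
    hospital_patient_id = "MRN00001",
    admission_date = as.Date("2006-01-10"),
    discharge_date = as.Date("2006-01-20"),
    age_at_admission = 80L,
    sex = "F",
    admission_source = "private_residence",
    care_type = "acute",
    admission_category = "emergency",
    discharge_status = "home",
    principal_diagnosis = "S72.0",
    additional_diagnoses = "",
    ext_mechanism = "W01",
    ext_place = "Y92.0",
    ext_activity = "U73.4",
    procedure_codes = "47522-00",
    key_sex = "F",
    key_dob = "1926-03-15",
    key_postcode = "3181",
    key_medicare = "2000000001",
    key_country = "AUSTRALIA"
  )
  out <- lapply(seq_along(rows), function(i) {
    r <- defaults
    r[names(rows[[i]])] <- rows[[i]]
    if (is.na(r$episode_id)) r$episode_id <- sprintf("E%06d", i)
    tibble::as_tibble(r)
  })
  dplyr::bind_rows(out)
}

truth_assignment_of <- function(truth) {
  out <- truth$episodes[c("episode_id", "true_person_id")]
  names(out)[2] <- "person_id"
  out
}

truth_labels_of <- function(truth, episodes) {
  tibble::tibble(
    episode_id = episodes$episode_id,
    incident = truth$episodes$true_incident[
      match(episodes$episode_id, truth$episodes$episode_id)]
  )
}

# nuisance-free configuration: every fracture event is a single clean
# index episode and all selectors must agree exactly with truth
degenerate_config <- function(n_persons = 2000, ...) {
  args <- list(
    n_persons = n_persons,
    transfer_prob = 0, readmission_30d_prob = 0, readmission_120d_prob = 0,
    inhospital_death_prob = 0, nonfracture_fall_rate = 0,
    second_fracture_prob = 0, nursing_home_fraction = 0,
    medicare_shared_prob = 0,
    key_corruption = corruption_spec(0, 0, 0, 0)
  )
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(simulation_config, args)
}

# memoised study-scale runs shared by calibration and acceptance tests
.fixture_env <- new.env(parent = emptyenv())

default_big_run <- function() {
  if (is.null(.fixture_env$big)) {
    cfg <- experiment_config(simulation = simulation_config(n_persons = 20000),
                             seed = 7L)
    .fixture_env$big <- run_experiment(cfg)
  }
  .fixture_env$big
}

# fully coded variant (no under-coding, no hospital-acquired flags) for
# comorbidity parameter recovery
recovery_run <- function() {
  if (is.null(.fixture_env$recovery)) {
    cfg <- simulation_config(n_persons = 20000, per_episode_coding_prob = 1,
                             hospital_acquired_prob = 0)
    sim <- simulate_cohort(cfg, 11L)
    ext <- extract_fall_injury_episodes(sim$episodes)
    ref <- select_reference_standard(ext, truth_assignment_of(sim$truth))
    rec <- comorbidity_records(ref$incidents, ext,
                               person_assignment = truth_assignment_of(sim$truth),
                               lookback = TRUE)
    .fixture_env$recovery <- list(config = cfg, sim = sim, extracted = ext,
                                  reference = ref, records = rec)
  }
  .fixture_env$recovery
}
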