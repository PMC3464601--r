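#' Simulate a synthetic episode-level discharge dataset with ground truth
#'
#' Generates a cohort of persons aged 65+ and the admitted episodes of
#' care their fall injuries produce over the study window, together with
#' complete ground-truth labels.  Every fall-related hip fracture event
#' yields one acute emergency index episode (principal diagnosis
#' S72.0-S72.2, external-cause mechanism W00-W19) and, with configured
#' probabilities, inter-hospital transfer episodes, 30-day and 31-120
#' day readmissions (including revision-procedure-only and non-acute
#' episodes), and in-hospital death on the last episode of the chain.
#' Second fracture events respect the configured admission-to-admission
#' gap distribution (median 335 days, never below the 120-day clearance
#' period) and draw a fresh external-cause triple.  Non-fracture
#' fall-injury episodes (S00-T75/T79 outside S72.0-S72.2) are also
#' emitted so that specificity has a denominator and comorbidity
#' lookback has prior records to search.
#'
#' Episodes carry the person's linkage keys as recorded at admission;
#' [simulate_cohort()] emits uncorrupted keys, and
#' [corrupt_linkage_keys()] applies the per-episode error model.
#'
#' @param config a [simulation_config()].
#' @param seed integer seed; identical `(config, seed)` give
#'   byte-identical output.
#' @return a list with elements
#'   \describe{
#'     \item{episodes}{tibble, one row per episode of care (flat,
#'       CSV-serialisable; see [write_episodes()]).}
#'     \item{truth}{a `cohort_truth` object: `$episodes` (per-episode
#'       true person, event chain and incident labels), `$persons`,
#'       `$events` and `$transfers` (sender/receiver episode pairs).}
#'   }
#' @export
simulate_cohort <- function(config, seed = 1L) {
  if (!inherits(config, "simulation_config")) {
    config <- do.call(simulation_config, config)
  }
  withr::with_seed(as.integer(seed), sim_cohort_impl(config))
}

# external-cause code pools and sampling weights
FALL_MECHANISMS <- sprintf("W%02d", 0:19)
FALL_MECH_W <- c(2, 25, 1, 1, 2, 6, 8, 5, 4, 1, 12, 1, 1, 2, 1, 1, 1, 2, 20, 15)
PLACE_CODES <- sprintf("Y92.%d", 0:9)
PLACE_W <- c(45, 10, 8, 5, 4, 4, 3, 2, 2, 17)
ACTIVITY_CODES <- sprintf("U73.%d", 0:9)
ACTIVITY_W <- c(5, 5, 8, 10, 15, 10, 8, 5, 20, 14)

HIP_FIXATION_CODES <- c("47522-00", "47528-01", "47531-00", "49315-00", "49318-00")

#' Hip revision procedure codes used by the generator and selectors
#' @return character vector of procedure codes.
#' @export
hip_revision_codes <- function() c("49324-00", "49327-00", "49346-00")

NONFRACTURE_DX <- c("S00.0", "S06.0", "S22.3", "S32.0", "S42.0", "S42.2",
                    "S52.5", "S52.6", "S62.1", "S80.0", "S92.3", "T14.9")

sample_triple <- function(n) {
  tibble::tibble(
    mech = sample(FALL_MECHANISMS, n, replace = TRUE, prob = FALL_MECH_W),
    place = sample(PLACE_CODES, n, replace = TRUE, prob = PLACE_W),
    activity = sample(ACTIVITY_CODES, n, replace = TRUE, prob = ACTIVITY_W)
  )
}

# Redraw each component from the pool excluding the previous value, so the
# new triple differs in all three components.
sample_differing_triple <- function(prev) {
  resample <- function(pool, w, old) {
    vapply(old, function(o) {
      keep <- pool != o
      sample(pool[keep], 1, prob = w[keep])
    }, "")
  }
  tibble::tibble(
    mech = resample(FALL_MECHANISMS, FALL_MECH_W, prev$mech),
    place = resample(PLACE_CODES, PLACE_W, prev$place),
    activity = resample(ACTIVITY_CODES, ACTIVITY_W, prev$activity)
  )
}

rpois_cap <- function(n, lambda, cap) pmin(stats::rpois(n, lambda), cap)

sim_cohort_impl <- function(cfg) {
  n <- cfg$n_persons
  start <- as.integer(cfg$study_start)
  end <- as.integer(cfg$study_end)

  # ---- persons ----------------------------------------------------------
  agefit <- fit_truncated_lognormal(cfg$age_q1, cfg$age_median, cfg$age_q3,
                                    cfg$age_min, cfg$age_max)
  age <- pmin(floor(rtrunc_lnorm(n, agefit$meanlog, agefit$sdlog,
                                 cfg$age_min, cfg$age_max)), cfg$age_max)
  sex <- ifelse(stats::runif(n) < cfg$female_fraction, "F", "M")
  dob <- start - round(age * 365.25 + stats::runif(n, 0, 365))
  residence <- ifelse(stats::runif(n) < cfg$nursing_home_fraction,
                      "nursing_home", "community")
  postcode_pool <- sprintf("%04d", sample(3000:3999, cfg$n_postcodes))
  postcode <- sample(postcode_pool, n, replace = TRUE)
  countries <- c("AUSTRALIA", "UNITED KINGDOM", "ITALY", "GREECE", "GERMANY",
                 "NETHERLANDS", "CHINA", "VIETNAM")
  country <- sample(countries, n, replace = TRUE,
                    prob = c(60, 12, 8, 6, 4, 3, 4, 3))
  medicare <- sprintf("2%09d", sample.int(999999999L, n))
  n_share <- floor(n * cfg$medicare_shared_prob / 2)
  if (n_share > 0) {
    pick <- sample.int(n, 2 * n_share)
    medicare[pick[seq_len(n_share) * 2]] <-
      medicare[pick[seq_len(n_share) * 2 - 1]]
  }
  n_hosp <- cfg$n_hospitals_public + cfg$n_hospitals_private
  home_public <- stats::runif(n) < cfg$public_hospital_fraction
  home_hosp <- ifelse(home_public,
                      sample.int(cfg$n_hospitals_public, n, replace = TRUE),
                      cfg$n_hospitals_public +
                        sample.int(cfg$n_hospitals_private, n, replace = TRUE))
  conds <- names(cfg$comorbidity_prevalences)
  cond_mat <- matrix(stats::runif(n * length(conds)) <
                       rep(cfg$comorbidity_prevalences, each = n),
                     nrow = n, dimnames = list(NULL, conds))

  # ---- fracture events --------------------------------------------------
  p_frac <- pmin(0.9, cfg$fracture_hazard *
                   2^((age - 80) / cfg$fracture_age_doubling))
  first <- stats::runif(n) < p_frac
  second <- first & stats::runif(n) < cfg$second_fracture_prob
  death1 <- first & !second & stats::runif(n) < cfg$inhospital_death_prob

  idx1 <- which(first)
  n1 <- length(idx1)
  prestart <- stats::runif(n1) < cfg$prestart_event_fraction
  # persons destined for a second event get their first event early enough
  # that the second always fits the window
  adm1 <- integer(n1)
  sec1 <- second[idx1]
  adm1[sec1] <- start + floor(stats::runif(sum(sec1), 0, end - 200 - start + 1))
  adm1[!sec1] <- start + floor(stats::runif(sum(!sec1), 0, end - start + 1))
  adm1[prestart] <- start - 1 - floor(stats::runif(sum(prestart), 0, 119))

  # a death event ends at the index admission: no transfer, no readmission
  ev1 <- tibble::tibble(
    person = idx1, event_no = 1L, adm = adm1,
    death = death1[idx1],
    transfer = !death1[idx1] & stats::runif(n1) < cfg$transfer_prob,
    r30 = !sec1 & !death1[idx1] & stats::runif(n1) < cfg$readmission_30d_prob,
    r120 = !sec1 & !death1[idx1] & stats::runif(n1) < cfg$readmission_120d_prob
  )
  ev1 <- dplyr::bind_cols(ev1, sample_triple(n1))
  ev1$event_id <- sprintf("V%05d-1", idx1)

  build_chain <- function(ev) {
    m <- nrow(ev)
    base_dx <- paste0(sample(c("S72.0", "S72.1", "S72.2"), m, replace = TRUE,
                             prob = c(55, 35, 10)),
                      sample(0:4, m, replace = TRUE))
    los_i <- 1L + rpois_cap(m, 7, 30)
    index <- tibble::tibble(
      person = ev$person, event_id = ev$event_id, role = "index",
      adm = ev$adm, dis = ev$adm + los_i,
      hosp = home_hosp[ev$person], dx = base_dx,
      mech = ev$mech, place = ev$place, activity = ev$activity,
      care_type = "acute", category = "emergency",
      source = ifelse(residence[ev$person] == "nursing_home",
                      "nursing_home", "private_residence"),
      status = "home",
      procedures = sample(HIP_FIXATION_CODES, m, replace = TRUE)
    )
    chain_end <- index$dis
    chain_hosp <- index$hosp

    tr <- which(ev$transfer)
    transfer <- NULL
    if (length(tr)) {
      other <- 1L + (home_hosp[ev$person[tr]] - 1L +
                       sample.int(n_hosp - 1L, length(tr), replace = TRUE)) %% n_hosp
      t_adm <- index$dis[tr] + sample(0:1, length(tr), replace = TRUE)
      t_los <- 1L + rpois_cap(length(tr), 12, 30)
      transfer <- tibble::tibble(
        person = ev$person[tr], event_id = ev$event_id[tr], role = "transfer",
        adm = t_adm, dis = t_adm + t_los,
        hosp = other, dx = base_dx[tr],
        mech = ev$mech[tr], place = ev$place[tr], activity = ev$activity[tr],
        care_type = ifelse(stats::runif(length(tr)) < 0.5,
                           "non_acute", "acute"),
        category = "non_emergency",
        source = "transfer", status = "home",
        procedures = ""
      )
      index$status[tr] <- "transfer"
      chain_end[tr] <- transfer$dis
      chain_hosp[tr] <- transfer$hosp
    }

    make_readmit <- function(rows, gaps, role) {
      k <- length(rows)
      if (!k) return(NULL)
      adm <- chain_end[rows] + gaps
      los <- 1L + rpois_cap(k, 4, 20)
      revision <- stats::runif(k) < cfg$revision_readmission_prob
      same <- stats::runif(k) < cfg$same_hospital_prob
      hosp <- ifelse(same, chain_hosp[rows],
                     1L + (chain_hosp[rows] - 1L +
                             sample.int(n_hosp - 1L, k, replace = TRUE)) %% n_hosp)
      tibble::tibble(
        person = ev$person[rows], event_id = ev$event_id[rows], role = role,
        adm = adm, dis = adm + los,
        hosp = hosp, dx = base_dx[rows],
        mech = ev$mech[rows], place = ev$place[rows],
        activity = ev$activity[rows],
        care_type = ifelse(stats::runif(k) < cfg$nonacute_episode_prob,
                           "non_acute", "acute"),
        category = ifelse(stats::runif(k) < cfg$nonemergency_readmission_prob,
                          "non_emergency", "emergency"),
        source = ifelse(residence[ev$person[rows]] == "nursing_home",
                        "nursing_home", "private_residence"),
        status = "home",
        procedures = ifelse(revision,
                            sample(hip_revision_codes(), k, replace = TRUE),
                            sample(c("", HIP_FIXATION_CODES[1]), k,
                                   replace = TRUE))
      )
    }

    r30rows <- which(ev$r30)
    readm30 <- make_readmit(r30rows, sample(1:30, length(r30rows),
                                            replace = TRUE), "readm30")
    if (!is.null(readm30)) {
      chain_end[r30rows] <- readm30$dis
      chain_hosp[r30rows] <- readm30$hosp
    }
    r120rows <- which(ev$r120)
    readm120 <- make_readmit(r120rows, sample(31:120, length(r120rows),
                                              replace = TRUE), "readm120")
    if (!is.null(readm120)) {
      chain_end[r120rows] <- readm120$dis
      chain_hosp[r120rows] <- readm120$hosp
    }

    eps <- dplyr::bind_rows(index, transfer, readm30, readm120)
    # in-hospital death lands on the last episode of the event's chain
    dead <- which(ev$death)
    if (length(dead)) {
      eps <- eps |>
        dplyr::group_by(.data$event_id) |>
        dplyr::mutate(
          status = ifelse(.data$event_id %in% ev$event_id[dead] &
                            .data$adm == max(.data$adm) &
                            .data$dis == max(.data$dis[.data$adm == max(.data$adm)]),
                          "died_in_hospital", .data$status)
        ) |>
        dplyr::ungroup()
    }
    list(episodes = eps, chain_end = chain_end)
  }

  chain1 <- build_chain(ev1)

  # ---- second events ----------------------------------------------------
  idx2 <- which(second)
  ev2 <- NULL
  chain2 <- NULL
  if (length(idx2)) {
    pos <- match(idx2, idx1)              # position of first event
    adm1_2 <- ev1$adm[pos]
    ce1 <- chain1$chain_end[pos]
    # admission-to-admission gap, lognormal truncated to fit the window
    ml <- log(cfg$second_gap_median); sl <- cfg$second_gap_sdlog
    plo <- stats::plnorm(cfg$second_gap_min, ml, sl)
    phi <- stats::plnorm(end - adm1_2, ml, sl)
    gap <- round(stats::qlnorm(stats::runif(length(idx2), plo, phi), ml, sl))
    adm2 <- pmin(pmax(adm1_2 + gap, ce1 + 121L), end)

    prev <- tibble::tibble(mech = ev1$mech[pos], place = ev1$place[pos],
                           activity = ev1$activity[pos])
    differs <- stats::runif(length(idx2)) < cfg$second_triple_differs
    trip <- sample_differing_triple(prev)
    # violation mode: repeat the first event's mechanism
    trip$mech[!differs] <- prev$mech[!differs]

    death2 <- stats::runif(length(idx2)) < cfg$inhospital_death_prob
    ev2 <- tibble::tibble(
      person = idx2, event_no = 2L, adm = adm2,
      death = death2,
      transfer = !death2 & stats::runif(length(idx2)) < cfg$transfer_prob,
      r30 = !death2 & stats::runif(length(idx2)) < cfg$readmission_30d_prob,
      r120 = !death2 & stats::runif(length(idx2)) < cfg$readmission_120d_prob,
      mech = trip$mech, place = trip$place, activity = trip$activity,
      event_id = sprintf("V%05d-2", idx2)
    )
    chain2 <- build_chain(ev2)
  }

  # ---- non-fracture fall-injury episodes --------------------------------
  k_nf <- stats::rpois(n, cfg$nonfracture_fall_rate)
  nf_person <- rep(seq_len(n), k_nf)
  m_nf <- length(nf_person)
  nonfracture <- NULL
  if (m_nf) {
    adm <- start + floor(stats::runif(m_nf, 0, end - start + 1))
    los <- rpois_cap(m_nf, 3, 20)
    same <- stats::runif(m_nf) < 0.7
    hosp <- ifelse(same, home_hosp[nf_person],
                   sample.int(n_hosp, m_nf, replace = TRUE))
    trip <- sample_triple(m_nf)
    nonfracture <- tibble::tibble(
      person = nf_person, event_id = NA_character_, role = "nonfracture",
      adm = adm, dis = adm + los, hosp = hosp,
      dx = sample(NONFRACTURE_DX, m_nf, replace = TRUE),
      mech = trip$mech, place = trip$place, activity = trip$activity,
      care_type = "acute",
      category = ifelse(stats::runif(m_nf) < 0.9, "emergency",
                        "non_emergency"),
      source = ifelse(residence[nf_person] == "nursing_home",
                      "nursing_home", "private_residence"),
      status = "home", procedures = ""
    )
  }

  eps <- dplyr::bind_rows(chain1$episodes,
                          if (!is.null(chain2)) chain2$episodes,
                          nonfracture)
  eps <- eps[eps$adm >= start & eps$adm <= end, , drop = FALSE]
  eps <- eps[order(eps$adm, eps$person, eps$dis, eps$role), , drop = FALSE]
  m <- nrow(eps)
  eps$episode_id <- sprintf("E%06d", seq_len(m))

  # ---- additional-diagnosis coding -------------------------------------
  cond_code <- condition_example_codes(default_code_map())[conds]
  if (anyNA(cond_code)) {
    stop("configuration error: `comorbidity_prevalences` names unknown to ",
         "the code map: ",
         paste(conds[is.na(cond_code)], collapse = ", "), call. = FALSE)
  }
  present <- cond_mat[eps$person, , drop = FALSE]
  coded <- present & matrix(stats::runif(m * length(conds)) <
                              cfg$per_episode_coding_prob, nrow = m)
  ade <- matrix(stats::runif(m * length(conds)) < cfg$hospital_acquired_prob,
                nrow = m)
  addl <- vapply(seq_len(m), function(i) {
    j <- which(coded[i, ])
    if (!length(j)) return("")
    pack_diagnoses(cond_code[j],
                   ifelse(ade[i, j], ONSET_ADE, ONSET_POA))
  }, "")

  ep_sex <- sex[eps$person]
  episodes <- tibble::tibble(
    episode_id = eps$episode_id,
    hospital_id = sprintf("H%03d", eps$hosp),
    hospital_sector = ifelse(eps$hosp <= cfg$n_hospitals_public,
                             "public", "private"),
    hospital_patient_id = sprintf("MRN%05d", eps$person),
    admission_date = as.Date(eps$adm, origin = "1970-01-01"),
    discharge_date = as.Date(eps$dis, origin = "1970-01-01"),
    age_at_admission = as.integer(floor((eps$adm - dob[eps$person]) / 365.25)),
    sex = ep_sex,
    admission_source = eps$source,
    care_type = eps$care_type,
    admission_category = eps$category,
    discharge_status = eps$status,
    principal_diagnosis = eps$dx,
    additional_diagnoses = addl,
    ext_mechanism = eps$mech,
    ext_place = eps$place,
    ext_activity = eps$activity,
    procedure_codes = eps$procedures,
    key_sex = ep_sex,
    key_dob = format(as.Date(dob[eps$person], origin = "1970-01-01")),
    key_postcode = postcode[eps$person],
    key_medicare = medicare[eps$person],
    key_country = country[eps$person]
  )

  # ---- ground truth -----------------------------------------------------
  person_id <- sprintf("P%05d", seq_len(n))
  events <- dplyr::bind_rows(
    ev1[c("person", "event_no", "adm", "death", "event_id")],
    if (!is.null(ev2)) ev2[c("person", "event_no", "adm", "death", "event_id")]
  )
  index_map <- eps$episode_id[eps$role == "index"]
  names(index_map) <- eps$event_id[eps$role == "index"]
  events <- tibble::tibble(
    event_id = events$event_id,
    true_person_id = person_id[events$person],
    event_no = events$event_no,
    admission_date = as.Date(events$adm, origin = "1970-01-01"),
    index_episode_id = unname(index_map[events$event_id]),
    is_second = events$event_no == 2L,
    community = residence[events$person] == "community",
    inhospital_death = events$death,
    in_window = !is.na(unname(index_map[events$event_id]))
  )
  events <- events[order(events$event_id), , drop = FALSE]

  truth_eps <- tibble::tibble(
    episode_id = eps$episode_id,
    true_person_id = person_id[eps$person],
    true_event_id = eps$event_id,
    role = eps$role,
    true_incident_event_id = ifelse(eps$role == "index", eps$event_id,
                                    NA_character_),
    true_incident = eps$role == "index" &
      residence[eps$person] == "community"
  )

  transfers <- NULL
  snd <- eps$role == "index" & eps$status %in% c("transfer", "died_in_hospital")
  # sender/receiver pairing: index discharged as transfer + its receiver
  rec <- eps[eps$role == "transfer", c("event_id", "episode_id")]
  snd_tbl <- eps[eps$role == "index" & eps$event_id %in% rec$event_id,
                 c("event_id", "episode_id")]
  transfers <- dplyr::inner_join(
    stats::setNames(snd_tbl, c("event_id", "sender_episode_id")),
    stats::setNames(rec, c("event_id", "receiver_episode_id")),
    by = "event_id"
  )

  persons <- tibble::tibble(
    true_person_id = person_id,
    sex = sex,
    age_at_start = as.integer(age),
    dob = as.Date(dob, origin = "1970-01-01"),
    residence = residence,
    postcode = postcode,
    country = country,
    medicare = medicare,
    home_hospital_id = sprintf("H%03d", home_hosp),
    home_hospital_sector = ifelse(home_hosp <= cfg$n_hospitals_public,
                                  "public", "private"),
    comorbidities = apply(cond_mat, 1,
                          function(r) paste(conds[r], collapse = ";"))
  )

  truth <- structure(
    list(episodes = truth_eps, persons = persons, events = events,
         transfers = tibble::as_tibble(transfers)),
    class = "cohort_truth"
  )
  list(episodes = episodes, truth = truth)
}

#' Corrupt the linkage keys recorded on episodes
#'
#' Applies the per-episode, independent key-error model: date-of-birth
#' perturbations (wrong day, possibly an impossible calendar date, or a
#' one-year shift), postcode changes, and missing or mis-keyed Medicare
#' surrogates.  Ground truth is unchanged.
#'
#' @param episodes episode table with uncorrupted master keys.
#' @param truth the matching `cohort_truth` (used for the postcode pool).
#' @param spec a [corruption_spec()].
#' @param seed integer seed.
#' @return the episode table with perturbed `key_*` columns.
#' @export
corrupt_linkage_keys <- function(episodes, truth, spec = corruption_spec(),
                                 seed = 1L) {
  if (!inherits(spec, "corruption_spec")) spec <- do.call(corruption_spec, spec)
  withr::with_seed(as.integer(seed), {
    m <- nrow(episodes)

    hit <- stats::runif(m) < spec$dob_error
    if (any(hit)) {
      d <- episodes$key_dob[hit]
      mode <- sample(c("day", "year"), sum(hit), replace = TRUE,
                     prob = c(0.7, 0.3))
      day <- sprintf("%02d", sample(1:31, sum(hit), replace = TRUE))
      d <- ifelse(mode == "day",
                  paste0(substr(d, 1, 8), day),
                  paste0(sprintf("%04d", as.integer(substr(d, 1, 4)) +
                                   sample(c(-1L, 1L), sum(hit), replace = TRUE)),
                         substr(d, 5, 10)))
      episodes$key_dob[hit] <- d
    }

    hit <- stats::runif(m) < spec$postcode_error
    if (any(hit)) {
      pool <- unique(truth$persons$postcode)
      episodes$key_postcode[hit] <- sample(pool, sum(hit), replace = TRUE)
    }

    miss <- stats::runif(m) < spec$medicare_missing
    episodes$key_medicare[miss] <- NA_character_
    hit <- !miss & stats::runif(m) < spec$medicare_error
    if (any(hit)) {
      med <- episodes$key_medicare[hit]
      pos <- sample(1:10, sum(hit), replace = TRUE)
      newd <- as.character(sample(0:9, sum(hit), replace = TRUE))
      substr(med, pos, pos) <- newd
      episodes$key_medicare[hit] <- med
    }
    episodes
  })
}

#' Synthetic population denominators
#'
#' Builds the population table the rate calculations divide by: one row
#' per (fiscal year, sex, age band) with the population estimate, the
#' number of nursing-home residents, and the community-dwelling
#' denominator (their difference).  Age-sex proportions equal the
#' cohort's sampling proportions, so the simulated persons are a
#' representative draw from this population.
#'
#' @param config a [simulation_config()].
#' @return tibble with columns `fiscal_year`, `sex`, `age_band`,
#'   `population_estimate`, `nursing_home_residents`,
#'   `community_denominator`.
#' @export
population_table <- function(config) {
  if (!inherits(config, "simulation_config")) {
    config <- do.call(simulation_config, config)
  }
  days <- seq(config$study_start, config$study_end, by = "day")
  years <- unique(fiscal_year(days))
  bandp <- age_band_probs(config)
  grid <- tidyr::expand_grid(
    fiscal_year = years,
    sex = c("F", "M"),
    age_band = names(bandp)
  )
  sexp <- ifelse(grid$sex == "F", config$female_fraction,
                 1 - config$female_fraction)
  pop <- round(config$population_total * sexp * bandp[grid$age_band])
  nh <- round(pop * config$nursing_home_fraction)
  tibble::tibble(
    grid,
    population_estimate = as.numeric(pop),
    nursing_home_residents = as.numeric(nh),
    community_denominator = as.numeric(pop - nh)
  )
}
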