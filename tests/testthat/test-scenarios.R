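test_that("shipped scenario flags reproduce the selection-criteria table", {
  flags <- function(nm) {
    s <- scenario_spec(nm)
    c(death = s$exclude_inhospital_death, r30 = s$exclude_readmit_30d,
      r120 = s$exclude_readmit_120d, rev = s$exclude_revision_only,
      nonacute = s$exclude_nonacute, nonemerg = s$exclude_nonemergency,
      link = s$use_person_linkage, ext = s$use_external_cause_rule)
  }
  expect_equal(flags("base"),
               c(death = TRUE, r30 = TRUE, r120 = FALSE, rev = FALSE,
                 nonacute = FALSE, nonemerg = FALSE, link = FALSE,
                 ext = FALSE))
  expect_equal(flags("S1"),
               c(death = FALSE, r30 = TRUE, r120 = FALSE, rev = FALSE,
                 nonacute = FALSE, nonemerg = FALSE, link = FALSE,
                 ext = FALSE))
  expect_equal(flags("S2"),
               c(death = TRUE, r30 = TRUE, r120 = TRUE, rev = FALSE,
                 nonacute = FALSE, nonemerg = FALSE, link = FALSE,
                 ext = FALSE))
  expect_equal(flags("S3"),
               c(death = TRUE, r30 = TRUE, r120 = TRUE, rev = TRUE,
                 nonacute = TRUE, nonemerg = TRUE, link = FALSE, ext = FALSE))
  # S4 is S3 with the death exclusion dropped
  expect_equal(flags("S4"), replace(flags("S3"), "death", FALSE))
  expect_equal(flags("reference"),
               c(death = FALSE, r30 = TRUE, r120 = TRUE, rev = TRUE,
                 nonacute = TRUE, nonemerg = TRUE, link = TRUE, ext = TRUE))
  # every shipped spec requires hip fracture dx + private residence
  for (nm in shipped_scenarios()) {
    s <- scenario_spec(nm)
    expect_true(s$require_hip_fracture_dx)
    expect_true(s$require_private_residence)
  }
  expect_error(scenario_spec("S9"), "base")
})

test_that("episode extraction applies the three entry conditions", {
  eps <- make_episodes(
    list(ext_mechanism = "W05", principal_diagnosis = "S72.1",
         age_at_admission = 70L),                       # retained
    list(ext_mechanism = "W10", principal_diagnosis = "T80",
         age_at_admission = 80L),                       # dx out of range
    list(ext_mechanism = "W00", principal_diagnosis = "S72.0",
         age_at_admission = 64L),                       # under 65
    list(ext_mechanism = "X59", principal_diagnosis = "S72.0"),  # not a fall
    list(ext_mechanism = "W06", principal_diagnosis = "T79.6")   # retained
  )
  out <- extract_fall_injury_episodes(eps)
  expect_equal(out$episode_id, eps$episode_id[c(1, 5)])

  malformed <- make_episodes(list(principal_diagnosis = "???"))
  expect_message(res <- extract_fall_injury_episodes(malformed), "malformed")
  expect_equal(nrow(res), 0)
})

test_that("hip fracture filter keeps S72.0-S72.2 only", {
  eps <- make_episodes(list(principal_diagnosis = "S72.1"),
                       list(principal_diagnosis = "S72.3"),
                       list(principal_diagnosis = "S71.9"))
  expect_equal(hip_fracture_filter(eps)$episode_id, eps$episode_id[1])
})

test_that("in-hospital deaths separate the base case from S1", {
  eps <- make_episodes(list(discharge_status = "died_in_hospital"))
  expect_false(select_unlinked_scenario(eps, "base")$labels$incident)
  expect_true(select_unlinked_scenario(eps, "S1")$labels$incident)
})

test_that("readmissions are only detectable at the same public hospital", {
  same <- make_episodes(
    list(admission_date = as.Date("2006-01-01"),
         discharge_date = as.Date("2006-01-10")),
    list(admission_date = as.Date("2006-01-30"),   # 20 days after discharge
         discharge_date = as.Date("2006-02-05"))
  )
  lab <- select_unlinked_scenario(same, "base")$labels
  expect_equal(lab$incident, c(TRUE, FALSE))

  other <- same
  other$hospital_id[2] <- "H002"                   # different hospital
  expect_equal(select_unlinked_scenario(other, "base")$labels$incident,
               c(TRUE, TRUE))

  private <- same
  private$hospital_sector <- "private"             # no site identifier
  expect_equal(select_unlinked_scenario(private, "base")$labels$incident,
               c(TRUE, TRUE))

  # gap 31-120: undetected by base, excluded by S2
  later <- same
  later$admission_date[2] <- as.Date("2006-03-01") # gap 50 days
  later$discharge_date[2] <- as.Date("2006-03-07")
  expect_equal(select_unlinked_scenario(later, "base")$labels$incident,
               c(TRUE, TRUE))
  expect_equal(select_unlinked_scenario(later, "S2")$labels$incident,
               c(TRUE, FALSE))

  # prior records that are not hip fractures do not trigger the exclusion
  nonhip <- same
  nonhip$principal_diagnosis[1] <- "S52.5"
  expect_equal(select_unlinked_scenario(nonhip, "base")$labels$incident,
               c(FALSE, TRUE))
})

test_that("revision-only, non-acute and non-emergency episodes fall to S3", {
  eps <- make_episodes(
    list(procedure_codes = "49324-00"),                    # revision only
    list(procedure_codes = "49324-00;47522-00"),           # revision + fixation
    list(care_type = "non_acute", hospital_id = "H003"),
    list(admission_category = "non_emergency", hospital_id = "H004")
  )
  base <- select_unlinked_scenario(eps, "base")$labels$incident
  s3 <- select_unlinked_scenario(eps, "S3")$labels$incident
  expect_equal(base, rep(TRUE, 4))
  expect_equal(s3, c(FALSE, TRUE, FALSE, FALSE))
})

test_that("the clearance period and external-cause rule separate incidents", {
  two_adm <- function(gap_days, mech2 = "W10", place2 = "Y92.9",
                      act2 = "U73.8") {
    d1 <- as.Date("2006-01-01")
    make_episodes(
      list(admission_date = d1, discharge_date = d1 + 9),
      list(admission_date = d1 + 9 + gap_days,
           discharge_date = d1 + 19 + gap_days, hospital_id = "H002",
           ext_mechanism = mech2, ext_place = place2, ext_activity = act2)
    )
  }
  assign_one <- function(eps) tibble::tibble(episode_id = eps$episode_id,
                                             person_id = "P1")
  # 90 days apart: inside the clearance period, one incident
  eps <- two_adm(90)
  expect_equal(sum(select_reference_standard(eps,
                                             assign_one(eps))$labels$incident),
               1)
  # 335 days apart, all three external-cause codes differ: two incidents
  eps <- two_adm(335)
  expect_equal(sum(select_reference_standard(eps,
                                             assign_one(eps))$labels$incident),
               2)
  # 200 days apart but identical triple: still one incident
  eps <- two_adm(200, mech2 = "W01", place2 = "Y92.0", act2 = "U73.4")
  expect_equal(sum(select_reference_standard(eps,
                                             assign_one(eps))$labels$incident),
               1)
  # 200 days apart, only two components differ: one incident
  eps <- two_adm(200, mech2 = "W10", place2 = "Y92.9", act2 = "U73.4")
  expect_equal(sum(select_reference_standard(eps,
                                             assign_one(eps))$labels$incident),
               1)
  # ... unless the external-cause rule is switched off
  expect_equal(sum(select_reference_standard(
    eps, assign_one(eps), use_external_cause_rule = FALSE)$labels$incident), 2)
  # exactly 120 days satisfies the clearance bound
  eps <- two_adm(120)
  expect_equal(sum(select_reference_standard(eps,
                                             assign_one(eps))$labels$incident),
               2)
  expect_equal(sum(select_reference_standard(eps, assign_one(eps),
                                             clearance_days = 121
                                             )$labels$incident), 1)
})

test_that("reference standard disregards discharge status but not care type", {
  eps <- make_episodes(
    list(discharge_status = "died_in_hospital"),
    list(care_type = "non_acute", hospital_id = "H002",
         admission_date = as.Date("2007-01-01"),
         discharge_date = as.Date("2007-01-05"))
  )
  assign <- tibble::tibble(episode_id = eps$episode_id,
                           person_id = c("P1", "P2"))
  lab <- select_reference_standard(eps, assign)$labels
  expect_equal(lab$incident, c(TRUE, FALSE))
  # unassigned episodes are an error
  expect_error(select_reference_standard(eps, assign[1, ]), "assigned")
})

test_that("selection counts are monotone in the exclusion flags", {
  ex <- default_big_run()
  n <- vapply(ex$scenarios, function(s) nrow(s$incidents), 0)
  expect_gte(n[["S1"]], n[["base"]])
  expect_gte(n[["base"]], n[["S2"]])
  expect_gte(n[["S2"]], n[["S3"]])
  expect_gte(n[["S4"]], n[["S3"]])
})

test_that("every extracted episode receives exactly one label per scenario", {
  ex <- default_big_run()
  for (s in c(ex$scenarios, list(ex$reference_linked))) {
    expect_equal(nrow(s$labels), nrow(ex$extracted))
    expect_false(anyNA(s$labels$incident))
    expect_equal(anyDuplicated(s$labels$episode_id), 0)
  }
})

test_that("selection is idempotent on its own output", {
  ex <- default_big_run()
  sel1 <- ex$scenarios$base
  chosen <- ex$extracted[ex$extracted$episode_id %in%
                           sel1$incidents$index_episode_id, ]
  sel2 <- select_unlinked_scenario(chosen, "base")
  expect_true(all(sel2$labels$incident))

  ref1 <- ex$reference_truth
  chosen_ref <- ex$extracted[ex$extracted$episode_id %in%
                               ref1$incidents$index_episode_id, ]
  assign <- truth_assignment_of(ex$truth)
  ref2 <- select_reference_standard(chosen_ref, assign)
  expect_true(all(ref2$labels$incident))
})

test_that("with truth linkage and honoured assumptions the reference
           standard recovers exactly the generator's incident events", {
  sim <- simulate_cohort(simulation_config(n_persons = 4000), seed = 29)
  ext <- extract_fall_injury_episodes(sim$episodes)
  ref <- select_reference_standard(ext, truth_assignment_of(sim$truth))
  expect_identical(ref$labels$incident, truth_labels_of(sim$truth, ext)$incident)
})

test_that("nuisance-free data make every scenario agree exactly with truth", {
  sim <- simulate_cohort(degenerate_config(second_fracture_prob = 0.023),
                         seed = 37)
  ext <- extract_fall_injury_episodes(sim$episodes)
  truth_lab <- truth_labels_of(sim$truth, ext)$incident
  for (nm in c("base", "S1", "S2", "S3", "S4")) {
    expect_identical(select_unlinked_scenario(ext, nm)$labels$incident,
                     truth_lab)
  }
  ref <- select_reference_standard(ext, truth_assignment_of(sim$truth))
  expect_identical(ref$labels$incident, truth_lab)
})
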