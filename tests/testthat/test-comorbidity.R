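test_that("the shipped code map loads and rejects undeclared overlaps", {
  map <- default_code_map()
  expect_true(all(c("dementia", "chf", "renal", "osteoporosis", "delirium")
                  %in% map$condition))
  # overlapping prefixes across unrelated conditions are rejected
  bad <- tempfile(fileext = ".csv")
  writeLines(c("condition,icd10_prefix,charlson,weight",
               "dementia,F00,TRUE,1",
               "delirium,F00.1,FALSE,0"), bad)
  expect_error(load_code_map(bad), "overlap")
})

test_that("the Deyo index sums weights with severity hierarchies", {
  expect_equal(charlson_index(character()), 0)
  # hand-summed from the shipped weight table: dementia 1 + chf 1
  expect_equal(charlson_index(c("dementia", "chf")), 2)
  # hierarchy: only the complicated form's weight counts
  expect_equal(charlson_index(c("diabetes", "diabetes_complications")), 2)
  expect_equal(charlson_index(c("liver_mild", "liver_severe")), 3)
  expect_equal(charlson_index(c("cancer", "metastatic")), 6)
  # risk factors carry no weight
  expect_equal(charlson_index(c("osteoporosis", "delirium")), 0)
  expect_equal(charlson_index(c("renal", "paraplegia", "mi")), 5)
  expect_error(charlson_index("gout"), "unknown condition")
})

lookback_fixture <- function() {
  # prior fall episode carries dementia; index carries delirium as a
  # hospital-acquired (arose during episode) diagnosis
  make_episodes(
    list(episode_id = "E000001", principal_diagnosis = "S52.5",
         admission_date = as.Date("2005-09-01"),
         discharge_date = as.Date("2005-09-03"),
         additional_diagnoses = pack_diagnoses("F00.0",
                                               "present_on_admission")),
    list(episode_id = "E000002", principal_diagnosis = "S72.1",
         admission_date = as.Date("2006-03-01"),
         discharge_date = as.Date("2006-03-12"),
         additional_diagnoses = pack_diagnoses(c("F05.9", "I50.0"),
                                               c("arose_during_episode",
                                                 "present_on_admission")))
  )
}

test_that("lookback finds conditions coded only on earlier records", {
  eps <- lookback_fixture()
  incident <- tibble::tibble(index_episode_id = "E000002", person_id = "P1")
  with_lb <- ascertain_comorbidities(incident, eps, lookback_enabled = TRUE)
  without <- ascertain_comorbidities(incident, eps, lookback_enabled = FALSE)
  expect_true(with_lb$dementia)
  expect_false(without$dementia)
  expect_equal(with_lb$lookback_days_available, 181)
  expect_equal(without$lookback_days_available, 0)
  # chf is flagged present-on-admission on the index record: always found
  expect_true(with_lb$chf && without$chf)
})

test_that("hospital-acquired (arose-during-episode) codes never count", {
  eps <- lookback_fixture()
  incident <- tibble::tibble(index_episode_id = "E000002", person_id = "P1")
  rec <- ascertain_comorbidities(incident, eps, lookback_enabled = TRUE)
  expect_false(rec$delirium)
  expect_equal(rec$charlson_index, 2)  # dementia + chf
})

test_that("the index record is the first multiday record of the chain", {
  # same-day index episode; the multiday transfer episode carries the code
  eps <- make_episodes(
    list(episode_id = "E000001", admission_date = as.Date("2006-01-10"),
         discharge_date = as.Date("2006-01-10"),
         discharge_status = "transfer"),
    list(episode_id = "E000002", admission_date = as.Date("2006-01-11"),
         discharge_date = as.Date("2006-01-25"), hospital_id = "H002",
         admission_source = "transfer",
         additional_diagnoses = pack_diagnoses("N18.9",
                                               "present_on_admission"))
  )
  incident <- tibble::tibble(index_episode_id = "E000001", person_id = "P1")
  rec <- ascertain_comorbidities(incident, eps, lookback_enabled = FALSE)
  expect_true(rec$renal)
})

test_that("empty diagnosis lists give empty records and index zero", {
  eps <- make_episodes(list(), list(episode_id = "E000002"))
  incident <- tibble::tibble(index_episode_id = "E000001", person_id = "P1")
  rec <- ascertain_comorbidities(incident, eps)
  conds <- unique(default_code_map()$condition)
  expect_false(any(unlist(rec[conds])))
  expect_equal(rec$charlson_index, 0)
})

test_that("prevalence tables report Wilson intervals and stable ranks", {
  conds <- unique(default_code_map()$condition)
  records <- tibble::as_tibble(
    c(list(incident_id = sprintf("E%03d", 1:10), person_id = sprintf("P%d", 1:10)),
      stats::setNames(rep(list(rep(FALSE, 10)), length(conds)), conds))
  )
  records$renal <- c(rep(TRUE, 3), rep(FALSE, 7))
  records$dementia <- rep(TRUE, 10)
  records$osteoporosis <- c(rep(TRUE, 3), rep(FALSE, 7))  # tie with renal
  records$charlson_index <- ifelse(records$renal, 2, 0) +
    ifelse(records$dementia, 1, 0)

  pt <- prevalence_table(records)
  expect_equal(pt$prevalence[pt$condition == "dementia"], 100)
  renal <- pt[pt$condition == "renal", ]
  expect_equal(renal$prevalence, 30)
  # frozen hand computation of the Wilson 95% bounds for 3/10
  expect_equal(renal$ci_lower, 10.77913, tolerance = 1e-5)
  expect_equal(renal$ci_upper, 60.32219, tolerance = 1e-5)
  # deterministic alphabetical tie-break: osteoporosis before renal
  expect_lt(pt$rank[pt$condition == "osteoporosis"],
            pt$rank[pt$condition == "renal"])
  # summary rows dominate any single condition
  any_cm <- pt$prevalence[pt$condition == "any_comorbidity"]
  expect_gte(any_cm, max(pt$prevalence[!is.na(pt$rank)]))
  expect_equal(pt$prevalence[pt$condition == "any_charlson"], 100)
  # top-share statistic: dementia (10) + renal (3) + osteoporosis (3) of 16
  expect_equal(top_share(pt, 3), 100)
  expect_equal(top_share(pt, 1), 100 * 10 / 16)

  expect_error(prevalence_table(records[0, ]), "empty")
})

test_that("enabling lookback never decreases any prevalence", {
  sim <- simulate_cohort(simulation_config(n_persons = 3000), seed = 43)
  ext <- extract_fall_injury_episodes(sim$episodes)
  assign <- truth_assignment_of(sim$truth)
  ref <- select_reference_standard(ext, assign)
  with_lb <- comorbidity_records(ref$incidents, ext, assign, lookback = TRUE)
  without <- comorbidity_records(ref$incidents, ext, assign, lookback = FALSE)
  conds <- unique(default_code_map()$condition)
  expect_true(all(colSums(as.matrix(with_lb[conds])) >=
                    colSums(as.matrix(without[conds]))))
  # per-record monotonicity, not just in aggregate
  expect_true(all(as.matrix(with_lb[conds]) >= as.matrix(without[conds])))
})

test_that("under-coding biases prevalence downward, lookback recovers some", {
  sim <- simulate_cohort(simulation_config(n_persons = 8000), seed = 47)
  ext <- extract_fall_injury_episodes(sim$episodes)
  assign <- truth_assignment_of(sim$truth)
  ref <- select_reference_standard(ext, assign)
  with_lb <- comorbidity_records(ref$incidents, ext, assign, lookback = TRUE)
  without <- comorbidity_records(ref$incidents, ext, assign, lookback = FALSE)
  cfg_prev <- simulation_config(n_persons = 1)$comorbidity_prevalences
  common <- names(cfg_prev)[cfg_prev >= 0.01]
  est <- function(rec) colMeans(as.matrix(rec[common]))
  expect_true(all(est(without) <= est(with_lb)))
  # estimated (under-coded) prevalence sits below truth for most conditions
  expect_gte(mean(est(with_lb) <= cfg_prev[common]), 0.75)
})
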