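#' Run the full linked-versus-unlinked experiment
#'
#' Orchestrates simulate -> corrupt keys -> standardise -> link ->
#' extract -> select (reference standard plus every configured unlinked
#' scenario) -> comorbidity -> evaluate, as one reproducible experiment
#' governed by a single seed.  Two reference standards are evaluated:
#' one built on the generator's true person partition and one on the
#' linkage output, so algorithmic selection bias can be separated from
#' linkage error (a production linkage would be taken as ground truth;
#' here it need not be).
#'
#' @param config an [experiment_config()].
#' @return an object of class `hdd_experiment`: a list with the episode
#'   table, ground truth, linkage result and quality, per-scenario
#'   labels and incident tables, accuracy tables against both reference
#'   standards, comorbidity prevalence tables and comparisons, the rate
#'   tables, and a stage log (`$log`).
#' @export
run_experiment <- function(config = experiment_config()) {
  stopifnot(inherits(config, "experiment_config"))
  sim_cfg <- config$simulation
  seed <- config$seed
  log <- list()
  note <- function(stage, n_in, n_out, detail = "") {
    log[[length(log) + 1]] <<- tibble::tibble(
      stage = stage, n_in = n_in, n_out = n_out, detail = detail)
  }

  sim <- simulate_cohort(sim_cfg, seed)
  note("simulate", sim_cfg$n_persons, nrow(sim$episodes),
       sprintf("%d true incident events",
               sum(sim$truth$events$community & sim$truth$events$in_window)))

  episodes <- corrupt_linkage_keys(sim$episodes, sim$truth,
                                   sim_cfg$key_corruption, seed + 1L)
  episodes <- standardise_keys(episodes)
  note("corrupt+standardise", nrow(sim$episodes), nrow(episodes))

  linkage <- link_records(episodes, config$passes)
  quality <- linkage_quality(linkage, sim$truth)
  note("link", nrow(episodes), length(unique(linkage$person_id)),
       sprintf("FP %.4f FN %.4f", quality$false_positive_rate,
               quality$false_negative_rate))

  extracted <- extract_fall_injury_episodes(episodes)
  note("extract", nrow(episodes), nrow(extracted))

  truth_assignment <- sim$truth$episodes[c("episode_id", "true_person_id")]
  names(truth_assignment)[2] <- "person_id"
  ref_truth <- select_reference_standard(extracted, truth_assignment,
                                         age_bands = sim_cfg$age_bands)
  ref_linked <- select_reference_standard(extracted, linkage,
                                          age_bands = sim_cfg$age_bands)
  note("reference_standard", nrow(extracted), nrow(ref_linked$incidents),
       sprintf("%d on truth partition", nrow(ref_truth$incidents)))

  scenarios <- lapply(config$scenarios, function(nm) {
    select_unlinked_scenario(extracted, scenario_spec(nm),
                             age_bands = sim_cfg$age_bands)
  })
  names(scenarios) <- config$scenarios
  for (nm in config$scenarios) {
    note(paste0("select_", nm), nrow(extracted),
         nrow(scenarios[[nm]]$incidents))
  }

  accuracy <- function(ref) {
    dplyr::bind_rows(lapply(config$scenarios, function(nm) {
      accuracy_measures(confusion(ref$labels, scenarios[[nm]]$labels),
                        scenario = nm, ci_method = config$ci_method)
    }))
  }
  accuracy_vs_linked <- accuracy(ref_linked)
  accuracy_vs_truth <- accuracy(ref_truth)

  cmap <- default_code_map()
  linked_records <- comorbidity_records(ref_linked$incidents, extracted,
                                        person_assignment = linkage,
                                        code_map = cmap, lookback = TRUE)
  linked_prevalence <- prevalence_table(linked_records, cmap,
                                        ci_method = config$ci_method)
  scenario_prevalence <- lapply(scenarios, function(s) {
    prevalence_table(
      comorbidity_records(s$incidents, extracted, code_map = cmap),
      cmap, ci_method = config$ci_method)
  })
  prevalence_compare <- lapply(scenario_prevalence, function(p) {
    compare_prevalence(linked_prevalence, p)
  })
  note("comorbidity", nrow(ref_linked$incidents), nrow(linked_prevalence))

  population <- population_table(sim_cfg)
  rates <- age_specific_rates(ref_linked$incidents, population)
  std_pop <- population[population$fiscal_year == population$fiscal_year[1], ] |>
    dplyr::group_by(.data$age_band) |>
    dplyr::summarise(population = sum(.data$population_estimate),
                     .groups = "drop")
  std_rates <- direct_standardise(rates, std_pop)
  note("rates", nrow(rates), nrow(std_rates))

  structure(list(
    config = config,
    episodes = episodes,
    truth = sim$truth,
    linkage = linkage,
    linkage_quality = quality,
    extracted = extracted,
    reference_truth = ref_truth,
    reference_linked = ref_linked,
    scenarios = scenarios,
    accuracy_vs_linked = accuracy_vs_linked,
    accuracy_vs_truth = accuracy_vs_truth,
    linked_prevalence = linked_prevalence,
    scenario_prevalence = scenario_prevalence,
    prevalence_compare = prevalence_compare,
    population = population,
    rates = rates,
    std_rates = std_rates,
    log = dplyr::bind_rows(log)
  ), class = "hdd_experiment")
}

#' @export
print.hdd_experiment <- function(x, ...) {
  cat("Linked vs unlinked discharge-data experiment\n")
  cat(sprintf("  persons: %d, episodes: %d, extracted fall-injury episodes: %d\n",
              x$config$simulation$n_persons, nrow(x$episodes),
              nrow(x$extracted)))
  cat(sprintf("  linkage: FP %.4f, FN %.4f\n",
              x$linkage_quality$false_positive_rate,
              x$linkage_quality$false_negative_rate))
  cat(sprintf("  reference standard: %d incidents (linked), %d (truth)\n",
              nrow(x$reference_linked$incidents),
              nrow(x$reference_truth$incidents)))
  acc <- x$accuracy_vs_linked
  for (i in seq_len(nrow(acc))) {
    cat(sprintf("  %-5s N=%5d overestimation %5.1f%% sens %.1f%% spec %.1f%% PPV %.1f%% NPV %.1f%%\n",
                acc$scenario[i], acc$n_scenario[i], acc$overestimation[i],
                acc$sensitivity[i], acc$specificity[i], acc$ppv[i],
                acc$npv[i]))
  }
  invisible(x)
}
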