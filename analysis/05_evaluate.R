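#!/usr/bin/env Rscript
# Stage 5: evaluation.
#
# Accuracy of each unlinked scenario against the reference standard
# (sensitivity, specificity, PPV, NPV with Wilson intervals, and
# overestimation of the incident count), computed against both the
# linkage-based and the truth-partition reference so linkage error can
# be separated from selection bias; age-specific and directly
# standardised admission rates from the linked incidents.

suppressMessages(library(hipfraclink))
suppressMessages(library(dplyr))

labels <- readr::read_csv("results/labels.csv", show_col_types = FALSE)
cfg <- read_experiment_config("results/experiment_config.yaml")

lab <- function(col) tibble::tibble(episode_id = labels$episode_id,
                                    incident = labels[[col]])
accuracy <- function(ref_col) {
  bind_rows(lapply(cfg$scenarios, function(nm) {
    accuracy_measures(confusion(lab(ref_col), lab(nm)), scenario = nm,
                      ci_method = cfg$ci_method)
  }))
}

acc_linked <- accuracy("ref_linked")
acc_truth <- accuracy("ref_truth")
readr::write_csv(acc_linked, "results/accuracy_vs_linked.csv")
readr::write_csv(acc_truth, "results/accuracy_vs_truth.csv")

cat("accuracy against the linked reference standard:\n")
for (i in seq_len(nrow(acc_linked))) {
  with(acc_linked[i, ], cat(sprintf(
    "  %-5s N=%5d over %5.1f%%  sens %.1f%% (%.1f-%.1f)  spec %.1f%%  PPV %.1f%%  NPV %.1f%%\n",
    scenario, n_scenario, overestimation, sensitivity, sens_lower,
    sens_upper, specificity, ppv, npv)))
}

population <- readr::read_csv("results/population.csv",
                              show_col_types = FALSE)
incidents <- readr::read_csv("results/incidents_reference.csv",
                             show_col_types = FALSE)
rates <- age_specific_rates(incidents, population)
readr::write_csv(rates, "results/rates.csv")

std_pop <- population |>
  filter(fiscal_year == "2005/06") |>
  group_by(age_band) |>
  summarise(population = sum(population_estimate), .groups = "drop")
std <- direct_standardise(rates, std_pop)
readr::write_csv(std, "results/std_rates.csv")

cat("directly standardised admission rates per 100,000 community-dwelling 65+:\n")
for (i in seq_len(nrow(std))) {
  cat(sprintf("  %s: %.1f\n", std$fiscal_year[i], std$std_rate_per_100k[i]))
}
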