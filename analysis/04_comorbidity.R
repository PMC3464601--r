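#!/usr/bin/env Rscript
# Stage 4: comorbidity ascertainment.
#
# Deyo-Charlson conditions plus five fall/fracture risk factors, from
# present-on-admission diagnosis codes.  The linked pathway searches the
# incident's index record plus the person's earlier fall-related records
# (lookback); the unlinked pathways see only the identified episode.
# Writes the prevalence table per data source and the pairwise
# comparisons against the linked estimates.

suppressMessages(library(hipfraclink))

episodes <- standardise_keys(read_episodes("results/episodes.csv"))
linkage <- readr::read_csv("results/linkage.csv", show_col_types = FALSE)
cfg <- read_experiment_config("results/experiment_config.yaml")
extracted <- extract_fall_injury_episodes(episodes)

linked_inc <- readr::read_csv("results/incidents_reference.csv",
                              show_col_types = FALSE)
linked_rec <- comorbidity_records(linked_inc, extracted,
                                  person_assignment = linkage,
                                  lookback = TRUE)
linked_prev <- prevalence_table(linked_rec, ci_method = cfg$ci_method)
readr::write_csv(linked_prev, "results/prevalence_reference.csv")

lb <- linked_rec$lookback_days_available
cat(sprintf("linked pathway: %d incidents; median lookback %0.f days among the %d with prior records\n",
            nrow(linked_rec), median(lb[lb > 0]), sum(lb > 0)))
cat(sprintf("any Charlson comorbidity: %.1f%%; any comorbidity: %.1f%%; top-3 share %.1f%%\n",
            linked_prev$prevalence[linked_prev$condition == "any_charlson"],
            linked_prev$prevalence[linked_prev$condition == "any_comorbidity"],
            top_share(linked_prev, 3)))

for (nm in cfg$scenarios) {
  inc <- readr::read_csv(sprintf("results/incidents_%s.csv", nm),
                         show_col_types = FALSE)
  prev <- prevalence_table(comorbidity_records(inc, extracted),
                           ci_method = cfg$ci_method)
  readr::write_csv(prev, sprintf("results/prevalence_%s.csv", nm))
  cmp <- compare_prevalence(linked_prev, prev)
  readr::write_csv(cmp, sprintf("results/prevalence_compare_%s.csv", nm))
  lower <- sum(cmp$difference < 0)
  cat(sprintf("%-5s any comorbidity %.1f%%; %d of %d conditions estimated below the linked value\n",
              nm, prev$prevalence[prev$condition == "any_comorbidity"],
              lower, nrow(cmp)))
}
cat("written: results/prevalence_*.csv, results/prevalence_compare_*.csv\n")
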