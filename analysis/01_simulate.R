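#!/usr/bin/env Rscript
# Stage 1: generate the synthetic episode-level discharge dataset.
#
# Simulates 20,000 persons aged 65+ over fiscal years 2005/06-2007/08,
# emits their fall-injury episodes of care with ground-truth labels,
# applies the per-episode linkage-key error model, and writes everything
# under results/ for the later stages.

suppressMessages(library(hipfraclink))

seed <- 2006L
dir.create("results", showWarnings = FALSE)

cfg <- experiment_config(simulation = simulation_config(n_persons = 20000),
                         seed = seed)
write_experiment_config(cfg, "results/experiment_config.yaml")

sim <- simulate_cohort(cfg$simulation, seed)
episodes <- corrupt_linkage_keys(sim$episodes, sim$truth,
                                 cfg$simulation$key_corruption, seed + 1L)

write_episodes(episodes, "results/episodes.csv")
write_truth(sim$truth, "results/truth")
readr::write_csv(population_table(cfg$simulation), "results/population.csv")

ev <- sim$truth$events
per_person <- tapply(ev$event_no, ev$true_person_id, max)
cat(sprintf("persons: %d; episodes of care: %d\n",
            cfg$simulation$n_persons, nrow(episodes)))
cat(sprintf("fractured persons: %d; incident events: %d (%.1f%% with a second fracture)\n",
            length(per_person), nrow(ev), 100 * mean(per_person == 2)))
cat(sprintf("in-hospital deaths: %d; transfer pairs: %d\n",
            sum(ev$inhospital_death), nrow(sim$truth$transfers)))
cat("written: results/episodes.csv, results/truth/, results/population.csv\n")
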