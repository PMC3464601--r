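#!/usr/bin/env Rscript
# Stage 2: internal linkage of the episode dataset.
#
# Standardises the person-identifying keys, collapses episodes to
# persons by stepwise deterministic matching, and scores the resulting
# partition against ground truth (transfer-pair false negatives and
# matched-pair false positives).

suppressMessages(library(hipfraclink))

episodes <- standardise_keys(read_episodes("results/episodes.csv"))
truth <- read_truth("results/truth")
cfg <- read_experiment_config("results/experiment_config.yaml")

linkage <- link_records(episodes, cfg$passes)
readr::write_csv(linkage, "results/linkage.csv")

q <- linkage_quality(linkage, truth)
cat(sprintf("episodes: %d -> linked persons: %d\n",
            nrow(episodes), length(unique(linkage$person_id))))
cat(sprintf("false positive rate: %.2f%% of %d matched pairs\n",
            100 * q$false_positive_rate, q$n_matched_pairs))
cat(sprintf("false negative rate: %.1f%% of %d transfer pairs\n",
            100 * q$false_negative_rate, q$n_transfer_pairs))
print(attr(linkage, "merges"))
cat("written: results/linkage.csv\n")
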