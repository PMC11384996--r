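#!/usr/bin/env Rscript

# Stage 1 — synthesise the experiment.
#
# Generates the hybrid-search trial table (110 participants x 112 trials,
# set sizes {1,2,4,8} crossed for memory and visual sets, 50% context and
# 50% target presence, DDM-generated responses with calibrated participant
# heterogeneity) plus the change-detection and go/no-go tables, and writes
# them under results/ with JSON manifests.

library(hybridsearch)

seed <- 20260+1
dir.create("results", showWarnings = FALSE)

cfg <- generator_config()
trials <- generate_experiment(cfg, seed = seed)
write_generated(as.data.frame(trials), "results/trials.csv", seed, cfg)

cdt <- generate_cdt(cfg, seed = seed + 1)
write_generated(cdt, "results/cdt.csv", seed + 1, cfg)

gng <- generate_gng(cfg, seed = seed + 2)
write_generated(gng, "results/gng.csv", seed + 2, cfg)

acc <- mean(trials$correct, na.rm = TRUE)
cat(sprintf("hybrid search: %d trials, %d timeouts, overall accuracy %.1f%%\n",
            nrow(trials), sum(trials$response == "none"), 100 * acc))
cat(sprintf("change detection: %d trials; go/no-go: %d trials\n",
            nrow(cdt), nrow(gng)))
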