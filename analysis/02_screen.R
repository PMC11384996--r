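#!/usr/bin/env Rscript

# Stage 2 — data cleaning.
#
# Applies the pre-analysis rules to the simulated experiment: exclusion of
# participants with accuracy 3 SD below the mean (computed on raw data),
# per-condition stimulus screening (one-way ANOVA, F > 20 and p < 0.05,
# Tukey HSD, at most one discard per cell), and the RT-analysis filter
# (drop timeouts, keep correct trials only, retain sub-200 ms responses).

library(hybridsearch)

trials <- read_trials("results/trials.csv")

excl <- exclude_low_accuracy_participants(trials)
cat(sprintf("low-accuracy exclusions (3 SD rule): %s\n",
            if (length(excl$excluded)) paste(excl$excluded, collapse = ", ")
            else "none"))

scr <- screen_stimuli(excl$trials)
cat(sprintf("stimulus screening: %d cell(s) triggered, discarded: %s\n",
            sum(vapply(scr$log, function(e) !isTRUE(e$skipped) &&
                         !is.na(e$discarded), logical(1))),
            if (length(scr$discarded)) paste(scr$discarded, collapse = ", ")
            else "none"))

clean <- filter_for_rt_analysis(scr$trials)
prov <- provenance(clean)
last <- prov[[length(prov)]]
cat(sprintf("RT filter: %d timeouts and %d incorrect trials removed; %d rows kept\n",
            last$removed$timeouts, last$removed$incorrect, nrow(clean)))

write_trials(clean, "results/trials_clean.csv")
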