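#!/usr/bin/env Rscript
# Simulate the study cohort and one raw ABR recording per illustration.
#
# Generates the synthetic cohort (n = 118: 26 young / 26 middle-aged /
# 66 elderly) with the calibrated age, hearing, wave V and cognition models,
# plus one synthetic epoch set, and writes both under results/.

suppressPackageStartupMessages(library(abrcog))

seed <- 20260925L
dir.create("results", showWarnings = FALSE)

g <- generate_cohort(cohort_params(seed = seed))
write_cohort(g$cohort, "results/cohort.csv")
cat(sprintf("cohort: %d participants (%s)\n", nrow(g$cohort),
            paste(sprintf("%s n=%d", names(table(g$cohort$group)),
                          as.integer(table(g$cohort$group))), collapse = ", ")))
cat(sprintf("age range %.0f-%.0f y; PTA mean by group: %s dB HL\n",
            min(g$cohort$age), max(g$cohort$age),
            paste(round(tapply(g$cohort$pta, g$cohort$group, mean), 1),
                  collapse = " / ")))

# raw sweeps are large; they go to scratch/ as a regenerable intermediate
dir.create("scratch", showWarnings = FALSE)
es <- generate_epoch_set(epoch_params(seed = seed))
write_epoch_set(es, "scratch/example_epochs.tsv")
cat(sprintf("epoch set: %d sweeps x %d samples at %g kHz, %d planted artifact(s)\n",
            nrow(es$data), ncol(es$data), es$sampling_rate / 1000,
            sum(es$artifact_mask)))
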