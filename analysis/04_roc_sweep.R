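#!/usr/bin/env Rscript
# Percentile-criterion ROC analysis: for every 1-99% cutoff on the cognitive
# composite, how well does each wave V feature separate good from poor
# performers? Includes Youden-optimal cutoffs, the age-adjusted variant, and
# the random-predictor chance band.

suppressPackageStartupMessages(library(abrcog))

seed <- 20260925L
scored <- suppressWarnings(read_cohort("results/scored_cohort.csv"))

specs <- c(wave_v_latency = "lower_better", wave_v_amplitude = "higher_better")
for (pred in names(specs)) {
  for (adj in c(FALSE, TRUE)) {
    sw <- run_sweep(scored, pred, orientation = specs[[pred]], adjust_age = adj)
    tag <- paste0(pred, if (adj) "_age_adjusted" else "_raw")
    write.csv(sw$table, sprintf("results/sweep_%s.csv", tag), row.names = FALSE)
    s <- sw$summary
    best <- sw$table[sw$table$percentile == s$argmax_percentile, ]
    cat(sprintf("%-34s mean AUC %.2f (sd %.2f, range %.2f-%.2f); best %.2f at %d%%: cutoff %s %.2f (%s), sens %.2f / spec %.2f\n",
                tag, s$mean_auc, s$sd_auc, s$min_auc, s$max_auc,
                best$auc, best$percentile, ">", best$cutoff,
                best$cutoff_direction, best$sensitivity, best$specificity))
  }
}

cb <- chance_band(scored, replicates = 1000, seed = seed)
write.csv(data.frame(replicate = seq_along(cb$replicate_mean_auc),
                     mean_auc = cb$replicate_mean_auc),
          "results/chance_band.csv", row.names = FALSE)
cat(sprintf("chance band: mean AUC %.3f (sd across replicates %.3f, across percentiles %.3f)\n",
            cb$mean, cb$sd_across_replicates, cb$sd_across_percentiles))

raw <- run_sweep(scored, "wave_v_latency", orientation = "lower_better")
adj <- run_sweep(scored, "wave_v_latency", orientation = "lower_better",
                 adjust_age = TRUE)
cmp <- compare_sweeps(raw, adj)
cat(sprintf("latency raw vs age-adjusted: %.2f vs %.2f (paired over %d percentiles, p = %.3g)\n",
            cmp$mean_a, cmp$mean_b, cmp$n_points, cmp$p))
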