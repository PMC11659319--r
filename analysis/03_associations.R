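#!/usr/bin/env Rscript
# Scoring and the association suite: direction-adjusted z-scores, the
# cognitive composite, PTA/hearing categories; then univariate and
# age-adjusted regressions of cognition on age, hearing and ABR features in
# the full sample and per age group, plus the age-group comparison with
# Bonferroni post-hocs.

suppressPackageStartupMessages(library(abrcog))

cohort <- suppressWarnings(read_cohort("results/cohort.csv"))
scored <- score_cohort(cohort)
write_cohort(scored, "results/scored_cohort.csv")

suite <- run_association_suite(scored)
write.csv(suite, "results/associations.csv", row.names = FALSE)

key <- suite[suite$subgroup == "all" & suite$outcome == "composite" &
               suite$predictor %in% c("age", "pta", "wave_v_latency",
                                      "wave_v_amplitude"), ]
cat("composite associations (full sample):\n")
for (i in seq_len(nrow(key))) {
  cat(sprintf("  %-18s %-10s B = %7.3f  [%7.3f, %7.3f]  p = %.4g\n",
              key$predictor[i], ifelse(key$adjusted[i], "age-adj", "raw"),
              key$B[i], key$ci_low[i], key$ci_high[i], key$p[i]))
}

cmp <- compare_age_groups(scored, "composite")
write.csv(cmp$pairwise, "results/age_group_pairwise.csv", row.names = FALSE)
cat(sprintf("\nage-group model: F(%d,%d) = %.2f, p = %.3g\n",
            cmp$df[1], cmp$df[2], cmp$F, cmp$p))
print(cmp$pairwise)
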