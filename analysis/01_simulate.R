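#!/usr/bin/env Rscript
# Simulate the study inputs: a three-visit cohort (197 non-diabetic + 106
# diabetic patients, GFR mix and visit intervals as in the study) and an
# 88-sample intra/interday stability substudy. Both are seeded and written
# as CSVs for the downstream analysis scripts.

suppressPackageStartupMessages(library(microalb))
seed <- as.integer(commandArgs(trailingOnly = TRUE)[1])
if (is.na(seed)) seed <- 1

dir.create("results/data", recursive = TRUE, showWarnings = FALSE)

cohort <- generate_cohort(cohort_truth(), seed = seed)
write_cohort_csv(cohort, "results/data/cohort.csv")
cat(sprintf("Cohort: %d patients, %d visit rows -> results/data/cohort.csv\n",
            length(unique(cohort$patient_id)), nrow(cohort)))
cat(sprintf("  censored protein measurements: %d (%.1f%%)\n",
            sum(cohort$up_censored), 100 * mean(cohort$up_censored)))

stab <- generate_stability_study(stability_truth(), seed = seed)
write_stability_csv(stab, "results/data/stability.csv")
cat(sprintf("Stability substudy: %d samples x 4 occasions -> results/data/stability.csv\n",
            length(unique(stab$sample_id))))
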