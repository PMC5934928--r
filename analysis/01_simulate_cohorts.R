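#!/usr/bin/env Rscript
# Generate the two synthetic study cohorts:
#   - a stable "reliability" cohort (84 subjects, retest at 7-17 days)
#   - an improving "responsiveness" cohort (97 subjects, follow-up at
#     50-70 days, plus 12 late returns outside the window)
# and write them as wide CSVs for the downstream analyses.

suppressPackageStartupMessages(library(svensson36))

seed <- 20180207
dir.create("results/data", recursive = TRUE, showWarnings = FALSE)

rel_cfg <- reliability_cohort_config(seed = seed)
rel <- generate_rand36_cohort(rel_cfg)
write.csv(rel, "results/data/cohort_reliability.csv", row.names = FALSE)

resp_cfg <- responsiveness_cohort_config(seed = seed + 1)
resp <- generate_rand36_cohort(resp_cfg)
write.csv(resp, "results/data/cohort_responsiveness.csv", row.names = FALSE)

cat(sprintf("reliability cohort:    %d subjects x 2 occasions (%d item cells missing)\n",
            length(unique(rel$patient_id)),
            sum(is.na(rel[paste0("q", 1:36)]))))
cat(sprintf("responsiveness cohort: %d subjects x 2 occasions, of whom %d are late returns\n",
            length(unique(resp$patient_id)), resp_cfg$n_late))
cat("written to results/data/\n")
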