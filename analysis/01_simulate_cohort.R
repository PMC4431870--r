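#!/usr/bin/env Rscript
# Stage 1: simulate the study cohort.
#
# 82 patients with type 2 diabetes, annual serum creatinine over 4 years of
# follow-up, 28 baseline biomarkers across seven disease pathways with
# configured missingness and below-LOD censoring, and clinical covariates
# matching the baseline table. The generating truth (linear slope model) is
# written alongside so later stages can be checked against it.

suppressMessages(library(renalpanel))

SEED <- 2026
cohort <- simulate_cohort(gen_config(n_patients = 82, seed = SEED))

dir.create("results", showWarnings = FALSE)
write_cohort(cohort, "results/cohort")

print(cohort)
cat(sprintf("clamped trajectories: %d\n", length(cohort$truth$clamped)))
cat(sprintf("biomarker cells missing: %.1f%%; below LOD: %.1f%%\n",
            100 * mean(is.na(cohort$biomarkers)),
            100 * mean(cohort$below_lod)))
cat("wrote results/cohort/{cohort.csv,creatinine.csv,truth.json}\n")
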