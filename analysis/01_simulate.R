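#!/usr/bin/env Rscript
# Simulate the paired tumor/non-tumor cohort used throughout the analysis:
# 49 patients, three RNA classes, planted differential expression, planted
# grade associations and 10 planted miRNA-mediated ceRNA triplets. Writes
# the cohort TSVs plus the planted truth under results/run/.

library(cernet)

dir <- file.path("results", "run")
sim <- sim_config(seed = 1)
cohort <- simulate_cohort(sim)
write_cohort(cohort, dir)

cat(sprintf("cohort: %d patients (%d samples/class)\n",
            sim$n_patients, ncol(cohort$expr$circRNA$values)))
for (cl in names(cohort$expr))
  cat(sprintf("  %s: %d features, %d planted DE\n", cl,
              nrow(cohort$expr[[cl]]$values), nrow(cohort$truth$de[[cl]])))
cat(sprintf("  planted ceRNA triplets: %d; target links: %d (decoys included)\n",
            nrow(cohort$truth$triplets), nrow(cohort$targets)))
cat(sprintf("wrote cohort to %s\n", dir))
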