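#!/usr/bin/env Rscript
# Associate DE features with clinical phenotypes (Welch t for binary
# groupings at |FC| >= 1.5 & p <= 0.05; log-rank on a median expression
# split for survival), call each feature's prognosis direction, and
# tabulate the clinical-category Venn overlaps.

library(cernet)

dir <- file.path("results", "run")
cfg <- run_config(seed = 1)
run_stage("clinical", dir, cfg)

assoc <- read_tsv(file.path(dir, "assoc.tsv"))
prog <- read_tsv(file.path(dir, "prognosis.tsv"))
sig <- assoc[assoc$significant, ]
for (cl in c("circRNA", "miRNA", "mRNA"))
  cat(sprintf("%s: %d clinically associated features (of %d tested)\n", cl,
              length(unique(sig$feature_id[sig$rna_class == cl])),
              length(unique(assoc$feature_id[assoc$rna_class == cl]))))
cat("association counts by variable:\n")
print(table(sig$clinical_variable))
cat("prognosis calls:\n")
print(table(prog$rna_class, prog$call))
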