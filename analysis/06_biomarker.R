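#!/usr/bin/env Rscript
# Evaluate the nodal circRNAs as diagnostic/prognostic markers: ROC per
# circRNA and a 4-circRNA logistic panel over three contrasts (non-tumor vs
# grade 1-2 tumors; grade 1-2 vs grade 3-4; non-tumor vs grade 3-4). Also
# runs gene-set over-representation on the network genes against a small
# synthetic GMT (one set seeded from the DE mRNAs plus random sets).

library(cernet)

dir <- file.path("results", "run")
cfg <- run_config(seed = 1)

# synthetic gene sets for the over-representation demonstration
de_m <- read_tsv(file.path(dir, "de_mRNA.tsv"))
set.seed(1)
sets <- c(list(deregulated_mrnas = de_m$feature_id[de_m$status != "ns"]),
          lapply(1:4, function(i) sample(de_m$feature_id, 25)))
names(sets)[2:5] <- paste0("random_set_", 1:4)
write_gmt(sets, file.path(dir, "genesets.gmt"))

run_stage("biomarker", dir, cfg)
run_stage("enrich", dir, cfg)

roc <- read_tsv(file.path(dir, "roc.tsv"))
cat("panel AUCs:\n")
print(roc[roc$kind == "panel", c("contrast", "auc", "auc_p", "sensitivity", "specificity")])
cat("\nbest single-circRNA AUC per contrast:\n")
feat <- roc[roc$kind == "feature", ]
print(do.call(rbind, lapply(split(feat, feat$contrast), function(d)
  d[which.max(d$auc), c("contrast", "name", "auc", "auc_p")])))
enr <- read_tsv(file.path(dir, "enrichment.tsv"))
cat("\ntop enrichment:\n")
print(utils::head(enr, 3))
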