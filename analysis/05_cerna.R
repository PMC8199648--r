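#!/usr/bin/env Rscript
# ceRNA inference: filter predicted miRNA-target links by inverse Spearman
# correlation (both predictors required), score every RNA pair sharing
# miRNAs with the hypergeometric test, PC, PPC, SPPC and CMI, tier the
# pairs (highly confident = all five criteria; moderate = PC + PPC), expand
# to circRNA-miRNA-mRNA triplets and intersect with the clinically relevant
# co-expression edges.

library(cernet)

dir <- file.path("results", "run")
cfg <- run_config(seed = 1)
run_stage("cerna", dir, cfg)

inter <- read_tsv(file.path(dir, "interactions.tsv"))
pairs <- read_tsv(file.path(dir, "pairs.tsv"))
trip <- read_tsv(file.path(dir, "triplets.tsv"))
cat(sprintf("miRNA-target links: %d tested, %d retained (both predictors, rho < 0, p <= %.2f)\n",
            nrow(inter), sum(inter$retained), cfg$interaction_p))
cat(sprintf("ceRNA pairs: %d scored; tiers: %s\n", nrow(pairs),
            paste(names(table(pairs$tier)), table(pairs$tier), sep = "=", collapse = ", ")))
cat(sprintf("triplets: %d, of which %d sit on a clinically relevant co-expression edge\n",
            nrow(trip), sum(trip$clinical_flag)))

# recovery against the planted truth
truth <- jsonlite::read_json(file.path(dir, "truth.json"), simplifyVector = TRUE)
tk <- paste(truth$triplets$circ_id, truth$triplets$mirna_id, truth$triplets$mrna_id)
ck <- unique(c(paste(trip$rna1_id, trip$mirna_id, trip$rna2_id),
               paste(trip$rna2_id, trip$mirna_id, trip$rna1_id)))
cat(sprintf("planted triplet recovery: %d/%d\n", sum(tk %in% ck), length(tk)))
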