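#!/usr/bin/env Rscript
# Paired differential expression per RNA class (|FC| >= 1.5, BH FDR <= 0.05)
# and hierarchical sample clustering on the DE features. Reads the cohort
# written by 01_simulate.R; writes de_<class>.tsv and sample_order_<class>.tsv.

library(cernet)

dir <- file.path("results", "run")
cfg <- run_config(seed = 1)
run_stage("de", dir, cfg)

for (cl in c("circRNA", "miRNA", "mRNA")) {
  de <- read_tsv(file.path(dir, paste0("de_", cl, ".tsv")))
  cat(sprintf("%s: %d/%d DE (%d up, %d down)\n", cl,
              sum(de$status != "ns"), nrow(de),
              sum(de$status == "up"), sum(de$status == "down")))
}

# tumor and non-tumor samples should separate in the dendrogram leaf order
ord <- read_tsv(file.path(dir, "sample_order_mRNA.tsv"))
runs <- rle(grepl("_T$", ord$sample_id))
cat(sprintf("mRNA dendrogram: %d tissue blocks across %d samples (2 = perfect split)\n",
            length(runs$lengths), nrow(ord)))
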