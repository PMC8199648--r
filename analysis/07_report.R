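#!/usr/bin/env Rscript
# Collect every stage's counts into the run report (report.json +
# report.txt) and print it.

library(cernet)

dir <- file.path("results", "run")
cfg <- run_config(seed = 1)
run_stage("report", dir, cfg)
cat(readLines(file.path(dir, "report.txt")), sep = "\n")
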