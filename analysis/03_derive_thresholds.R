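#!/usr/bin/env Rscript
# Derive the diagnostic battery: one-vs-rest ROC for CP% (UVH), NPQ visual
# and total scores (PPPD), HADS-A and age (CDA), with DeLong 95% CIs and
# Youden-optimal thresholds.

suppressPackageStartupMessages(library(vestscreen))

cohort <- read_cohort("results/cohort.csv")
battery <- derive_battery(cohort)

for (b in battery) print(b)

for (item in names(battery))
  write.csv(battery[[item]]$points,
            sprintf("results/roc_%s.csv", item), row.names = FALSE)
jsonlite::write_json(
  lapply(battery, function(b) b[setdiff(names(b), "points")]),
  "results/battery.json", auto_unbox = TRUE, digits = NA, pretty = TRUE)
cat("Wrote results/battery.json and per-item ROC tables\n")
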