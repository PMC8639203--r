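#!/usr/bin/env Rscript
# Build the three disease rule blocks from the derived thresholds,
# enumerate the six ordered algorithms (PPPD-first, UVH-first, CDA-first
# pairs) and evaluate each on the complete-case cohort: per-class recall
# and overall accuracy excluding undifferentiated dizziness.

suppressPackageStartupMessages(library(vestscreen))

cohort <- read_cohort("results/cohort.csv")
battery <- jsonlite::read_json("results/battery.json")
battery <- lapply(battery, function(b)
  list(youden = list(threshold = b$youden$threshold)))

blocks <- build_blocks(battery)
algorithms <- enumerate_algorithms(blocks)
evaluations <- lapply(algorithms, function(a) evaluate(cohort, a))

for (ev in evaluations) { print(ev); cat("\n") }

best <- which.max(vapply(evaluations, `[[`, numeric(1),
                         "overall_accuracy_excl_ud"))
cat(sprintf("Best-performing ordering: %s (%.1f%%)\n",
            evaluations[[best]]$algorithm,
            evaluations[[best]]$overall_accuracy_excl_ud))

jsonlite::write_json(
  lapply(evaluations, function(ev) list(
    algorithm = ev$algorithm,
    per_class_recall = as.list(ev$per_class_recall),
    overall_accuracy_excl_ud = ev$overall_accuracy_excl_ud,
    n_evaluated = ev$n_evaluated,
    n_excluded_incomplete = ev$n_excluded_incomplete)),
  "results/evaluation.json", auto_unbox = TRUE, digits = NA, pretty = TRUE)
cat("Wrote results/evaluation.json\n")
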