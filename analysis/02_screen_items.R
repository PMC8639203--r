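#!/usr/bin/env Rscript
# Screen every demographic, questionnaire and vestibular-test item across
# the four diagnostic groups: Kruskal-Wallis per item on its available
# cases, Dunn-Bonferroni post-hoc for the significant items, and the
# resulting battery shortlist.

suppressPackageStartupMessages(library(vestscreen))

cohort <- read_cohort("results/cohort.csv")
cmp <- compare_all_items(cohort)

cat(sprintf("Kruskal-Wallis significant items (p < 0.05): %d of %d\n",
            sum(cmp$results$significant_overall), nrow(cmp$results)))
cat("Battery shortlist (>= 1 significant Dunn-Bonferroni pair):\n  ")
cat(paste(cmp$shortlist, collapse = ", "), "\n")

jsonlite::write_json(cmp, "results/comparison.json", auto_unbox = TRUE,
                     digits = NA, pretty = TRUE, na = "null")
cat("Wrote results/comparison.json\n")
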