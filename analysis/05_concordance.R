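#!/usr/bin/env Rscript
# Step 5: quantify agreement between PID values/scores and pathologist DAB
# scores: regression R^2, DAB x PID contingency with row percentages, and
# variance-test-gated comparisons of adjacent classes.

suppressPackageStartupMessages(library(pidquant))

rec <- read_cohort_table("results/classified.csv")

fit <- fit_score_regression(rec)
print(fit)

ct <- contingency(rec)
cat("DAB (rows) x PID (columns):\n")
print(ct$table)
cat("Row percentages (PV%):\n")
print(round(ct$pv_percent, 1))

cmps <- adjacent_class_comparisons(rec)
for (nm in names(cmps)) {
  cat(nm, ": ")
  print(cmps[[nm]])
}

jsonlite::write_json(
  list(regression = unclass(fit),
       contingency = list(
         table = matrix(as.integer(ct$table), nrow(ct$table),
                        dimnames = dimnames(ct$table)),
         pv_percent = ct$pv_percent, n = ct$n),
       adjacent_comparisons = lapply(cmps, unclass)),
  "results/concordance.json", auto_unbox = TRUE, digits = NA, pretty = TRUE
)
cat("Wrote results/concordance.json\n")
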