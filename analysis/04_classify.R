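#!/usr/bin/env Rscript
# Step 4: derive cut points (per-class PID-value minima over analyzable
# cores), assign tentative PID IHC scores, and flag DAB-0 cores above the
# negative-control floor as candidate ultra-low.

suppressPackageStartupMessages(library(pidquant))

cohort <- read_cohort_table("results/cohort.csv")
scores <- read_cohort_table("results/scores.csv")
rec <- merge(cohort, scores, by = "core_id")
rec$dab_consensus <- consensus_dab(rec$dab_score_p1, rec$dab_score_p2)

is_nc <- rec$is_negative_control %in% TRUE
tissue <- rec[!is_nc, ]

cuts <- derive_cut_points(tissue)
print(cuts)
tissue$pid_score <- classify_pid(tissue$pid_value, cuts)

ncs <- negative_control_mean(rec[is_nc, ])
cat(sprintf("Negative-control mean: %.2f x 10^3 (n = %d)\n",
            ncs$mean_value / 1e3, ncs$n))

tissue <- flag_ultra_low(tissue, cuts, ncs)
ul <- attr(tissue, "ultra_low_counts")
cat(sprintf("DAB-0 cores above the control floor (candidate ultra-low): %d of %d\n",
            ul[["flagged"]], sum(ul)))

write_results(tissue, "results/classified.csv")
jsonlite::write_json(
  list(cut_points = unclass(cuts),
       negative_control = unclass(ncs),
       ultra_low = as.list(ul)),
  "results/cut_points.json", auto_unbox = TRUE, pretty = TRUE
)
cat("Wrote results/classified.csv and results/cut_points.json\n")
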