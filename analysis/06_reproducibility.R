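#!/usr/bin/env Rscript
# Step 6: triplicate reproducibility — three independently rendered staining
# runs of one shared cohort design (same tissue, same expression levels),
# scored and compared run against run.

suppressPackageStartupMessages(library(pidquant))

seed <- 3L
params <- sim_params(core_diameter_um = 120)
design <- cohort_design(tma208_class_counts(), n_negative_controls = 8,
                        exclusion_plan = tma208_exclusion_plan(),
                        seed = seed, params = params)
keep <- design$exclusion_reason == "none" & !design$is_negative_control

runs <- lapply(1:3, function(r) {
  child <- withr::with_seed(seed + r,
                            sample.int(.Machine$integer.max, nrow(design)))
  pid <- rep(NA_real_, nrow(design))
  for (i in which(keep)) {
    sim <- simulate_core(params, design$true_class[i], seed = child[i],
                         rate = design$case_rate[i],
                         core_id = design$core_id[i])
    pid[i] <- score_core(sim$image, sim$mask)$pid_value
  }
  data.frame(core_id = design$core_id[keep],
             dab_consensus = consensus_dab(design$dab_score_p1,
                                           design$dab_score_p2)[keep],
             pid_value = pid[keep])
})

rep3 <- reproducibility(runs)
cat("Per-run R^2 against the DAB score:",
    paste(sprintf("%.3f", rep3$r_squared), collapse = ", "), "\n")
cat("Between-run PID-value correlations:\n")
print(round(rep3$between_run_correlation, 4))

jsonlite::write_json(
  list(r_squared = as.list(rep3$r_squared),
       between_run_correlation = as.list(rep3$between_run_correlation)),
  "results/reproducibility.json", auto_unbox = TRUE, digits = NA, pretty = TRUE
)
cat("Wrote results/reproducibility.json\n")
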