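#!/usr/bin/env Rscript
# Step 1: generate the synthetic 208-core TMA replica (104 duplicate-core
# cases, 8 negative controls, the reference exclusion annotations) and write
# rasters to scratch/ (binary, regenerable) and the cohort table to results/.

suppressPackageStartupMessages(library(pidquant))

seed <- 1L
params <- sim_params(core_diameter_um = 120) # scaled-down cores, same per-area physics
dir.create("results", showWarnings = FALSE)

cat("Simulating 208 cores + 8 negative controls (seed", seed, ")...\n")
sim <- simulate_cohort(params, tma208_class_counts(), n_negative_controls = 8,
                       exclusion_plan = tma208_exclusion_plan(), seed = seed)

write_cohort(sim, "scratch/cohort")
write_results(sim$truth, "results/cohort.csv")

cat("Wrote", length(sim$cores), "image/mask pairs to scratch/cohort/",
    "and the cohort table to results/cohort.csv\n")
cat("Class composition:\n")
print(table(sim$truth$true_class[!sim$truth$is_negative_control]))
cat("Spots drawn, total:", sum(sim$truth$n_spots_drawn), "\n")
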