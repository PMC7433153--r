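#!/usr/bin/env Rscript

# End-to-end discrimination on voxel phantoms: 20 MVI-positive cases carry a
# 2-mm peritumoral rim with +0.5 mg/mL iodine; 20 negatives do not. Every
# case runs the full pipeline (decompose, segment from a line, peel at 2 and
# 4 mm, quantify), and the outer-layer-1 NIC is scored by ROC. The rim is
# constructed to separate the groups, so this validates the plumbing: a
# pipeline defect (mask leakage, band misplacement, normalization error)
# would destroy the separation.

suppressPackageStartupMessages(library(dectpeel))
dir.create("results", showWarnings = FALSE)

line <- diameter_line(c(17, 32, 32), c(35, 32, 32))
cfg <- pipeline_config()

run_one <- function(seed, rim) {
  ph <- generate_phantom(phantom_spec(noise_sd = 10, seed = seed,
                                      rim_present = rim))
  run_case(ph$study, ph$masks$aorta, line = line, config = cfg,
           patient_id = sprintf("PH%02d", seed), mvi = as.integer(rim))$features
}

t0 <- Sys.time()
rows <- rbind(do.call(rbind, lapply(1:20, run_one, rim = FALSE)),
              do.call(rbind, lapply(21:40, run_one, rim = TRUE)))
cat(sprintf("40 cases in %.1f s\n", as.numeric(Sys.time() - t0, units = "secs")))

write_cohort_csv(rows, "results/03_phantom_cohort.csv")

for (f in c("nic_outer1_2mm", "nic_outer2_2mm", "nic_outer1_4mm")) {
  r <- roc_auc(rows[[f]], rows$mvi)
  cat(sprintf("%-16s AUC %.3f (95%% CI %.2f-%.2f), cutoff %.3f\n",
              f, r$auc, r$ci_low, r$ci_high, r$cutoff))
}
cat("cohort table written to results/03_phantom_cohort.csv\n")
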