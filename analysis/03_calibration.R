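#!/usr/bin/env Rscript
# Stage 3 — calibration and power of the permutation-adjusted test.
#
# Null calibration: 500 cohorts at a scaled design (200 cases / 200
# controls, 20 rare sites, odds ratio 1) measure the empirical size of
# the adjusted test at alpha = 0.05 and 0.01. The exact tie-inclusive
# estimator is conservative on sparse carrier data, so the empirical
# size is expected to fall below the nominal level.
#
# Power: 200 replicates each at odds ratios 1, 2, 4, 8 (500/500)
# trace the rejection-rate curve. Output: results/calibration.tsv.

suppressPackageStartupMessages(library(vtburden))

dir.create("results", showWarnings = FALSE)
bc <- burden_config(n_permutations = 200L)

null_cfg <- sim_config(n_cases = 200, n_controls = 200, n_sites = 20,
                       odds_ratio = 1)
null_tab <- calibration_study(null_cfg, bc, n_reps = 500,
                              alpha = c(0.05, 0.01), seed = 1042L)
cat("null calibration (odds ratio 1):\n")
print(null_tab[c("alpha", "n_reject", "rate", "ci_lo", "ci_hi")],
      row.names = FALSE)

grid <- lapply(c(1, 2, 4, 8), function(o)
  sim_config(n_cases = 500, n_controls = 500, n_sites = 20,
             odds_ratio = o))
power_tab <- calibration_study(grid, bc, n_reps = 200, alpha = 0.05,
                               seed = 2042L)
cat("\npower curve at alpha = 0.05:\n")
print(power_tab[c("odds_ratio", "n_reject", "rate", "ci_lo", "ci_hi")],
      row.names = FALSE)

out <- rbind(cbind(study = "null", null_tab),
             cbind(study = "power", power_tab))
utils::write.table(out, "results/calibration.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
cat("\ncalibration table written to results/calibration.tsv\n")
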