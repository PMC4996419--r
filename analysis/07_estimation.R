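#!/usr/bin/env Rscript
# Analyses the synthetic plate like real data: equilibrium detection,
# bootstrap equilibrium fractions, regime calls per condition, and the
# intrinsic growth-rate disadvantage of the Leu- strain from the
# saturating-supplementation conditions.

library(crossfeedr)

if (!file.exists("results/plate.csv"))
  stop("run analysis/06_synthetic_plate.R first")
plate <- read_plate("results/plate.csv")

res <- analyze_plate(plate, rel_tol = 0.05, seed = 1)
write.csv(res, "results/plate_analysis.csv", row.names = FALSE)
cat("regime calls by condition (uM tryptophan):\n")
print(res[, c("trp_uM", "label", "eq_fraction")], digits = 3)

sat <- plate[plate$trp_uM >= 100, ]
rec <- day_fitness_records(sat)
est <- estimate_growth_disadvantage(rec, n_boot = 2000, seed = 2)
cat(sprintf("Leu- per-day growth disadvantage: %.3f (95%% CI %.3f-%.3f)\n",
            est$estimate, est$ci[1], est$ci[2]))
jsonlite::write_json(list(disadvantage = est$estimate, ci = est$ci),
                     "results/disadvantage.json", digits = NA)
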