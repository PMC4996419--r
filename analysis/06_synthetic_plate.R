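#!/usr/bin/env Rscript
# Generates the synthetic daily-dilution plate experiment: 16 amino-acid
# conditions (leucine at 8x tryptophan), monocultures plus co-cultures at
# six starting ratios, 7 days of 10x dilution, OD and flow-cytometry
# readouts with measurement noise.

library(crossfeedr)

dir.create("results", showWarnings = FALSE)
cfg <- experiment_config(seed = 20260924)
plate <- simulate_plate(cfg, cf_params())
write_plate(plate, "results/plate.csv")
cat(sprintf("wrote %d records (%d wells x %d days) to results/plate.csv\n",
            nrow(plate), length(unique(plate$well)), cfg$days))
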