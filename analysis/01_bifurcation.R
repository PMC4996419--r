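#!/usr/bin/env Rscript
# Fixed-point structure of the cross-feeding pair as supplementation varies:
# locates the saddle-node onset of coexistence, the two monoculture
# viability thresholds and the competitive-exclusion threshold, and writes
# the full equilibrium branches for plotting.

library(crossfeedr)

p <- cf_params()
dir.create("results", showWarnings = FALSE)

bs <- bifurcation_scan(p, seq(0.005, 1, by = 0.005))
write_bifurcation(bs, "results/bifurcation.csv", "results/boundaries.json")

a_star <- saddle_node_point(p)
a_excl <- exclusion_threshold(p)
cat(sprintf("saddle-node onset of coexistence:  a* = %.6f\n", a_star))
cat(sprintf("Trp- monoculture viable above:     a  = %.6f\n",
            monoculture_viability_threshold(p, "X")))
cat(sprintf("Leu- monoculture viable above:     a  = %.6f\n",
            monoculture_viability_threshold(p, "Y")))
cat(sprintf("Leu- competitively excluded above: a  = %.6f\n", a_excl))
cat("branches written to results/bifurcation.csv\n")
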