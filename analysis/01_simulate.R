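#!/usr/bin/env Rscript
# Stage 1: solve the steady-state reaction-transport model for the
# North-Pond-like scenario and generate the noisy observed profiles.
#
# Writes: results/solution.csv, results/profiles.csv
#
# Run from the repository root: Rscript analysis/01_simulate.R

library(sednitro)
dir.create("results", showWarnings = FALSE)

spec <- load_config(northpond_config())
gp <- generate_profiles(spec)
truth <- gp$truth
cat(sprintf("column: %.0f m, %d nodes; solver %s (residual %.2g)\n",
            spec$column$depth_max, spec$column$n_nodes,
            if (truth$converged) "converged" else "FAILED",
            truth$residual_norm))

cc <- truth$concentrations
cat(sprintf("O2: %.0f uM at the seafloor, %.0f uM at the basement, minimum %.2g uM\n",
            cc[1, "O2"], cc[nrow(cc), "O2"], min(cc[, "O2"])))
cat(sprintf("NO3: interior maximum %.1f uM at %.1f m (boundaries 21.0/21.1)\n",
            max(cc[, "NO3"]), truth$z[which.max(cc[, "NO3"])]))
cat(sprintf("NH4 up to %.1f uM in the anoxic zone; TOC %.2f%% at the surface\n",
            max(cc[, "NH4"]),
            100 * cc[1, "OM"] * 12.011 /
              ((1 - spec$column$porosity[1]) * 2.65e6)))

mb <- mass_balance(truth)
cat(sprintf("mass-balance closure: worst species %.2f%% (%s)\n",
            100 * max(mb$residual), mb$species[which.max(mb$residual)]))

write_solution(truth, "results/solution.csv")
write_profiles(gp$observed, "results/profiles.csv")
cat("wrote results/solution.csv and results/profiles.csv\n")
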