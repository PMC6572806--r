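#!/usr/bin/env Rscript
# Stage 3: cell-specific metabolic rates.  Divides the modelled volumetric
# rates by simulated functional-gene abundances, normalizes to electron
# transfers, converts nitrifier rates to carbon metabolic rates and
# turnover times, and classifies metabolic state against example
# survival/growth threshold curves.
#
# Reads:  results/solution.csv context via re-solve; results/zones.csv
# Writes: results/abundances.csv, results/cellrates.csv
#
# Run from the repository root after 02_fluxes_zones.R.

library(sednitro)

spec <- load_config(northpond_config())
truth <- solve_steady_state(spec$column, spec$kinetics)
zones <- read.csv("results/zones.csv")

ab <- generate_abundances(spec, zones)
write_abundances(ab, "results/abundances.csv")
tot <- ab[ab$marker %in% c("16S_bac", "16S_arc"), ]
cat(sprintf("total 16S: %.1e copies/g at the surface, %.1e at depth\n",
            sum(tot$copies_per_g[tot$depth_m == min(tot$depth_m)]),
            sum(tot$copies_per_g[tot$depth_m == max(tot$depth_m)])))

# example threshold lines (log10 rate vs temperature): user-configurable;
# chosen so the growth line passes well above typical deep-sediment rates
curves <- list(survival = c(-7.5, 0.05), growth = c(-2.5, 0.05))
crt <- cell_rate_table(truth, ab, curves = curves)
write.csv(crt, "results/cellrates.csv", row.names = FALSE)

for (p in unique(crt$process)) {
  r <- crt$fmol_e_cell_d[crt$process == p]
  r <- r[is.finite(r) & r > 0]
  cat(sprintf("%s: cell-specific rates 1e%.1f - 1e%.1f fmol e- cell-1 d-1\n",
              p, log10(min(r)), log10(max(r))))
}
nit <- crt[crt$process == "nitrification" & is.finite(crt$gC_per_gC_hr), ]
cat(sprintf("nitrifier carbon metabolic rates 1e%.1f - 1e%.1f gC (gC cell)-1 hr-1\n",
            log10(min(nit$gC_per_gC_hr)), log10(max(nit$gC_per_gC_hr))))
cat(sprintf("turnover times %.2g - %.2g yr; states: %s\n",
            min(nit$turnover_yr), max(nit$turnover_yr),
            paste(names(table(nit$state)), table(nit$state),
                  sep = "=", collapse = ", ")))
cat(sprintf("basal power scale: 1e-5 fmol e- cell-1 d-1 is %.2g electrons/day (order 1e%d)\n",
            electrons_per_day(1e-5)$electrons_per_day,
            electrons_per_day(1e-5)$order_of_magnitude))
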