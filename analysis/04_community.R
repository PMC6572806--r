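#!/usr/bin/env Rscript
# Stage 4: community statistics on the simulated OTU table -- rarefied
# richness by depth, functional-group relative abundances, total-sum-scaled
# AOA composition, and the surface-community reappearance statistic at the
# OATZ scored against the planted truth.
#
# Reads:  results/zones.csv
# Writes: results/otu_table.tsv, results/otu_meta.csv, results/richness.csv,
#         results/functional_groups.csv, results/reappearance.csv
#
# Run from the repository root after 02_fluxes_zones.R.

library(sednitro)

spec <- load_config(northpond_config())
zones <- read.csv("results/zones.csv")

ot <- generate_otu_table(spec, zones)
write_otu_table(ot$table, "results/otu_table.tsv", "results/otu_meta.csv")

rt <- rarefy_counts(ot$table, depth = 1000, seed = spec$seed)
rich <- data.frame(sample = colnames(rt$counts), depth_m = rt$meta$depth_m,
                   zone = rt$meta$zone, richness = as.integer(richness(rt)))
write.csv(rich, "results/richness.csv", row.names = FALSE)
cat(sprintf("rarefied richness: surface %d; anoxic mean %.0f; OATZ mean %.0f (resurgence)\n",
            rich$richness[1], mean(rich$richness[rich$zone == "anoxic"]),
            mean(rich$richness[rich$zone == "OATZ"])))

fg <- assign_functional_groups(ot$table)
write.csv(data.frame(group = rownames(fg), fg, check.names = FALSE),
          "results/functional_groups.csv", row.names = FALSE)
cat(sprintf("AOA relative abundance: %.1f%% at the surface, %.1f%% mean in the OATZ\n",
            fg["AOA", 1], mean(fg["AOA", ot$table$meta$zone == "OATZ"])))

tss <- total_sum_scale(ot$table, taxa = "Nitrosopumilales")
cat(sprintf("total-sum-scaled AOA matrix: %d OTUs x %d samples (heatmap input)\n",
            nrow(tss), ncol(tss)))

reap <- reappearance_fraction(ot$table, taxa = "Nitrosopumilales",
                              gap_zones = "anoxic")
write.csv(as.data.frame(reap), "results/reappearance.csv", row.names = FALSE)
cat(sprintf("of %d surface AOA OTUs undetected mid-column, %d reappear in the OATZ: %.0f%% (planted %.0f%%)\n",
            reap$n_candidates, reap$n_reappeared, 100 * reap$fraction,
            100 * spec$community$resurrection_p))
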