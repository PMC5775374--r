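#!/usr/bin/env Rscript
# Stage 4: hazard scores. Multiplicative raw profile scores
# (POP = Pov x BAF x TE, vPvB = Pov x BAF, APC = Pov x CTD_air,
# WPC = Pov x CTD_water), percentile benchmarking against the reference
# set, priority flags and the spatial-coverage summary.

library(hazscreen)

chems <- read_chemical_table("results/chemicals_with_metrics.csv")
ref <- read_reference_set("results/reference_set.csv")
fingerprint <- parameter_fingerprint()

scored <- score_table(chems, ref, fingerprint = fingerprint)
flagged <- priority_flags(scored)
write_chemical_table(flagged, "results/scored_chemicals.csv")

s <- priority_summary(flagged)
counts <- data.frame(
  profile = c("pop", "vpvb", "apc", "wpc"),
  over90 = s$over90_per_profile,
  over90_exclusive = s$over90_exclusive
)
write.csv(counts, "results/priority_counts.csv", row.names = FALSE)

cat("scored", nrow(flagged), "chemicals against", ref$n, "reference chemicals\n")
cat("over 90 in at least one profile:", s$over90_any, "\n")
cat("under 10 in all profiles:", s$under10_all, " | zero in all profiles:", s$all_zero, "\n")
cat(
  "spatial scheme: vPvB90", s$spatial_vpvb90,
  "| POP90 not vPvB90", s$spatial_pop90_not_vpvb90,
  "| APC90 not POP90", s$spatial_apc90_not_pop90,
  "| WPC90 not POP90", s$spatial_wpc90_not_pop90, "\n"
)
cat(sprintf(
  "median scores: POP %.1f vPvB %.1f APC %.1f WPC %.1f\n",
  median(flagged$s_pop), median(flagged$s_vpvb),
  median(flagged$s_apc), median(flagged$s_wpc)
))
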