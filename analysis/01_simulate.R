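#!/usr/bin/env Rscript
# Stage 1: generate the synthetic screening table and the synthetic
# reference fixture. Both are fully determined by the seed; the screening
# table emulates a commerce-scale database of neutral organics (2000
# records here) and the reference fixture emulates a set of 148
# well-characterized contaminants.

library(hazscreen)

seed <- 20260928
dir.create("results", showWarnings = FALSE)

screen <- generate_screening_set(synthetic_config(n_chemicals = 2000, seed = seed))
write_chemical_table(screen, "results/synthetic_chemicals.csv")

fix <- generate_reference_fixture(n = 148, seed = seed + 1)
write_chemical_table(fix$records, "results/reference_chemicals.csv")
write_reference_set(fix$reference, fix$records, "results/reference_set.csv")

cat("screening table:", nrow(screen), "records -> results/synthetic_chemicals.csv\n")
cat(
  "reference fixture:", fix$reference$n, "records, raw vPvB score spread",
  format(max(fix$reference$scores$vpvb) / min(fix$reference$scores$vpvb), digits = 3),
  "-> results/reference_set.csv\n"
)
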