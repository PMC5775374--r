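#!/usr/bin/env Rscript
# Stage 2: curation. Remove chemicals likely ionized at environmental pH
# (pKa < 5 or pKb > 8; strict inequalities) and clamp partition ratios to
# the property-model domain (log Kow to [-4, 10], log Kaw to [-12, 3]).

library(hazscreen)

screen <- read_chemical_table("results/synthetic_chemicals.csv")
cur <- curate_records(screen)

write_chemical_table(cur$records, "results/curated_chemicals.csv")
removed <- screen[screen$chem_id %in% cur$report$removed_ids, ]
write_chemical_table(removed, "results/removed_chemicals.csv")

print(cur$report)
cat(
  "kept", cur$report$n_output, "of", cur$report$n_input,
  sprintf("(%.1f%%)", 100 * cur$report$n_output / cur$report$n_input),
  "-> results/curated_chemicals.csv\n"
)
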