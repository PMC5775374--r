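#!/usr/bin/env Rscript
# Stage 3: hazard metrics. Multimedia fate metrics (Pov, CTD_air,
# CTD_water, TE) from the evaluative three-compartment model, and the
# bioaccumulation factor from the single-fish mass balance.

library(hazscreen)

curated <- read_chemical_table("results/curated_chemicals.csv")
env <- default_environment()
fish <- default_fish_parameters()

with_metrics <- fate_metrics_table(curated, env)
with_baf <- apply_baf_column(with_metrics, fish)
write_chemical_table(with_baf, "results/chemicals_with_metrics.csv")

ok <- is.na(with_baf$fate_error)
cat("fate metrics computed for", sum(ok), "of", nrow(with_baf), "chemicals\n")
cat(sprintf(
  "median Pov %.1f d | median CTD_air %.0f km | median CTD_water %.0f km | median log BAF %.2f\n",
  median(with_baf$pov_days, na.rm = TRUE),
  median(with_baf$ctd_air_km, na.rm = TRUE),
  median(with_baf$ctd_water_km, na.rm = TRUE),
  median(with_baf$log_baf, na.rm = TRUE)
))
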