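#!/usr/bin/env Rscript
# Stage 5: structural composition analytics. Element presence percentages
# and molecular weights, halogen atom-count histograms, and the mean
# atoms-per-structure of each element across hazard-score bins.

library(hazscreen)

scored <- read_chemical_table("results/scored_chemicals.csv")

s <- presence_summary(scored)
write.csv(s$elements, "results/element_presence.csv", row.names = FALSE)
cat("element presence over", s$n_parseable, "parseable structures:\n")
print(s$elements)
cat(sprintf(
  "molecular weight (g/mol): min %.0f max %.0f median %.0f mean %.0f\n",
  s$molecular_weight[["min"]], s$molecular_weight[["max"]],
  s$molecular_weight[["median"]], s$molecular_weight[["mean"]]
))

for (el in c("F", "Cl", "Br", "I")) {
  h <- atom_count_histogram(scored, el)
  write.csv(h, sprintf("results/atom_histogram_%s.csv", el), row.names = FALSE)
}

assoc <- do.call(rbind, lapply(c("F", "Cl", "Br", "I", "N", "S", "P", "O", "Si", "B"), function(el) {
  do.call(rbind, lapply(c("s_pop", "s_vpvb", "s_apc", "s_wpc"), function(profile) {
    a <- element_score_association(scored, scored[[profile]], el, n_bins = 10)
    a$element <- el
    a$profile <- profile
    a
  }))
}))
write.csv(assoc, "results/element_score_association.csv", row.names = FALSE)
cat("wrote results/element_presence.csv, atom_histogram_*.csv, element_score_association.csv\n")
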