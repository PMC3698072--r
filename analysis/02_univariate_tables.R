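#!/usr/bin/env Rscript
# Step 2 — univariate group comparisons.
#
# Reproduces the supplementary-table layout on the simulated cohort: for
# each stratified comparison, raw-scale means (SE) per group with the
# pooled t test p-value on log2 data and the Wilcoxon rank-sum p-value on
# raw data, per (cytokine, time point).  No multiplicity adjustment, as in
# the replication target.

library(cytosig)

panel <- read_panel("results/synthetic_panel.csv")
assert_study_panel(panel)

comparisons <- list(
  hc_male_vs_female = list(sexes = c("male", "female"), diagnosis = "HC"),
  males_gwi_vs_hc = list(diagnoses = c("HC", "GWI"), sex = "male"),
  males_cfs_vs_hc = list(diagnoses = c("HC", "CFS"), sex = "male"),
  females_gwi_vs_hc = list(diagnoses = c("HC", "GWI"), sex = "female"),
  females_cfs_vs_hc = list(diagnoses = c("HC", "CFS"), sex = "female")
)

for (nm in names(comparisons)) {
  tab <- do.call(compare_table, c(list(panel), comparisons[[nm]]))
  out <- file.path("results", paste0("univariate_", nm, ".csv"))
  write.csv(tab, out, row.names = FALSE)
  hits <- tab$feature[tab$significant]
  cat(sprintf("%-22s %2d/48 features at p <= 0.05%s\n", nm, length(hits),
              if (length(hits)) paste0(": ", paste(head(hits, 6),
                                                   collapse = ", "),
                                       if (length(hits) > 6) ", ...") else ""))
}
cat("\nWrote results/univariate_*.csv\n")
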