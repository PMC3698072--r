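#!/usr/bin/env Rscript
# Step 4 — random-subset ensemble ranking for the least separable stratum.
#
# The stepwise constraint of minimal marker redundancy can truncate too
# aggressively when informative cytokines are co-expressed (the female
# CFS stratum in the replication target).  This step relaxes it: 500
# random 5-of-48 subsets, each scored as a diagonal-covariance
# discriminant by LOOCV; features are ranked by how often they appear in
# subsets reaching 80% accuracy, and the top 2 are refit as the final
# model.

library(cytosig)

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[1]) else 1L

panel <- read_panel("results/synthetic_panel.csv")
sel <- select_cohort(panel, diagnoses = c("HC", "CFS"), sex = "female")
Xp <- preprocess_matrix(sel$X, sel$mask)

rk <- suppressWarnings(
  ensemble_rank(Xp, sel$y, n_iterations = 500, subset_size = 5,
                accuracy_threshold = 0.80, seed = seed))
print(rk)
write.csv(rk$ranking, "results/ensemble_ranking.csv", row.names = FALSE)

if (rk$n_passing > 0) {
  fin <- build_final_model(Xp, sel$y, rk, top_k = 2)
  cat("\nFinal 2-marker diagonal model:",
      paste(fin$features, collapse = " + "), "\n")
  print(fin$confusion)
  print(fin$metrics)
  jsonlite::write_json(
    list(seed = seed, features = fin$features,
         standardized = fin$model$standardized,
         confusion = fin$confusion$counts,
         metrics = fin$metrics[c("accuracy", "sensitivity", "specificity",
                                 "ppv", "npv")]),
    "results/ensemble_final_model.json", auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  cat("\nWrote results/ensemble_ranking.csv and ensemble_final_model.json\n")
} else {
  cat("\nNo subset reached the accuracy threshold; ranking written, no final model.\n")
}
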