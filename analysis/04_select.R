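#!/usr/bin/env Rscript

# Stage 4: cross-validated model comparison.
#
# For every afferent: 100 randomized 75/25 train/test splits (stratified
# by stretch type), pooled bounded least-squares fits of all six candidate
# models on each training set at the frozen lags, held-out R^2, AICc
# (likelihood proxied by 1/J_test, n = test trial count), Akaike weights,
# and per-iteration winners. The force-encoding afferents are then pooled
# into a population summary. Expectation: the force model wins on the
# force-truth afferents, the length model on the elastic-muscle control,
# and the 11-predictor free regression tops R^2 everywhere while AICc
# penalizes it below the generating model.

suppressPackageStartupMessages(library(spindlefit))
cohort <- readRDS("results/cohort.rds")
explores <- readRDS("results/explores.rds")
afferents <- c(cohort$force$afferents, cohort$length$afferents)
cfg <- spindle_config()
seed <- cohort$seed

summaries <- lapply(seq_along(afferents), function(i) {
  af <- afferents[[i]]
  message("Cross-validating afferent ", af$afferent_id, " ...")
  cross_validate(af, config = cfg, seed = seed + 10 + i,
                 explore = explores[[af$afferent_id]])
})
names(summaries) <- names(afferents)
saveRDS(summaries, "results/selection.rds")

sel_tab <- do.call(rbind, lapply(names(summaries), function(id) {
  tb <- summaries[[id]]$table
  tb$afferent <- id
  tb
}))
write.csv(sel_tab, "results/04_selection_per_afferent.csv", row.names = FALSE)

pop <- population_summary(unname(summaries[c("dynamic", "static")]))
write.csv(pop$table, "results/04_selection_population_force.csv",
          row.names = FALSE)

for (id in names(summaries)) {
  cat("\n")
  print(summaries[[id]])
}
cat("\nPopulation over the force-encoding afferents:\n")
print(pop)
message("\nWrote results/selection.rds and the 04_selection_*.csv tables")
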