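#!/usr/bin/env Rscript

# Stage 3: exploratory per-trial fits and lag consolidation.
#
# For each afferent and candidate model, fits trial-by-trial over the
# 0-15 ms lag sweep on the exploratory subset, freezes the per-afferent
# lag (mean best lag, rounded), derives the parameter search limits for
# cross-validation, and - for the force model - decides between the plain
# and competing-influence variants. The frozen lags and exploratory fits
# are reused by stage 4.

suppressPackageStartupMessages(library(spindlefit))
cohort <- readRDS("results/cohort.rds")
afferents <- c(cohort$force$afferents, cohort$length$afferents)
cfg <- spindle_config()

explores <- lapply(afferents, function(af) {
  message("Exploring afferent ", af$afferent_id, " ...")
  explore_afferent(af, config = cfg, check_competing = TRUE)
})
saveRDS(explores, "results/explores.rds")

lag_tab <- do.call(rbind, lapply(names(explores), function(id) {
  ex <- explores[[id]]
  mods <- setdiff(names(ex), "force_variant")
  data.frame(
    afferent = id,
    model = mods,
    lambda_ms = vapply(mods, function(m) ex[[m]]$lambda_ms, numeric(1)),
    mean_explore_r2 = vapply(mods, function(m) ex[[m]]$mean_r2, numeric(1)),
    force_variant = ifelse(mods == "force", ex$force_variant, "")
  )
}))
write.csv(lag_tab, "results/03_lags.csv", row.names = FALSE)
cat("\nFrozen per-afferent lags and exploratory fit quality:\n")
print(lag_tab, row.names = FALSE, digits = 3)
message("\nWrote results/explores.rds and results/03_lags.csv")
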