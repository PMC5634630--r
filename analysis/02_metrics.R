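#!/usr/bin/env Rscript

# Stage 2: classical spindle characterization of the simulated cohort.
#
# Computes per-trial dynamic index (DI) and initial-burst amplitude (IBA),
# summarizes DI by 10 mm/s velocity bin (bins with fewer than 4 trials
# dropped), and regresses IBA on the preceding peaks in dF/dt and in
# acceleration. Expectation from the generative model: DI grows with
# stretch velocity and with the afferent's dF/dt weight; IBA correlates
# with both dF/dt and acceleration peaks (they are collinear at onset).

suppressPackageStartupMessages(library(spindlefit))
cohort <- readRDS("results/cohort.rds")
afferents <- c(cohort$force$afferents, cohort$length$afferents)

metrics <- do.call(rbind, lapply(afferents, function(af) {
  m <- spindle_metrics(af$trials, af$channels)
  m$afferent <- af$afferent_id
  m
}))
write.csv(metrics, "results/02_trial_metrics.csv", row.names = FALSE)

di_bins <- do.call(rbind, lapply(split(metrics, metrics$afferent), function(d) {
  d <- d[!is.na(d$di), ]
  agg <- aggregate(di ~ velocity_bin, data = d, FUN = mean)
  n <- aggregate(di ~ velocity_bin, data = d, FUN = length)
  agg$n_trials <- n$di
  agg <- agg[agg$n_trials >= 4, ] # small bins dropped
  agg$afferent <- d$afferent[1]
  agg
}))
write.csv(di_bins, "results/02_di_by_velocity.csv", row.names = FALSE)
cat("\nDynamic index by velocity bin (imp/s):\n")
print(di_bins, row.names = FALSE)

cat("\nInitial-burst regressions (ramp-hold-release trials):\n")
iba_rows <- do.call(rbind, lapply(split(metrics, metrics$afferent), function(d) {
  d <- d[d$stretch_type == "ramp_hold_release", ]
  rd <- iba_regression(d$iba, d$peak_dfdt_n_s)
  ra <- iba_regression(d$iba, d$peak_accel_mm_s2)
  data.frame(
    afferent = d$afferent[1],
    r2_dfdt = rd$r2, p_dfdt = rd$p,
    r2_accel = ra$r2, p_accel = ra$p,
    n = rd$n
  )
}))
write.csv(iba_rows, "results/02_iba_regressions.csv", row.names = FALSE)
print(iba_rows, row.names = FALSE, digits = 3)
message("\nWrote results/02_trial_metrics.csv, 02_di_by_velocity.csv, ",
        "02_iba_regressions.csv")
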