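#!/usr/bin/env Rscript
# Stage 4: sensitivity of the verdict to a miscalibrated board.
#
# Re-runs the study with a 5% gain error injected on the top-right load
# cell of board 2. The closed-form effect of a single-corner gain on a
# centroid-normalized quad board is a CoP translation plus a small AP->ML
# coupling; the translation is invisible to every sway parameter, so the
# study-level footprint is a small negative shift of the biased board's
# FP-board differences for ML-derived parameters. This stage quantifies
# that shift and writes results/sensitivity.csv.

suppressPackageStartupMessages(library(swayagree))

seed <- 20260924
scenario <- default_scenario(seed = seed, trial_duration = 30)
scenario$boards[[2]]$gains[2] <- scenario$boards[[2]]$gains[2] * 1.05

study <- generate_synthetic_study(
  design = scenario$design, sway = scenario$sway,
  population = scenario$population, boards = scenario$boards,
  plate = scenario$plate, geom = scenario$geometry, seed = seed,
  truth_rate_hz = scenario$truth_rate_hz,
  surface_offset_dz_mm = scenario$surface_offset_dz_mm)
met <- study_metrics(study)
report <- run_interchangeability_study(met$fp, met$board,
                                       design = scenario$design)

d <- report$differences
rows <- do.call(rbind, lapply(metric_names(), function(p) {
  dp <- d[d$parameter == p, ]
  data.frame(parameter = p,
             mean_diff_biased = mean(dp$value[dp$device_id == "B2"]),
             mean_diff_others = mean(dp$value[dp$device_id != "B2"]),
             friedman_p = report$friedman$p_value[
               report$friedman$parameter == p])
}))
dir.create("results", showWarnings = FALSE)
write.csv(rows, "results/sensitivity.csv", row.names = FALSE)
print(rows, digits = 3)

cat("\nThe closed-form footprint of the injected bias (an AP->ML coupling\n")
cat("inflating the board's ML parameters by ~0.1-1%, i.e. a negative shift\n")
cat("of its FP-board differences) is far smaller than trial-to-trial sway\n")
cat("variability, so a single study cannot resolve it and the Friedman\n")
cat("test rarely flags the biased board; pooling replicate studies (as the\n")
cat("test-suite does) is needed to measure the direction of the effect.\n")
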