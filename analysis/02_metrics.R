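#!/usr/bin/env Rscript
# Stage 2: condition every recording and compute the nine stabilometric
# parameters.
#
# Board corner loads -> CoP via the quad-cell moment balance; plate wrench
# -> CoP via the surface-transported moment equations; both resampled to a
# uniform 1000 Hz grid (linear interpolation) and low-pass filtered with a
# zero-phase 2nd-order Butterworth at 12 Hz. One metrics row per recording
# (both device roles) is written to results/metrics.csv.

suppressPackageStartupMessages(library(swayagree))

cfg <- run_config()
metrics <- run_metrics("results/corpus", cfg, "results/metrics.csv")

cat(sprintf("\n%d metric rows (%d board, %d force plate)\n",
            nrow(metrics), sum(metrics$role == "board"),
            sum(metrics$role == "forceplate")))
cat("\nForce-plate means across trials:\n")
fp <- metrics[metrics$role == "forceplate", metric_names()]
print(round(colMeans(fp), 2))
cat("\nBoard means across trials:\n")
bd <- metrics[metrics$role == "board", metric_names()]
print(round(colMeans(bd), 2))
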