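#!/usr/bin/env Rscript
# Stage 3: the device-agreement battery.
#
# Per-trial force-plate minus board differences for each parameter feed:
# two-way random ICC across the four boards (single and average forms, at
# trial-level and subject-mean granularity), Friedman repeated-measures
# tests, pooled 95% limits of agreement with the out-of-limit contingency
# table and its chi-square test, and per-device Spearman correlations
# between plate and board values. Tables land in results/report/.

suppressPackageStartupMessages(library(swayagree))

cfg <- run_config()
report <- run_agreement("results/metrics.csv", cfg, "results/report")

print(report)

cat("\nInterpretation aids:\n")
cat("- ICC(2,1) near 1: the FP-board difference is consistent across\n")
cat("  boards, i.e. the boards are interchangeable up to a shared bias.\n")
cat("- Friedman p > 0.05: no detectable systematic ranking of the boards.\n")
cat("- The contingency chi-square tests whether out-of-limit differences\n")
cat("  concentrate on particular boards.\n")
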