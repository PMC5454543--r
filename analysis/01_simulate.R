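#!/usr/bin/env Rscript
# Stage 1: simulate the crossover study corpus.
#
# Emulates the study conditions: 6 subjects, 4 consumer balance boards with
# mild uncalibrated gain/offset errors, 3 quiet-stance trials of 30 s per
# board, every trial recorded simultaneously by the board (low-rate,
# jittered, noisy) and a clean 1000 Hz force plate beneath it. Writes one
# CSV per recording plus a manifest and the scenario echo under
# results/corpus/.

suppressPackageStartupMessages(library(swayagree))

seed <- 20260924
scenario <- default_scenario(seed = seed, trial_duration = 30)
out_dir <- "results/corpus"

manifest <- run_simulate(scenario, out_dir)

cat(sprintf("\nSimulated %d paired trials into %s\n", nrow(manifest), out_dir))
cat(sprintf("Subject masses (kg): %s\n",
            paste(sprintf("%.1f", unique(manifest$mass_kg)), collapse = ", ")))
cat("Each subject-device-trial cell holds one shared ground-truth sway\n")
cat("realization observed independently by the board and the plate.\n")
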