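#!/usr/bin/env Rscript
# Step 1: simulate the study corpus.
#
# Generates a synthetic two-stage sleep-laboratory dream-report corpus (20
# participants, 2 nights x 5 awakenings, N2-heavy stage mix, stage-dependent
# recall and report length, longer-range word recurrence in REM, more
# paragraphs in N2) and writes it in the transcript + metadata layout that
# the rest of the workflow consumes.

library(dreamgraph)

SEED <- 20260928L
out_dir <- "results/corpus"

sim <- generate_corpus(preset_dream_study(master_seed = SEED))
write_corpus(sim, out_dir)

awk <- sim$ground_truth$awakenings
message(sprintf("simulated %d awakenings -> %d dream reports (REM %d, N2 %d)",
                nrow(awk), nrow(sim$metadata),
                sum(sim$metadata$stage == "REM"),
                sum(sim$metadata$stage == "N2")))
message(sprintf("recall rates: REM %.1f%%, N2 %.1f%%",
                100 * mean(awk$recalled[awk$stage == "REM"]),
                100 * mean(awk$recalled[awk$stage == "N2"])))
message("corpus written to ", out_dir)
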