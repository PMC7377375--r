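#!/usr/bin/env Rscript
# Step 3: shuffle-null z-scores.
#
# For every retained report, shuffles the word order 1000 times (paragraph
# breaks fixed), recomputes the windowed measures per shuffle, and converts
# the observed LCC/LSC to random-likeness z-scores.  Scores near 0 indicate
# a report whose structure is indistinguishable from a random word order.

library(dreamgraph)

SEED <- 20260928L

corpus <- load_corpus("results/corpus/metadata.tsv", "results/corpus")
kept <- filter_min_length(corpus, min_tokens = 30)$kept

nulls <- corpus_null_zscores(kept, n_shuffles = 1000, seed = SEED)
write.table(nulls, "results/nulls.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

measures <- read.delim("results/measures.tsv")
measures <- merge(measures, nulls[, c("report_id", "lcc_z", "lsc_z")],
                  by = "report_id", sort = FALSE)
write.table(measures, "results/measures_with_z.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

message(sprintf("mean LCCz = %.2f, mean LSCz = %.2f across %d reports",
                mean(nulls$lcc_z, na.rm = TRUE),
                mean(nulls$lsc_z, na.rm = TRUE), nrow(nulls)))
message("null table written to results/nulls.tsv")
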