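#!/usr/bin/env Rscript
# Step 6: confound follow-ups.
#
# Two confirmatory reruns: (a) remove common English stop-words and repeat
# the measure computation and the stage-discernment ledger on the reduced
# corpus (note: synthetic vocabularies contain no stop-words, so on
# simulated corpora this demonstrates the machinery rather than changing
# the numbers; on real transcripts it is a substantive control); (b) add
# the paragraph count as a covariate to every model, partialling it out of
# every comparison.

library(dreamgraph)

SEED <- 20260928L
dir.create("results/followup", showWarnings = FALSE)

corpus <- load_corpus("results/corpus/metadata.tsv", "results/corpus")
sw_file <- system.file("extdata", "stopwords_english.txt",
                       package = "dreamgraph")

filtered <- lapply(corpus, apply_stopword_filter, stopwords = sw_file)
flt <- filter_min_length(filtered, min_tokens = 30)
message("stop-word rerun: ", flt$log)
m_sw <- corpus_measures(flt$kept)
nz_sw <- corpus_null_zscores(flt$kept, n_shuffles = 1000, seed = SEED)
m_sw <- merge(m_sw, nz_sw[, c("report_id", "lcc_z", "lsc_z")],
              by = "report_id", sort = FALSE)
led_sw <- suppressWarnings(build_ledger(m_sw, "stage_discernment",
                                        random = c("participant_id", "night_id")))
print(led_sw)
write.table(as.data.frame(led_sw),
            "results/followup/ledger_stage_discernment_stopwords.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

measures <- read.delim("results/measures_with_z.tsv")
led_par <- suppressWarnings(build_ledger(measures, "stage_discernment",
                                         random = c("participant_id", "night_id"),
                                         paragraph_covariate = TRUE))
print(led_par)
write.table(as.data.frame(led_par),
            "results/followup/ledger_stage_discernment_paragraphs.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

message("follow-up ledgers written to results/followup/")
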