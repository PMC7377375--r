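#!/usr/bin/env Rscript
# Step 5: hierarchical model-comparison ledgers.
#
# Bottom-up model comparison with random intercepts for participants and
# nights: (a) can any measure predict the time of night beyond sleep
# stage?  (b) can the measures discern the sleep stage of a report?
# (c) do they predict the ordinal 0-9 complexity rating beyond sleep
# stage, individually, as composites over TRC, and with stage-by-measure
# interactions?  (d) do LCC/TRC still discern stage once the complexity
# rating is partialled out?

library(dreamgraph)

measures <- read.delim("results/measures_with_z.tsv")

for (design in c("time_of_night", "stage_discernment", "pirs",
                 "stage_given_pirs")) {
  led <- suppressWarnings(build_ledger(
    measures, design = design,
    random = c("participant_id", "night_id"),
    interactions = design == "pirs"))
  print(led)
  write.table(as.data.frame(led),
              sprintf("results/ledger_%s.tsv", design),
              sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(as.data.frame(led),
                       sprintf("results/ledger_%s.json", design),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}
message("ledgers written to results/ledger_*.tsv / .json")
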