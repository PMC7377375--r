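#!/usr/bin/env Rscript
# Step 4: REM vs N2 comparison on participant medians.
#
# To keep observations independent, each participant contributes one median
# per stage per measure; the paired medians are compared with Wilcoxon
# signed-rank tests, reporting z, the effect size r = |z| / sqrt(n_obs),
# and the two-sided p-value.

library(dreamgraph)

measures <- read.delim("results/measures_with_z.tsv")
tab <- wilcoxon_table(measures)
write.table(tab, "results/wilcoxon.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

message("participant-median Wilcoxon comparison (REM vs N2):")
print(tab, digits = 3)
sig <- tab$measure[tab$significant]
message("measures with a significant stage difference: ",
        if (length(sig)) paste(sig, collapse = ", ") else "none")
message("table written to results/wilcoxon.tsv")
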