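#!/usr/bin/env Rscript
# Step 5: targets of the DE miRNAs (expectation score <= 5) and
# hypergeometric GO enrichment of the target set with BH correction.

library(seedmir)

report <- readRDS("scratch/report.rds")

write.table(report$targets, "results/05_targets.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(report$enrichment, "results/05_go_enrichment.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

sig <- report$enrichment[report$enrichment$significant, ]
cat(sprintf("%d target sites (E <= %g) on %d transcripts for %d DE miRNAs\n",
            nrow(report$targets), report$config$max_e,
            length(unique(report$targets$transcript_id)),
            length(unique(report$targets$mirna))))
cat(sprintf("%d GO terms significant at FDR 0.05; top term: %s (q = %.2g)\n",
            nrow(sig), if (nrow(sig)) sig$term[1] else "none",
            if (nrow(sig)) sig$q[1] else NA))
cat("Tables: results/05_targets.tsv, results/05_go_enrichment.tsv\n")
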