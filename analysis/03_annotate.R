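#!/usr/bin/env Rscript
# Step 3: miRNA annotation summaries — conserved families and isoform
# counts, novel and high-confidence calls, 5'-nucleotide composition.

library(seedmir)

report <- readRDS("scratch/report.rds")

cons <- report$conserved
novel <- report$novel
ann <- rbind(
  data.frame(sequence = cons$sequence, status = "conserved",
             family = cons$family, mismatches = cons$best_mismatches,
             high_confidence = NA, stringsAsFactors = FALSE),
  data.frame(sequence = novel$sequence, status = novel$status,
             family = NA, mismatches = NA,
             high_confidence = novel$high_confidence,
             stringsAsFactors = FALSE))
ann$sequence_rna <- dna_to_rna(ann$sequence)
write.table(ann, "results/03_mirna_annotation.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

iso <- report$family_isoforms
write.table(data.frame(family = names(iso), isoforms = as.integer(iso)),
            "results/03_family_isoforms.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

fp <- rbind(conserved = report$five_prime$conserved,
            novel = report$five_prime$novel)
write.table(data.frame(set = rownames(fp), round(fp, 3)),
            "results/03_five_prime_composition.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

s <- report$annotation_summary
cat(sprintf("Annotated %d conserved miRNAs in %d families; %d novel (%d high-confidence); %d stars\n",
            s[["conserved"]], length(iso), s[["novel"]],
            s[["high_confidence"]], s[["stars"]]))
cat("Conserved 5' composition:",
    paste(sprintf("%s=%.0f%%", colnames(fp),
                  100 * report$five_prime$conserved), collapse = " "),
    "\n")
cat("Tables: results/03_mirna_annotation.tsv, results/03_family_isoforms.tsv,",
    "results/03_five_prime_composition.tsv\n")
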