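#!/usr/bin/env Rscript
# Step 4: expression analysis — CPM matrix, correlation PCA, replicate
# clustering, differential expression (ANOVA over ZE stages, t-test
# MG4B vs MG7), profile clusters, presence Venn counts and the CPM>=100
# shortlist.

library(seedmir)

report <- readRDS("scratch/report.rds")

write.table(data.frame(sequence = rownames(report$cpm),
                       round(report$cpm, 3)),
            "results/04_cpm_matrix.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
pca <- data.frame(library = rownames(report$pca$scores),
                  round(report$pca$scores[, 1:3], 4))
write.table(pca, "results/04_pca_scores.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(data.frame(component = seq_along(report$pca$var_frac),
                       variance_fraction = report$pca$var_frac),
            "results/04_pca_variance.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

de <- report$de_ze
de$cluster <- NA
if (!is.null(report$ze_clusters)) {
  cl <- report$ze_clusters$cluster
  de$cluster[match(names(cl), de$feature)] <- cl
}
write.table(de, "results/04_de_ze_anova.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(report$de_mg, "results/04_de_mg_ttest.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

venn <- do.call(rbind, lapply(names(report$venn), function(st)
  data.frame(stage = st, region = names(report$venn[[st]]),
             count = as.integer(report$venn[[st]]))))
write.table(venn, "results/04_presence_venn.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
writeLines(report$shortlist, "results/04_shortlist_cpm100.txt")

cat(sprintf("PC1/PC2 explain %.1f%% / %.1f%% of the variance\n",
            100 * report$pca$var_frac[1], 100 * report$pca$var_frac[2]))
cat(sprintf("%d of %d miRNAs DE across ZE stages (ANOVA p<0.05), grouped into %d profile clusters (mean silhouette %.2f)\n",
            sum(de$de), nrow(de), report$ze_clusters$k,
            report$ze_clusters$silhouette))
cat(sprintf("%d of %d miRNAs DE between MG4B and MG7 (t-test p<0.05)\n",
            sum(report$de_mg$de), nrow(report$de_mg)))
cat(sprintf("%d miRNAs pass the CPM>=100 shortlist\n",
            length(report$shortlist)))
cat("Replicate pairs merging first in HCL:",
    sum(report$hcl$replicate_pairs$merged_first), "of",
    nrow(report$hcl$replicate_pairs), "\n")
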