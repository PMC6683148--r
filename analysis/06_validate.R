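#!/usr/bin/env Rscript
# Step 6: score the whole run against the planted ground truth.

library(seedmir)

sim <- readRDS("scratch/sim.rds")
report <- readRDS("scratch/report.rds")

m <- validate_against_truth(report, sim$truth)
tab <- data.frame(metric = names(m),
                  value = vapply(m, function(x)
                    if (is.logical(x)) as.numeric(x) else x, numeric(1)))
write.table(tab, "results/06_truth_metrics.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat("Planted-truth recovery:\n")
for (i in seq_len(nrow(tab))) {
  cat(sprintf("  %-28s %.3f\n", tab$metric[i], tab$value[i]))
}
cat("Table: results/06_truth_metrics.tsv\n")
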