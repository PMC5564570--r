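#!/usr/bin/env Rscript
# Stage 5: gene-level aggregation. A gene is DM in a sample when at
# least one promoter CpG is called DM; promoters with both directions
# are inconsistent and excluded. Cross-sample frequencies classify
# genes as universal (> 95% of samples), heterogeneous (20-80%) or
# rare.

library(rmodm)

calls <- read.delim("results/dm_calls.tsv")
annotation <- read_annotation("results/data/annotation.tsv")
tumors <- read_beta_matrix("results/data/tumors.tsv", group = "tumor")

gdm <- genes_from_sites(calls, annotation, samples = colnames(tumors))
gs <- classify_frequency(gdm, universal = 0.95, hetero = c(0.20, 0.80))

cls <- table(gs$class)
cat("Gene frequency classes:",
    paste(sprintf("%s=%d", names(cls), cls), collapse = ", "), "\n")
univ <- gs[grepl("^universal", gs$class), ]
if (nrow(univ)) {
  cat("Universal DM genes (direction, frequency):\n")
  for (i in seq_len(nrow(univ)))
    cat(sprintf("  %s %s %.1f%%\n", univ$gene[i], univ$class[i],
                100 * max(univ$hyper_freq[i], univ$hypo_freq[i])))
}

states_long <- data.frame(
  sample_id = rep(gdm$samples, each = length(gdm$genes)),
  gene = rep(gdm$genes, times = length(gdm$samples)),
  state = as.vector(gdm$states))
write.table(states_long, "results/gene_states.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(gs, "results/gene_summary.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
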