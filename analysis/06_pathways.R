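#!/usr/bin/env Rscript
# Stage 6: individualized pathway analysis. For every sample, pathways
# over-represented among its hyper- and hypomethylated genes
# (hypergeometric test, BH within sample and direction, FDR < 0.1) are
# flagged, and each pathway's cross-sample significance frequency is
# reported.

library(rmodm)

calls <- read.delim("results/dm_calls.tsv")
annotation <- read_annotation("results/data/annotation.tsv")
tumors <- read_beta_matrix("results/data/tumors.tsv", group = "tumor")
pathways <- read_gmt("results/data/pathways.gmt")

gdm <- genes_from_sites(calls, annotation, samples = colnames(tumors))
enr <- enrich_cohort(gdm, pathways, fdr = 0.1)

fr <- enr$frequencies
frequent <- fr[fr$frequency >= 0.30, ]
cat(sprintf("%d pathway/direction pairs significant in >= 30%% of samples:\n",
            nrow(frequent)))
for (i in seq_len(nrow(frequent)))
  cat(sprintf("  %s (%s): %.1f%% of samples\n", frequent$pathway_id[i],
              frequent$direction[i], 100 * frequent$frequency[i]))

write.table(enr$table, "results/enrichment.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(fr, "results/pathway_frequencies.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
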