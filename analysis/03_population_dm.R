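#!/usr/bin/env Rscript
# Stage 3: population-level candidate screening. Two independent
# cohorts (here: interleaved halves of the simulated normals and
# tumors) are tested per site with Welch t-tests under BH control, and
# sites significant in both with the same direction become the
# candidate set for individualized calling.

library(rmodm)

normals <- read_beta_matrix("results/data/normals.tsv", group = "normal")
tumors <- read_beta_matrix("results/data/tumors.tsv", group = "tumor")

halves <- rmodm:::split_cohort_halves(normals, tumors)
resA <- ttest_dm(halves$A, fdr = 0.01)
resB <- ttest_dm(halves$B, fdr = 0.01)
cat(sprintf("Dataset A: %d significant sites; dataset B: %d (FDR < 0.01).\n",
            sum(resA$significant), sum(resB$significant)))

out <- intersect_concordant(resA, resB)
cat(sprintf(
  "%d sites significant in both; %.2f%% direction-concordant; %d candidates kept.\n",
  out$n_overlap, 100 * out$concordant_fraction, nrow(out$candidates)))

write.table(resA, "results/population_dm_A.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(resB, "results/population_dm_B.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(out$candidates, "results/candidates.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
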