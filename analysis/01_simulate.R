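#!/usr/bin/env Rscript
# Stage 1: generate the synthetic methylation cohort used throughout the
# analysis — pooled normals with conserved between-site orderings, tumors
# carrying planted hyper/hypomethylation events, paired adjacent normals,
# promoter annotations and pathway blocks — and write it to
# results/data/ with its full ground truth.

library(rmodm)

cfg <- sim_config(seed = 1)
cohort <- simulate_cohort(cfg)

out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

write_beta_matrix(cohort$normals, file.path(out, "normals.tsv"))
write_beta_matrix(cohort$tumors, file.path(out, "tumors.tsv"))
write_beta_matrix(cohort$adjacents, file.path(out, "adjacents.tsv"))
w <- function(df, f) write.table(df, file.path(out, f), sep = "\t",
                                 quote = FALSE, row.names = FALSE)
w(cohort$pairing, "pairing.tsv")
w(cohort$truth$events, "truth_events.tsv")
w(cohort$annotation, "annotation.tsv")
write_gmt(cohort$pathways, file.path(out, "pathways.gmt"))

cat(sprintf(
  "Simulated %d CpG sites x (%d normals + %d tumors + %d adjacent normals).\n",
  nrow(cohort$normals), ncol(cohort$normals), ncol(cohort$tumors),
  ncol(cohort$adjacents)))
cls <- table(cohort$truth$site_class)
cat(sprintf("Planted truth: %d universal, %d subtype, %d null sites; %d events.\n",
            cls[["universal"]], cls[["subtype"]], cls[["null"]],
            nrow(cohort$truth$events)))
cat("Wrote cohort and ground truth under", out, "\n")
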