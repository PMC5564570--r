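#' Pipeline configuration
#'
#' Collects every threshold of the individualized differential
#' methylation workflow in one flat list: stability fraction `f` for
#' pair mining, population and individual BH-FDR thresholds, pathway
#' FDR, chance-agreement probability `Pe`, minimum partner count,
#' refinement passes, minimum paired beta difference for the precision
#' gold standard, and the gene frequency-class boundaries.
#'
#' @param f Stability threshold fraction (default 0.99).
#' @param population_fdr BH threshold for population-level DM (0.01).
#' @param individual_fdr Per-sample BH threshold for individual calls
#'   (0.01).
#' @param pathway_fdr BH threshold for pathway enrichment (0.1).
#' @param Pe Chance agreement probability for pair-list concordance
#'   (0.5).
#' @param min_partners Minimum stable partners for a testable site (5).
#' @param refine_iters Refinement passes in [call_sample()] (1).
#' @param delta_min Minimum paired beta difference for a gold direction
#'   (0).
#' @param universal Strict universality frequency threshold (0.95).
#' @param hetero Closed heterogeneous frequency interval (0.20, 0.80).
#' @param sim A [sim_config()] describing the synthetic cohort.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(f = 0.99, population_fdr = 0.01,
                            individual_fdr = 0.01, pathway_fdr = 0.1,
                            Pe = 0.5, min_partners = 5, refine_iters = 1,
                            delta_min = 0, universal = 0.95,
                            hetero = c(0.20, 0.80), sim = sim_config()) {
  cfg <- list(f = f, population_fdr = population_fdr,
              individual_fdr = individual_fdr, pathway_fdr = pathway_fdr,
              Pe = Pe, min_partners = min_partners,
              refine_iters = refine_iters, delta_min = delta_min,
              universal = universal, hetero = hetero, sim = sim)
  stopifnot(f > 0.5, f <= 1,
            population_fdr > 0, population_fdr < 1,
            individual_fdr > 0, individual_fdr < 1,
            pathway_fdr > 0, pathway_fdr < 1,
            Pe > 0, Pe < 1, min_partners >= 0, refine_iters >= 0,
            delta_min >= 0, universal > 0, universal <= 1,
            length(hetero) == 2, hetero[1] <= hetero[2])
  validate_sim_config(sim)
  structure(cfg, class = "pipeline_config")
}

#' Run the full individualized differential-methylation workflow
#'
#' Executes, on a synthetic cohort generated from `config$sim`:
#' simulate -> stable-pair mining on pooled normals (plus a two-platform
#' split concordance check) -> population-level candidate screening on
#' two half-cohorts -> per-sample RankComp-style calling -> precision
#' evaluation against paired adjacent normals -> gene aggregation and
#' frequency classification -> per-sample pathway enrichment. All stage
#' outputs are written as TSV under `out_dir` together with a
#' machine-readable `summary.json`; a rerun with the same config is
#' byte-identical.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if missing); `NULL` skips
#'   all file output.
#' @return The summary list, invisibly containing all stage results in
#'   `stages`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage `%s` failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  cohort <- stage("simulate", simulate_cohort(config$sim))
  message(sprintf("simulate: %d sites, %d normals, %d tumors, %d pairs",
                  nrow(cohort$normals), ncol(cohort$normals),
                  ncol(cohort$tumors), nrow(cohort$pairing)))

  sps <- stage("stable_pairs", find_stable_pairs(cohort$normals, config$f))
  message(sprintf("stable_pairs: %d ordered pairs (threshold %d/%d)",
                  nrow(sps$pairs), sps$threshold, sps$n_samples_used))

  # cross-platform reproducibility of the stable orderings
  plat <- stage("platforms", {
    sp <- split_platforms(cohort$normals,
                          config$sim$platform_overlap_fraction)
    concordance(find_stable_pairs(sp$platformA, config$f),
                find_stable_pairs(sp$platformB, config$f), Pe = config$Pe)
  })
  message(sprintf("platform concordance: %.4f over %d shared pairs (p=%.3g)",
                  plat$concordance, plat$k, plat$p_value))

  # population-level candidates from two half-cohorts
  pop <- stage("population_dm", {
    halves <- split_cohort_halves(cohort$normals, cohort$tumors)
    resA <- ttest_dm(halves$A, fdr = config$population_fdr)
    resB <- ttest_dm(halves$B, fdr = config$population_fdr)
    c(intersect_concordant(resA, resB), list(resA = resA, resB = resB))
  })
  message(sprintf(
    "population_dm: %d/%d significant in both concordant (%.2f%%), %d candidates",
    pop$n_concordant, pop$n_overlap, 100 * pop$concordant_fraction,
    nrow(pop$candidates)))

  calls <- stage("rankcomp",
                 call_cohort(cohort$tumors, pop$candidates, sps,
                             fdr = config$individual_fdr,
                             min_partners = config$min_partners,
                             refine_iters = config$refine_iters))
  counts <- attr(calls, "per_sample_counts")
  message(sprintf("rankcomp: %.1f DM sites per sample on average",
                  mean(counts)))

  prec <- stage("evaluate",
                evaluate_precision(
                  calls[calls$sample_id %in% cohort$pairing$tumor_id, ],
                  cohort$tumors, cohort$adjacents, cohort$pairing,
                  delta_min = config$delta_min))
  message(sprintf("precision: mean %.4f over %d paired samples",
                  prec$mean_precision, nrow(prec$per_sample)))

  gdm <- stage("aggregate",
               genes_from_sites(calls, cohort$annotation,
                                samples = sample_ids(cohort$tumors)))
  gene_summary <- classify_frequency(gdm, universal = config$universal,
                                     hetero = config$hetero)
  message(sprintf("aggregate: %s",
                  paste(sprintf("%s=%d", names(table(gene_summary$class)),
                                table(gene_summary$class)), collapse = ", ")))

  enr <- stage("enrich",
               enrich_cohort(gdm, cohort$pathways, fdr = config$pathway_fdr))
  top <- enr$frequencies[!duplicated(enr$frequencies$direction), ]
  message(sprintf("enrich: top frequency %s",
                  paste(sprintf("%s/%s=%.2f", top$pathway_id, top$direction,
                                top$frequency), collapse = ", ")))

  summary <- list(
    seed = config$sim$seed,
    config = config_to_list(config),
    n_stable_pairs = nrow(sps$pairs),
    platform_concordance = plat$concordance,
    platform_overlap_fraction = plat$overlap_fraction,
    population = list(n_sig_A = sum(pop$resA$significant),
                      n_sig_B = sum(pop$resB$significant),
                      n_overlap = pop$n_overlap,
                      concordant_fraction = pop$concordant_fraction,
                      n_candidates = nrow(pop$candidates)),
    mean_dm_sites_per_sample = mean(counts),
    mean_precision = prec$mean_precision,
    gene_classes = as.list(table(gene_summary$class)),
    top_pathway_frequencies = top$frequency)

  if (!is.null(out_dir)) {
    w <- function(df, name)
      utils::write.table(df, file.path(out_dir, name), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    write_beta_matrix(cohort$normals, file.path(out_dir, "normals.tsv"))
    write_beta_matrix(cohort$tumors, file.path(out_dir, "tumors.tsv"))
    write_beta_matrix(cohort$adjacents, file.path(out_dir, "adjacents.tsv"))
    w(cohort$pairing, "pairing.tsv")
    w(cohort$truth$events, "truth_events.tsv")
    w(cohort$annotation, "annotation.tsv")
    write_gmt(cohort$pathways, file.path(out_dir, "pathways.gmt"))
    write_stable_pairs(sps, file.path(out_dir, "stable_pairs.tsv"))
    w(pop$candidates, "candidates.tsv")
    w(calls, "dm_calls.tsv")
    w(prec$per_sample, "precision.tsv")
    w(gene_summary, "gene_summary.tsv")
    w(enr$table, "enrichment.tsv")
    w(enr$frequencies, "pathway_frequencies.tsv")
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  invisible(c(summary,
              list(stages = list(cohort = cohort, stable_pairs = sps,
                                 platform = plat, population = pop,
                                 calls = calls, precision = prec,
                                 gene_dm = gdm, gene_summary = gene_summary,
                                 enrichment = enr))))
}

# deterministic interleaved split of normals and tumors into two
# half-cohorts, each with both groups, for the two-dataset population
# screen
split_cohort_halves <- function(normals, tumors) {
  nn <- ncol(normals); nt <- ncol(tumors)
  n_idx <- seq_len(nn) %% 2 == 1
  t_idx <- seq_len(nt) %% 2 == 1
  bind <- function(a, b) {
    v <- cbind(unclass(a), unclass(b))
    attr(v, "group") <- NULL
    beta_matrix(v, group = c(sample_groups(a), sample_groups(b)))
  }
  list(A = bind(bm_subset(normals, samples = which(n_idx)),
                bm_subset(tumors, samples = which(t_idx))),
       B = bind(bm_subset(normals, samples = which(!n_idx)),
                bm_subset(tumors, samples = which(!t_idx))))
}

config_to_list <- function(config) {
  out <- unclass(config)
  out$sim <- unclass(out$sim)
  out
}
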