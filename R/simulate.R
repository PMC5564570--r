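logit <- function(p) log(p / (1 - p))
inv_logit <- function(x) 1 / (1 + exp(-x))

BETA_EPS <- 1e-6

clip_beta <- function(b) pmin(pmax(b, BETA_EPS), 1 - BETA_EPS)

#' Configuration for the synthetic methylation cohort
#'
#' Describes a cohort with the statistical structure the individualized
#' analysis assumes: a pool of normal samples whose between-site beta
#' orderings are highly conserved, tumor samples carrying planted
#' hyper-/hypomethylation events at controlled per-site frequencies, and
#' paired tumor/adjacent-normal samples. Sites are tied to gene
#' promoters in consecutive blocks and genes to pathways in consecutive
#' blocks, so planted signal propagates cleanly to the gene and pathway
#' level.
#'
#' The noise model is additive Gaussian on the logit of the beta value,
#' which keeps betas inside (0, 1) and mimics the bounded, heteroscedastic
#' behaviour of array beta values. A planted event shifts the logit by
#' `+effect_size` (hypermethylation) or `-effect_size` (hypomethylation)
#' before noise; the direction is fixed per gene block so promoter CpGs
#' of one gene move coherently.
#'
#' @param n_sites Number of CpG sites.
#' @param n_normals Number of pooled normal samples.
#' @param n_tumors Number of tumor samples.
#' @param n_paired Number of tumors with a paired adjacent normal
#'   (`<= n_tumors`).
#' @param baseline_range Range (low, high) of per-site baseline beta
#'   values, drawn uniformly.
#' @param dm_baseline_range Range of baseline beta values for *planted*
#'   (universal/subtype) sites. Cancer differential methylation
#'   concentrates at CpGs with intermediate normal methylation, and a
#'   site needs stable partners both above and below it for ordering
#'   disruption to carry directional evidence, so planted sites sit in
#'   the interior of the methylation spectrum; null sites span the full
#'   `baseline_range`.
#' @param noise_sd Standard deviation of logit-scale noise (>= 0; 0 is
#'   the noiseless limit).
#' @param universal_fraction Fraction of sites planted as events in at
#'   least 95% of tumors ("universal" sites).
#' @param subtype_fraction Fraction of sites planted in 20-80% of tumors
#'   ("subtype" sites).
#' @param effect_size Logit-scale shift of a planted event (>= 0).
#' @param hyper_prob Probability that a planted gene block is
#'   hypermethylated (vs hypomethylated).
#' @param platform_overlap_fraction Fraction of sites shared by the two
#'   simulated platform subsets (see [split_platforms()]).
#' @param genes_per_pathway Genes per simulated pathway block.
#' @param sites_per_gene Consecutive sites per gene promoter.
#' @param seed Integer seed for the root generator; all component
#'   sub-streams are derived from it deterministically.
#' @return A `sim_config` list, validated.
#' @export
sim_config <- function(n_sites = 600, n_normals = 40, n_tumors = 30,
                       n_paired = 20, baseline_range = c(0.1, 0.9),
                       dm_baseline_range = c(0.3, 0.7),
                       noise_sd = 0.3, universal_fraction = 0.05,
                       subtype_fraction = 0.15, effect_size = 2.0,
                       hyper_prob = 0.5, platform_overlap_fraction = 0.8,
                       genes_per_pathway = 10, sites_per_gene = 3,
                       seed = 1L) {
  cfg <- list(n_sites = n_sites, n_normals = n_normals, n_tumors = n_tumors,
              n_paired = n_paired, baseline_range = baseline_range,
              dm_baseline_range = dm_baseline_range,
              noise_sd = noise_sd, universal_fraction = universal_fraction,
              subtype_fraction = subtype_fraction, effect_size = effect_size,
              hyper_prob = hyper_prob,
              platform_overlap_fraction = platform_overlap_fraction,
              genes_per_pathway = genes_per_pathway,
              sites_per_gene = sites_per_gene, seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  chk <- function(ok, field, msg) {
    if (!ok) stop(sprintf("invalid sim_config field `%s`: %s", field, msg),
                  call. = FALSE)
  }
  for (f in c("n_sites", "n_normals", "n_tumors", "n_paired",
              "genes_per_pathway", "sites_per_gene"))
    chk(is.numeric(cfg[[f]]) && length(cfg[[f]]) == 1 && cfg[[f]] >= 0 &&
          cfg[[f]] == round(cfg[[f]]), f, "must be a non-negative integer")
  chk(cfg$n_sites >= 1, "n_sites", "must be >= 1")
  chk(cfg$n_paired <= cfg$n_tumors, "n_paired", "must be <= n_tumors")
  for (f in c("baseline_range", "dm_baseline_range"))
    chk(length(cfg[[f]]) == 2 && all(cfg[[f]] > 0 & cfg[[f]] < 1) &&
          cfg[[f]][1] <= cfg[[f]][2],
        f, "must be (low, high) strictly inside (0,1)")
  chk(cfg$noise_sd >= 0, "noise_sd", "must be >= 0")
  chk(cfg$effect_size >= 0, "effect_size", "must be >= 0")
  for (f in c("universal_fraction", "subtype_fraction", "hyper_prob",
              "platform_overlap_fraction"))
    chk(cfg[[f]] >= 0 && cfg[[f]] <= 1, f, "must be in [0,1]")
  chk(cfg$universal_fraction + cfg$subtype_fraction <= 1,
      "universal_fraction", "universal_fraction + subtype_fraction must be <= 1")
  invisible(cfg)
}

#' Simulate a methylation cohort with full ground truth
#'
#' Draws per-site baselines uniformly from `baseline_range`; a normal
#' sample's beta at site i is `inv_logit(logit(mu_i) + eps)` with
#' `eps ~ N(0, noise_sd^2)`. Universal sites are planted as events in at
#' least `ceil(0.95 * n_tumors)` tumors; subtype sites in a uniformly
#' drawn 20-80% subset. Paired adjacent normals carry no planted events.
#' All betas are clipped to the open interval (0, 1).
#'
#' @param config A [sim_config()].
#' @return A list with components `normals`, `tumors`, `adjacents`
#'   ([beta_matrix()] objects), `pairing` (data.frame `tumor_id`,
#'   `adjacent_id`), `truth` (list: `events` data.frame with `site_id`,
#'   `sample_id`, `direction`, `shift`; `site_class`; `site_direction`;
#'   `baseline`), `annotation` (data.frame `probe_id`, `gene_symbol`)
#'   and `pathways` (named list of gene vectors).
#' @export
simulate_cohort <- function(config) {
  cfg <- validate_sim_config(config)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(cfg$seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, 5L)

  n <- cfg$n_sites
  sites <- sprintf("cg%06d", seq_len(n))
  n_genes <- ceiling(n / cfg$sites_per_gene)
  genes <- sprintf("GENE%04d", seq_len(n_genes))
  annotation <- data.frame(
    probe_id = sites,
    gene_symbol = genes[ceiling(seq_len(n) / cfg$sites_per_gene)])
  n_pw <- max(1L, ceiling(n_genes / cfg$genes_per_pathway))
  pathways <- split(genes,
                    ceiling(seq_len(n_genes) / cfg$genes_per_pathway))
  names(pathways) <- sprintf("PATHWAY%03d", seq_len(n_pw))

  # baselines and planted structure
  set.seed(sub_seeds[1])
  n_univ <- round(cfg$universal_fraction * n)
  n_sub <- round(cfg$subtype_fraction * n)
  site_class <- rep("null", n)
  site_class[seq_len(n_univ)] <- "universal"
  if (n_sub > 0) site_class[n_univ + seq_len(n_sub)] <- "subtype"
  names(site_class) <- sites
  mu <- stats::runif(n, cfg$baseline_range[1], cfg$baseline_range[2])
  planted <- site_class != "null"
  mu[planted] <- stats::runif(sum(planted), cfg$dm_baseline_range[1],
                              cfg$dm_baseline_range[2])
  names(mu) <- sites
  # one direction per gene block, so promoter CpGs move coherently
  gene_dir <- ifelse(stats::runif(n_genes) < cfg$hyper_prob, "hyper", "hypo")
  site_direction <- ifelse(site_class == "null", NA_character_,
                           gene_dir[ceiling(seq_len(n) / cfg$sites_per_gene)])
  names(site_direction) <- sites

  tumors_ids <- sprintf("T%03d", seq_len(cfg$n_tumors))
  # carrier tumors per planted site
  set.seed(sub_seeds[2])
  events <- list()
  if (cfg$n_tumors > 0) {
    min_univ <- ceiling(0.95 * cfg$n_tumors)
    for (i in which(site_class != "null")) {
      k <- if (site_class[i] == "universal") {
        if (min_univ >= cfg$n_tumors) cfg$n_tumors
        else sample(min_univ:cfg$n_tumors, 1)
      } else {
        f <- stats::runif(1, 0.20, 0.80)
        lo <- ceiling(0.20 * cfg$n_tumors)
        hi <- max(lo, floor(0.80 * cfg$n_tumors))
        min(max(round(f * cfg$n_tumors), lo, 1L), hi)
      }
      carriers <- sample(tumors_ids, k)
      events[[length(events) + 1L]] <- data.frame(
        site_id = sites[i], sample_id = carriers,
        direction = unname(site_direction[i]),
        shift = unname(ifelse(site_direction[i] == "hyper", cfg$effect_size,
                              -cfg$effect_size)))
    }
  }
  events <- if (length(events)) do.call(rbind, events) else
    data.frame(site_id = character(), sample_id = character(),
               direction = character(), shift = numeric())
  rownames(events) <- NULL

  base_logit <- logit(mu)
  draw <- function(n_samp, prefix, seed, shift_mat = NULL) {
    set.seed(seed)
    ids <- sprintf("%s%03d", prefix, seq_len(n_samp))
    m <- matrix(rep(base_logit, n_samp), nrow = n, ncol = n_samp)
    if (!is.null(shift_mat)) m <- m + shift_mat
    m <- m + matrix(stats::rnorm(n * n_samp, 0, cfg$noise_sd), n, n_samp)
    matrix(clip_beta(inv_logit(m)), n, n_samp, dimnames = list(sites, ids))
  }

  normals <- beta_matrix(draw(cfg$n_normals, "N", sub_seeds[3]),
                         group = "normal")
  shift_mat <- matrix(0, n, cfg$n_tumors,
                      dimnames = list(sites, tumors_ids))
  if (nrow(events)) shift_mat[cbind(events$site_id, events$sample_id)] <-
    events$shift
  tumors <- beta_matrix(draw(cfg$n_tumors, "T", sub_seeds[4],
                             shift_mat = shift_mat), group = "tumor")
  adjacents <- beta_matrix(draw(cfg$n_paired, "A", sub_seeds[5]),
                           group = "adjacent_normal")
  pairing <- data.frame(tumor_id = tumors_ids[seq_len(cfg$n_paired)],
                        adjacent_id = sprintf("A%03d", seq_len(cfg$n_paired)))

  list(normals = normals, tumors = tumors, adjacents = adjacents,
       pairing = pairing,
       truth = list(events = events, site_class = site_class,
                    site_direction = site_direction, baseline = mu),
       annotation = annotation, pathways = pathways, config = cfg)
}

#' Split a beta matrix into two platform-like site subsets
#'
#' Emulates two array platforms measuring overlapping probe sets: the
#' shared core has `round(platform_overlap_fraction * n_sites)` sites
#' and the remaining sites are dealt alternately to the two platforms,
#' so the union covers all sites. Deterministic given the matrix.
#'
#' @param matrix A [beta_matrix()].
#' @param platform_overlap_fraction Fraction of sites on both platforms,
#'   in \[0, 1\].
#' @return List with `platformA`, `platformB` (beta matrices) and
#'   `shared` (character vector of shared site ids).
#' @export
split_platforms <- function(matrix, platform_overlap_fraction) {
  if (nrow(matrix) == 0) stop("empty beta matrix", call. = FALSE)
  if (platform_overlap_fraction < 0 || platform_overlap_fraction > 1)
    stop("platform_overlap_fraction must be in [0,1]", call. = FALSE)
  n <- nrow(matrix)
  n_shared <- round(platform_overlap_fraction * n)
  ids <- site_ids(matrix)
  shared <- ids[seq_len(n_shared)]
  rest <- ids[setdiff(seq_len(n), seq_len(n_shared))]
  a_only <- rest[seq_along(rest) %% 2 == 1]
  b_only <- rest[seq_along(rest) %% 2 == 0]
  list(platformA = bm_subset(matrix, sites = c(shared, a_only)),
       platformB = bm_subset(matrix, sites = c(shared, b_only)),
       shared = shared)
}
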