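#' Hypergeometric over-representation of a gene set in a pathway
#'
#' Upper-tail hypergeometric probability of observing at least `k`
#' overlaps between the DM gene set and a pathway when `n` genes are
#' drawn from a universe of `N` genes of which `K` belong to the
#' pathway. Both sets are restricted to the universe before testing.
#'
#' @param dm_genes Character vector of DM gene symbols.
#' @param pathway Character vector of pathway gene symbols.
#' @param universe Character vector of background gene symbols.
#' @return List: `k`, `K`, `n`, `N`, `p`, `tested` (FALSE when the
#'   universe or the restricted DM set is empty).
#' @export
hypergeom_enrich <- function(dm_genes, pathway, universe) {
  universe <- unique(universe)
  N <- length(universe)
  dm <- intersect(unique(dm_genes), universe)
  pw <- intersect(unique(pathway), universe)
  k <- length(intersect(dm, pw)); K <- length(pw); n <- length(dm)
  if (N == 0 || n == 0)
    return(list(k = k, K = K, n = n, N = N, p = NA_real_, tested = FALSE))
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  list(k = k, K = K, n = n, N = N, p = p, tested = TRUE)
}

#' Per-sample pathway enrichment of hyper- and hypomethylated genes
#'
#' For every sample and each direction separately, each pathway is
#' tested for over-representation of that sample's DM genes (genes in
#' the `inconsistent` state belong to neither set). P-values are
#' BH-adjusted across pathways within each (sample, direction) family.
#' The cross-sample significance frequency of a pathway-direction is the
#' fraction of all cohort samples in which it is significant (samples
#' with an empty DM set count as not significant).
#'
#' @param gene_dm A `gene_dm` from [genes_from_sites()].
#' @param pathways Named list of gene-symbol vectors (e.g. from
#'   [read_gmt()]).
#' @param fdr BH threshold for the significance flag (default 0.1).
#' @param universe Background gene set; defaults to the genes covered by
#'   the pathway collection intersected with the measured (annotated)
#'   genes.
#' @return List: `table` (data.frame `sample_id`, `pathway_id`,
#'   `direction`, `k`, `K`, `n`, `N`, `p`, `q`, `significant`) and
#'   `frequencies` (data.frame `pathway_id`, `direction`, `frequency`).
#' @export
enrich_cohort <- function(gene_dm, pathways, fdr = 0.1, universe = NULL) {
  if (length(pathways) == 0) stop("pathway collection is empty", call. = FALSE)
  if (ncol(gene_dm$states) < 1) stop("need at least one sample", call. = FALSE)
  if (is.null(universe))
    universe <- intersect(unique(unlist(pathways, use.names = FALSE)),
                          gene_dm$genes)
  samples <- gene_dm$samples
  out <- vector("list", length(samples) * 2L)
  ix <- 0L
  for (sid in samples) {
    st <- gene_dm$states[, sid]
    for (dir in c("hyper", "hypo")) {
      dm <- gene_dm$genes[st == dir]
      rows <- lapply(names(pathways), function(pid) {
        h <- hypergeom_enrich(dm, pathways[[pid]], universe)
        data.frame(sample_id = sid, pathway_id = pid, direction = dir,
                   k = h$k, K = h$K, n = h$n, N = h$N, p = h$p,
                   tested = h$tested)
      })
      df <- do.call(rbind, rows)
      df$q <- NA_real_
      df$q[df$tested] <- stats::p.adjust(df$p[df$tested], method = "BH")
      df$significant <- df$tested & !is.na(df$q) & df$q < fdr
      ix <- ix + 1L
      out[[ix]] <- df
    }
  }
  tab <- do.call(rbind, out)
  rownames(tab) <- NULL
  freq <- stats::aggregate(significant ~ pathway_id + direction, tab,
                           function(z) sum(z) / length(samples))
  names(freq)[names(freq) == "significant"] <- "frequency"
  freq <- freq[order(freq$direction, -freq$frequency, freq$pathway_id), ]
  rownames(freq) <- NULL
  list(table = tab, frequencies = freq)
}
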