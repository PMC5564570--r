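#' Lift site-level DM calls to gene-level states per sample
#'
#' A gene is DM in a sample if at least one CpG site in its promoter is
#' called DM: state `hyper` when at least one promoter CpG is called
#' hyper and none hypo, `hypo` symmetrically, `inconsistent` when both
#' directions occur (such genes are excluded from frequency counting and
#' enrichment for that sample), `none` otherwise. DM probes without a
#' gene annotation are ignored (their count is reported via a message).
#'
#' @param calls DM call table from [call_cohort()].
#' @param annotation data.frame `probe_id`, `gene_symbol` (one gene per
#'   probe).
#' @param samples Optional character vector fixing the sample universe
#'   (defaults to the samples present in `calls`).
#' @return A `gene_dm` object: list with `states` (gene x sample
#'   character matrix over all annotated genes), `genes`, `samples`.
#' @export
genes_from_sites <- function(calls, annotation, samples = NULL) {
  if (anyDuplicated(annotation$probe_id))
    annotation <- annotation[!duplicated(annotation$probe_id), ]
  if (is.null(samples)) samples <- unique(calls$sample_id)
  genes <- sort(unique(annotation$gene_symbol))
  states <- matrix("none", nrow = length(genes), ncol = length(samples),
                   dimnames = list(genes, samples))
  dm <- calls[calls$direction %in% c("hyper", "hypo"), , drop = FALSE]
  if (nrow(dm)) {
    g <- annotation$gene_symbol[match(dm$site_id, annotation$probe_id)]
    n_unannot <- sum(is.na(g))
    if (n_unannot)
      message(n_unannot, " DM probe call(s) without gene annotation ignored")
    keep <- !is.na(g)
    dm <- dm[keep, , drop = FALSE]; g <- g[keep]
    hyper <- dm$direction == "hyper"
    has_hyper <- matrix(FALSE, length(genes), length(samples),
                        dimnames = dimnames(states))
    has_hypo <- has_hyper
    has_hyper[cbind(g[hyper], dm$sample_id[hyper])] <- TRUE
    has_hypo[cbind(g[!hyper], dm$sample_id[!hyper])] <- TRUE
    states[has_hyper & !has_hypo] <- "hyper"
    states[!has_hyper & has_hypo] <- "hypo"
    states[has_hyper & has_hypo] <- "inconsistent"
  }
  structure(list(states = states, genes = genes, samples = samples),
            class = "gene_dm")
}

#' @export
print.gene_dm <- function(x, ...) {
  cat(sprintf("gene_dm: %d genes x %d samples; states: %s\n",
              length(x$genes), length(x$samples),
              paste(sprintf("%s=%d", names(table(x$states)),
                            table(x$states)), collapse = ", ")))
  invisible(x)
}

#' Cross-sample gene DM frequencies and frequency classes
#'
#' Per gene, the hyper (hypo) frequency is the fraction of all cohort
#' samples in which the gene is in the hyper (hypo) state; samples where
#' the gene is inconsistent count in the denominator but never in a
#' numerator. Classes: `universal_hyper` / `universal_hypo` when the
#' corresponding frequency strictly exceeds `universal` ("more than
#' 95%"); else `heterogeneous` when either frequency lies in the closed
#' interval `hetero`; else `rare`.
#'
#' @param gene_dm A `gene_dm` from [genes_from_sites()].
#' @param universal Strict universality threshold (default 0.95).
#' @param hetero Closed interval for heterogeneous genes (default
#'   `c(0.20, 0.80)`).
#' @return data.frame per gene: `gene`, `hyper_freq`, `hypo_freq`,
#'   `inconsistent_freq`, `none_freq`, `class`.
#' @export
classify_frequency <- function(gene_dm, universal = 0.95,
                               hetero = c(0.20, 0.80)) {
  st <- gene_dm$states
  if (ncol(st) < 1) stop("need at least one sample", call. = FALSE)
  n <- ncol(st)
  hyper <- rowSums(st == "hyper") / n
  hypo <- rowSums(st == "hypo") / n
  inc <- rowSums(st == "inconsistent") / n
  cls <- ifelse(hyper > universal, "universal_hyper",
         ifelse(hypo > universal, "universal_hypo",
         ifelse((hyper >= hetero[1] & hyper <= hetero[2]) |
                (hypo >= hetero[1] & hypo <= hetero[2]),
                "heterogeneous", "rare")))
  data.frame(gene = gene_dm$genes, hyper_freq = hyper, hypo_freq = hypo,
             inconsistent_freq = inc, none_freq = 1 - hyper - hypo - inc,
             class = cls, row.names = NULL)
}
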