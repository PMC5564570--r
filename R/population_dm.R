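#' Population-level differential methylation by per-site t-test
#'
#' Two-sample t-test (Welch by default) of tumor vs normal beta values
#' at every site, with Benjamini-Hochberg adjustment across all tested
#' sites in the dataset. The direction of a site is the sign of
#' `mean(tumor) - mean(normal)` on the beta scale: positive is
#' hypermethylation. Sites with fewer than two non-missing values in
#' either group are marked untested and never significant.
#'
#' @param dataset A [beta_matrix()] whose group labels include both
#'   `"tumor"` and `"normal"` (adjacent normals count as normal).
#' @param fdr BH false-discovery threshold for the `significant` flag.
#' @param var_equal Use the pooled-variance Student t-test instead of
#'   Welch.
#' @return A data.frame, one row per site: `site_id`, `t`, `p`, `q`,
#'   `direction` (`"hyper"`/`"hypo"`/`NA`), `significant`, `tested`.
#' @export
ttest_dm <- function(dataset, fdr = 0.01, var_equal = FALSE) {
  grp <- sample_groups(dataset)
  if (is.null(grp))
    stop("dataset needs group labels (tumor/normal)", call. = FALSE)
  tum <- unclass(dataset)[, grp == "tumor", drop = FALSE]
  nor <- unclass(dataset)[, grp %in% c("normal", "adjacent_normal"),
                          drop = FALSE]
  if (ncol(tum) == 0 || ncol(nor) == 0)
    stop("dataset must contain both tumor and normal samples", call. = FALSE)
  n <- nrow(dataset)
  t_stat <- p <- rep(NA_real_, n)
  diff <- rowMeans(tum, na.rm = TRUE) - rowMeans(nor, na.rm = TRUE)
  tested <- rowSums(!is.na(tum)) >= 2 & rowSums(!is.na(nor)) >= 2
  for (i in which(tested)) {
    tt <- tryCatch(stats::t.test(tum[i, ], nor[i, ], var.equal = var_equal),
                   error = function(e) NULL)
    if (is.null(tt)) { tested[i] <- FALSE; next }  # e.g. zero variance
    t_stat[i] <- unname(tt$statistic)
    p[i] <- tt$p.value
  }
  q <- rep(NA_real_, n)
  q[tested] <- stats::p.adjust(p[tested], method = "BH")
  res <- data.frame(site_id = site_ids(dataset), t = t_stat, p = p, q = q,
                    direction = ifelse(!tested | diff == 0, NA,
                                       ifelse(diff > 0, "hyper", "hypo")),
                    significant = !is.na(q) & q < fdr, tested = tested)
  rownames(res) <- NULL
  attr(res, "fdr") <- fdr
  res
}

#' Concordant intersection of two population-level DM results
#'
#' The reproducible candidate set for individualized calling: sites
#' significant in both datasets with the same direction. Discordant
#' overlaps (significant in both but with opposite direction) are
#' counted and reported but excluded.
#'
#' @param resA,resB Results from [ttest_dm()] over a shared site
#'   universe.
#' @return List: `candidates` (data.frame `site_id`, `direction`),
#'   `n_overlap` (significant in both), `n_concordant`,
#'   `concordant_fraction`, `discordant` (site ids).
#' @export
intersect_concordant <- function(resA, resB) {
  sigA <- resA[resA$significant, c("site_id", "direction")]
  sigB <- resB[resB$significant, c("site_id", "direction")]
  m <- merge(sigA, sigB, by = "site_id", suffixes = c("_a", "_b"))
  conc <- !is.na(m$direction_a) & !is.na(m$direction_b) &
    m$direction_a == m$direction_b
  candidates <- data.frame(site_id = m$site_id[conc],
                           direction = m$direction_a[conc])
  candidates <- candidates[order(candidates$site_id), ]
  rownames(candidates) <- NULL
  if (nrow(candidates) == 0)
    warning("no concordant population-level DM sites; candidate list is empty")
  list(candidates = candidates,
       n_overlap = nrow(m),
       n_concordant = sum(conc),
       concordant_fraction = if (nrow(m)) sum(conc) / nrow(m) else NA_real_,
       discordant = m$site_id[!conc])
}
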