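#' Reversal counts of a CpG site in one cancer sample
#'
#' For site c with stable partners in normal tissue, a partner stably
#' *above* c that is observed strictly *below* c in the cancer sample is
#' a reversal supporting hypermethylation of c; a partner stably below c
#' observed strictly above supports hypomethylation. Ties are
#' non-reversals; partners with a missing value in the sample are
#' dropped from numerator and denominator alike.
#'
#' @param sample_beta Named numeric vector of beta values for one cancer
#'   sample (names are site ids).
#' @param site Site id of c.
#' @param pairs A `stable_pair_set` (see [find_stable_pairs()]).
#' @return List: `site`, `n_above`, `n_below`, `r_above`, `r_below`,
#'   `tested` (FALSE when c has no stable partner or its own value is
#'   missing).
#' @export
count_reversals <- function(sample_beta, site, pairs) {
  above <- partners_above(pairs, site)
  below <- partners_below(pairs, site)
  count_reversals_idx(sample_beta, sample_beta[site],
                      sample_beta[above], sample_beta[below], site)
}

# internal worker shared with call_sample: takes partner values directly
count_reversals_idx <- function(sample_beta, x_c, x_above, x_below, site) {
  if (length(x_above) + length(x_below) == 0 || is.na(x_c))
    return(list(site = site, n_above = 0L, n_below = 0L,
                r_above = 0L, r_below = 0L, tested = FALSE))
  x_above <- x_above[!is.na(x_above)]
  x_below <- x_below[!is.na(x_below)]
  list(site = site,
       n_above = length(x_above), n_below = length(x_below),
       r_above = sum(x_above < x_c), r_below = sum(x_below > x_c),
       tested = TRUE)
}

#' Fisher's exact test on reversal asymmetry
#'
#' Tests the null hypothesis that the proportion of reversal pairs
#' supporting hypermethylation of the site equals the proportion
#' supporting hypomethylation, via a two-sided Fisher's exact test on
#' the 2x2 table
#' `[[r_above, n_above - r_above], [r_below, n_below - r_below]]`
#' (probability-mass two-sidedness: the p-value sums all tables with
#' fixed margins whose probability does not exceed the observed
#' table's). The direction hint compares the two reversal proportions.
#'
#' @param counts A list as returned by [count_reversals()].
#' @return List: `p`, `direction_hint` (`"hyper"`, `"hypo"` or
#'   `"none"`), `tested`.
#' @export
fisher_dm <- function(counts) {
  na <- counts$n_above; nb <- counts$n_below
  ra <- counts$r_above; rb <- counts$r_below
  if (isFALSE(counts$tested) || na + nb == 0)
    return(list(p = NA_real_, direction_hint = "none", tested = FALSE))
  tab <- matrix(c(ra, na - ra, rb, nb - rb), nrow = 2, byrow = TRUE)
  p <- stats::fisher.test(tab)$p.value
  pa <- if (na > 0) ra / na else 0
  pb <- if (nb > 0) rb / nb else 0
  hint <- if (pa > pb) "hyper" else if (pa < pb) "hypo" else "none"
  list(p = min(p, 1), direction_hint = hint, tested = TRUE)
}

#' Call DM CpG sites in a single cancer sample
#'
#' For every population-level candidate site, reversal counts against
#' the stable-pair background are tested with [fisher_dm()]; p-values
#' are BH-adjusted across the tested candidates *within this sample*
#' (each call is a per-sample claim), and a direction is assigned where
#' `q < fdr`. With `refine_iters > 0`, partners that were themselves
#' called DM in the previous pass are excluded from every site's counts
#' and the pass is rerun, cleaning the normal-ordering background of
#' disrupted partners.
#'
#' @param sample_beta Named numeric vector of one cancer sample's betas.
#' @param candidates data.frame with column `site_id` (and optionally
#'   `direction`, the population-level direction, carried through).
#' @param pairs A `stable_pair_set`.
#' @param fdr Per-sample BH threshold (default 0.01).
#' @param min_partners Minimum total stable partners for a site to be
#'   testable (default 5).
#' @param refine_iters Number of refinement passes (default 1; 0
#'   disables).
#' @param sample_id Sample identifier recorded in the output.
#' @return data.frame, one row per candidate: `sample_id`, `site_id`,
#'   `n_above`, `n_below`, `r_above`, `r_below`, `p`, `q`, `direction`
#'   (`hyper`/`hypo`/`none`), `tested`.
#' @export
call_sample <- function(sample_beta, candidates, pairs, fdr = 0.01,
                        min_partners = 5, refine_iters = 1,
                        sample_id = "sample") {
  if (!is.data.frame(candidates))
    candidates <- data.frame(site_id = as.character(candidates))
  if (nrow(candidates) == 0)
    stop("candidate list is empty", call. = FALSE)
  idx <- partner_index(pairs)
  # sample values in the pair set's site order (NA where unmeasured)
  x <- sample_beta[match(pairs$site_ids, names(sample_beta))]
  cand_sites <- as.character(candidates$site_id)
  ci <- match(cand_sites, pairs$site_ids)

  one_pass <- function(excluded_idx) {
    rows <- vector("list", length(cand_sites))
    for (j in seq_along(cand_sites)) {
      i <- ci[j]
      if (is.na(i)) {
        rows[[j]] <- list(site = cand_sites[j], n_above = 0L, n_below = 0L,
                          r_above = 0L, r_below = 0L, tested = FALSE)
        next
      }
      ab <- idx$above[[i]]; be <- idx$below[[i]]
      if (length(excluded_idx)) {
        ab <- setdiff(ab, excluded_idx)
        be <- setdiff(be, excluded_idx)
      }
      cnt <- count_reversals_idx(NULL, x[i], x[ab], x[be], cand_sites[j])
      if (cnt$tested && cnt$n_above + cnt$n_below < min_partners)
        cnt$tested <- FALSE
      rows[[j]] <- cnt
    }
    df <- data.frame(
      sample_id = sample_id, site_id = cand_sites,
      n_above = vapply(rows, `[[`, integer(1), "n_above"),
      n_below = vapply(rows, `[[`, integer(1), "n_below"),
      r_above = vapply(rows, function(r) as.integer(r$r_above), integer(1)),
      r_below = vapply(rows, function(r) as.integer(r$r_below), integer(1)),
      tested = vapply(rows, `[[`, logical(1), "tested"))
    ft <- lapply(rows, fisher_dm)
    df$p <- vapply(ft, `[[`, numeric(1), "p")
    df$p[!df$tested] <- NA_real_
    df$q <- NA_real_
    df$q[df$tested] <- stats::p.adjust(df$p[df$tested], method = "BH")
    hint <- vapply(ft, `[[`, character(1), "direction_hint")
    df$direction <- ifelse(df$tested & !is.na(df$q) & df$q < fdr, hint, "none")
    df$direction[df$direction == "none"] <- "none"
    df
  }

  df <- one_pass(integer())
  iter <- 0
  while (iter < refine_iters) {
    dm_idx <- ci[df$direction != "none"]
    dm_idx <- dm_idx[!is.na(dm_idx)]
    new_df <- one_pass(dm_idx)
    iter <- iter + 1
    if (identical(new_df$direction, df$direction)) { df <- new_df; break }
    df <- new_df
  }
  if (!any(df$tested))
    warning("no testable candidates in sample ", sample_id)
  df[, c("sample_id", "site_id", "n_above", "n_below", "r_above", "r_below",
         "p", "q", "direction", "tested")]
}

#' Call DM CpG sites for every sample of a cancer cohort
#'
#' Runs [call_sample()] independently on each tumor column; sample
#' columns are never pooled. A failure or warning in one sample never
#' aborts the cohort.
#'
#' @param tumors A [beta_matrix()] of cancer samples.
#' @inheritParams call_sample
#' @return A `DM call table` data.frame: the per-sample tables bound
#'   together, with attribute `per_sample_counts` (named vector of DM
#'   calls per sample).
#' @export
call_cohort <- function(tumors, candidates, pairs, fdr = 0.01,
                        min_partners = 5, refine_iters = 1) {
  if (ncol(tumors) == 0) {
    warning("empty tumor matrix; no calls")
    out <- data.frame(sample_id = character(), site_id = character(),
                      n_above = integer(), n_below = integer(),
                      r_above = integer(), r_below = integer(),
                      p = numeric(), q = numeric(), direction = character(),
                      tested = logical())
    attr(out, "per_sample_counts") <- integer()
    return(out)
  }
  X <- unclass(tumors)
  res <- lapply(colnames(X), function(sid) {
    tryCatch(call_sample(stats::setNames(X[, sid], rownames(X)), candidates,
                         pairs, fdr = fdr, min_partners = min_partners,
                         refine_iters = refine_iters, sample_id = sid),
             error = function(e) {
               warning("sample ", sid, " failed: ", conditionMessage(e))
               NULL
             })
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  cnt <- tapply(out$direction != "none", out$sample_id, sum)
  attr(out, "per_sample_counts") <- cnt[colnames(X)[colnames(X) %in% names(cnt)]]
  out
}

#' Precision of individual calls against paired adjacent normals
#'
#' The gold standard for a called (sample, site) is the observed
#' direction of the beta difference between the tumor and its paired
#' adjacent normal: hyper when `tumor - adjacent > delta_min`, hypo when
#' `< -delta_min`. A call matching the gold direction is a true
#' positive; any other call — including calls whose paired difference is
#' zero or below `delta_min` in magnitude — is a false positive.
#' Precision per sample is the positive predictive value TP/(TP+FP).
#'
#' @param calls DM call table from [call_cohort()].
#' @param tumors,adjacents [beta_matrix()] objects.
#' @param pairing data.frame with columns `tumor_id`, `adjacent_id`.
#' @param delta_min Minimum absolute paired beta difference for a gold
#'   direction (default 0: any nonzero difference sets the gold).
#' @return List: `per_sample` (data.frame `sample_id`, `n_calls`, `tp`,
#'   `precision`), `mean_precision` (mean of per-sample precisions over
#'   samples with at least one call).
#' @export
evaluate_precision <- function(calls, tumors, adjacents, pairing,
                               delta_min = 0) {
  called <- calls[calls$direction != "none", , drop = FALSE]
  samples <- unique(called$sample_id)
  unpaired <- setdiff(samples, pairing$tumor_id)
  if (length(unpaired))
    warning("skipping sample(s) without paired adjacent normal: ",
            paste(unpaired, collapse = ", "))
  samples <- intersect(pairing$tumor_id, samples)
  per <- lapply(samples, function(sid) {
    adj <- pairing$adjacent_id[match(sid, pairing$tumor_id)]
    rows <- called[called$sample_id == sid, ]
    d <- unclass(tumors)[rows$site_id, sid] -
      unclass(adjacents)[rows$site_id, adj]
    gold <- ifelse(is.na(d), "none",
                   ifelse(d > delta_min, "hyper",
                          ifelse(d < -delta_min, "hypo", "none")))
    tp <- sum(rows$direction == gold)
    data.frame(sample_id = sid, n_calls = nrow(rows), tp = tp,
               precision = tp / nrow(rows))
  })
  per <- if (length(per)) do.call(rbind, per) else
    data.frame(sample_id = character(), n_calls = integer(), tp = integer(),
               precision = numeric())
  list(per_sample = per,
       mean_precision = if (nrow(per)) mean(per$precision) else NA_real_)
}
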