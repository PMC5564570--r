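#' Mine highly stable relative methylation orderings from normal samples
#'
#' An ordered CpG pair (a, b), meaning beta(a) < beta(b) within a
#' sample, is *stable* when that ordering holds in at least
#' `ceiling(f * N)` of the N pooled normal samples. Ties
#' (`beta(a) == beta(b)`) and samples missing either value support
#' neither direction but still count in N, so the rule is conservative:
#' a pair qualifies only on strict-inequality evidence from almost all
#' samples.
#'
#' Counting is blockwise over site blocks, so the full n^2 pair grid is
#' never materialised at once; memory is bounded by `block_size^2`.
#'
#' @param normals A [beta_matrix()] of pooled normal samples (>= 2
#'   samples).
#' @param f Stability threshold fraction, in (0.5, 1\]; the default 0.99
#'   reads as "identical ordering in at least 99% of normal samples".
#' @param block_size Sites per counting block.
#' @return A `stable_pair_set`: list with `pairs` (two-column integer
#'   matrix of site indices, each row (a, b) meaning beta(a) < beta(b)),
#'   `site_ids`, `f`, `n_samples_used`, `threshold` (the integer count
#'   required).
#' @export
find_stable_pairs <- function(normals, f = 0.99, block_size = 512L) {
  if (ncol(normals) < 2)
    stop("need at least 2 normal samples", call. = FALSE)
  if (f <= 0.5 || f > 1)
    stop("`f` must be in (0.5, 1]: below 0.5 both directions could qualify",
         call. = FALSE)
  X <- unclass(normals)
  n <- nrow(X)
  N <- ncol(X)
  thr <- as.integer(ceiling(f * N))
  starts <- seq(1L, n, by = block_size)
  out_a <- list(); out_b <- list(); k <- 0L
  for (i0 in starts) {
    I <- i0:min(i0 + block_size - 1L, n)
    XI <- X[I, , drop = FALSE]
    for (j0 in starts) {
      J <- j0:min(j0 + block_size - 1L, n)
      XJ <- X[J, , drop = FALSE]
      acc <- matrix(0L, length(I), length(J))
      for (s in seq_len(N)) {
        cmp <- outer(XI[, s], XJ[, s], "<")
        cmp[is.na(cmp)] <- FALSE
        acc <- acc + cmp
      }
      hit <- which(acc >= thr, arr.ind = TRUE)
      if (nrow(hit)) {
        a <- I[hit[, 1]]; b <- J[hit[, 2]]
        keep <- a != b
        if (any(keep)) {
          k <- k + 1L
          out_a[[k]] <- a[keep]; out_b[[k]] <- b[keep]
        }
      }
    }
  }
  pairs <- cbind(a = unlist(out_a, use.names = FALSE),
                 b = unlist(out_b, use.names = FALSE))
  if (is.null(pairs)) pairs <- cbind(a = integer(), b = integer())
  ord <- order(pairs[, 1], pairs[, 2])
  pairs <- pairs[ord, , drop = FALSE]
  structure(list(pairs = pairs, site_ids = rownames(X), f = f,
                 n_samples_used = N, threshold = thr),
            class = "stable_pair_set")
}

#' @export
print.stable_pair_set <- function(x, ...) {
  cat(sprintf(
    "stable_pair_set: %d ordered pairs over %d sites (f=%.3g, N=%d, threshold=%d)\n",
    nrow(x$pairs), length(x$site_ids), x$f, x$n_samples_used, x$threshold))
  invisible(x)
}

#' Stable partners of a site
#'
#' `partners_above(c)` are the sites stably above c in normals (pairs
#' (c, b)); `partners_below(c)` the sites stably below (pairs (a, c)).
#'
#' @param sps A `stable_pair_set`.
#' @param site A site id present in `sps$site_ids`.
#' @return Character vector of partner site ids.
#' @export
partners_above <- function(sps, site) {
  i <- match(site, sps$site_ids)
  if (is.na(i)) return(character())
  sps$site_ids[sps$pairs[sps$pairs[, 1] == i, 2]]
}

#' @rdname partners_above
#' @export
partners_below <- function(sps, site) {
  i <- match(site, sps$site_ids)
  if (is.na(i)) return(character())
  sps$site_ids[sps$pairs[sps$pairs[, 2] == i, 1]]
}

# fast per-site partner index: list of integer vectors keyed by site index
partner_index <- function(sps) {
  n <- length(sps$site_ids)
  above <- split(sps$pairs[, 2], factor(sps$pairs[, 1], levels = seq_len(n)))
  below <- split(sps$pairs[, 1], factor(sps$pairs[, 2], levels = seq_len(n)))
  list(above = above, below = below)
}

# unordered-pair keys and directions for set comparison; direction is
# +1 if the lexicographically smaller site id is the lower one
pair_keys <- function(sps) {
  ida <- sps$site_ids[sps$pairs[, 1]]
  idb <- sps$site_ids[sps$pairs[, 2]]
  lo <- pmin(ida, idb)
  hi <- pmax(ida, idb)
  list(key = paste(lo, hi, sep = "\r"), dir = ifelse(ida == lo, 1L, -1L))
}

#' Cross-list concordance of stable pair sets
#'
#' Two stable pair lists (e.g. mined from two platforms or cohorts)
#' share a pair when the unordered site pair is stable in both, in
#' either direction; `s` of the `k` shared pairs agree in direction.
#' The chance probability of observing at least `s` agreements is the
#' upper-tail cumulative binomial
#' `P = 1 - sum_{i=0}^{s-1} C(k,i) Pe^i (1-Pe)^(k-i)`, computed via the
#' binomial survival function so it is numerically safe for very large
#' k.
#'
#' @param listA,listB `stable_pair_set` objects over a shared site
#'   universe.
#' @param Pe Chance agreement probability per shared pair (default 0.5).
#' @return List of class `concordance_result`: `k`, `s`, `concordance`
#'   (= s/k), `Pe`, `p_value`, `overlap_fraction` (k over the smaller
#'   list size).
#' @export
concordance <- function(listA, listB, Pe = 0.5) {
  if (nrow(listA$pairs) == 0 || nrow(listB$pairs) == 0)
    stop("both stable pair sets must be nonempty", call. = FALSE)
  ka <- pair_keys(listA)
  kb <- pair_keys(listB)
  m <- match(ka$key, kb$key)
  sharedA <- which(!is.na(m))
  k <- length(sharedA)
  if (k == 0) stop("no shared pairs between the two lists", call. = FALSE)
  s <- sum(ka$dir[sharedA] == kb$dir[m[sharedA]])
  p <- stats::pbinom(s - 1, k, Pe, lower.tail = FALSE)
  structure(list(k = k, s = s, concordance = s / k, Pe = Pe, p_value = p,
                 overlap_fraction = k / min(nrow(listA$pairs),
                                            nrow(listB$pairs))),
            class = "concordance_result")
}

#' @export
print.concordance_result <- function(x, ...) {
  cat(sprintf(
    "concordance: %d/%d shared pairs same direction (%.4f); overlap %.4f; binomial p = %.3g\n",
    x$s, x$k, x$concordance, x$overlap_fraction, x$p_value))
  invisible(x)
}

#' @rdname write_stable_pairs
#' @param site_ids Optional full site universe; defaults to the sites
#'   appearing in at least one pair.
#' @export
read_stable_pairs <- function(path, site_ids = NULL) {
  df <- utils::read.delim(path, colClasses = "character")
  meta <- utils::read.delim(paste0(path, ".meta.tsv"))
  if (is.null(site_ids))
    site_ids <- sort(unique(c(df$site_a, df$site_b)))
  pairs <- cbind(a = match(df$site_a, site_ids),
                 b = match(df$site_b, site_ids))
  if (anyNA(pairs))
    stop("pair file contains sites outside `site_ids`", call. = FALSE)
  structure(list(pairs = pairs, site_ids = site_ids, f = meta$f,
                 n_samples_used = meta$n_samples_used,
                 threshold = meta$threshold),
            class = "stable_pair_set")
}

#' Write / read a stable pair set as TSV
#'
#' The pair TSV has columns `site_a`, `site_b`, each row meaning
#' beta(site_a) < beta(site_b) in normal tissue; a sidecar
#' `<path>.meta.tsv` records the threshold fraction, required count and
#' sample size.
#'
#' @param sps A `stable_pair_set`.
#' @param path Output TSV path.
#' @export
write_stable_pairs <- function(sps, path) {
  df <- data.frame(site_a = sps$site_ids[sps$pairs[, 1]],
                   site_b = sps$site_ids[sps$pairs[, 2]])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- data.frame(f = sps$f, threshold = sps$threshold,
                     n_samples_used = sps$n_samples_used,
                     n_sites = length(sps$site_ids))
  utils::write.table(meta, paste0(path, ".meta.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
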