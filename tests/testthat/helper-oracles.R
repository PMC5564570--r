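# Independent oracle implementations used to pin down expected values.
# These deliberately use brute-force loops and direct formulas, never
# the package's own code paths.

# exhaustive double-loop stable-pair miner: ordered pairs (a,b) with
# strict beta(a) < beta(b) in at least ceiling(f*N) of N samples; ties
# and NAs support neither direction but count in N
oracle_stable_pairs <- function(X, f) {
  N <- ncol(X)
  thr <- ceiling(f * N)
  out <- NULL
  for (i in seq_len(nrow(X))) for (j in seq_len(nrow(X))) {
    if (i == j) next
    cnt <- sum(X[i, ] < X[j, ], na.rm = TRUE)
    if (cnt >= thr) out <- rbind(out, c(i, j))
  }
  if (is.null(out)) out <- matrix(integer(), ncol = 2)
  out[order(out[, 1], out[, 2]), , drop = FALSE]
}

# direct term-by-term summation of the upper-tail cumulative binomial
# P = sum_{i=s}^{k} C(k,i) Pe^i (1-Pe)^(k-i)
oracle_binom_tail <- function(k, s, Pe) {
  if (s <= 0) return(1)
  i <- s:k
  sum(exp(lchoose(k, i) + i * log(Pe) + (k - i) * log(1 - Pe)))
}

# exhaustive fixed-margin enumeration of the two-sided Fisher p for the
# 2x2 table [[ra, na-ra], [rb, nb-rb]]: sum of the hypergeometric
# probabilities of all tables with the observed margins whose
# probability does not exceed the observed table's (standard
# probability-mass convention, relative tolerance 1 + 1e-7)
oracle_fisher_p <- function(ra, na, rb, nb) {
  c1 <- ra + rb                       # first-column total
  xs <- max(0, c1 - nb):min(na, c1)   # feasible r_above cells
  logp <- lchoose(na, xs) + lchoose(nb, c1 - xs) - lchoose(na + nb, c1)
  pr <- exp(logp)
  p_obs <- pr[match(ra, xs)]
  sum(pr[pr <= p_obs * (1 + 1e-7)])
}

# direct combinatorial upper-tail hypergeometric: P(overlap >= k)
oracle_hyper_p <- function(k, K, n, N) {
  js <- k:min(K, n)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# textbook Welch two-sample t statistic and p-value
oracle_welch <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  vx <- var(x) / length(x); vy <- var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  list(t = t, p = 2 * pt(-abs(t), df))
}

# small labelled beta matrix from a plain matrix
bm <- function(values, sites = NULL, samples = NULL, group = NULL) {
  if (is.null(sites)) sites <- sprintf("cg%03d", seq_len(nrow(values)))
  if (is.null(samples)) samples <- sprintf("S%02d", seq_len(ncol(values)))
  dimnames(values) <- list(sites, samples)
  beta_matrix(values, group = group)
}

# ordered pair set as a sorted "a<b" key vector, for set comparison
pair_set_keys <- function(sps) {
  if (nrow(sps$pairs) == 0) return(character())
  sort(paste(sps$site_ids[sps$pairs[, 1]], sps$site_ids[sps$pairs[, 2]],
             sep = "<"))
}

oracle_pair_keys <- function(pairs_idx, ids) {
  if (nrow(pairs_idx) == 0) return(character())
  sort(paste(ids[pairs_idx[, 1]], ids[pairs_idx[, 2]], sep = "<"))
}

# build two synthetic stable-pair sets sharing exactly k unordered pairs
# of which s agree in direction, to exercise the concordance p-value
make_pair_sets <- function(k, s, hub = k + 1L) {
  ids <- sprintf("s%03d", seq_len(k + 1))
  a <- seq_len(k); b <- rep(hub, k)
  A <- structure(list(pairs = cbind(a = a, b = b), site_ids = ids,
                      f = 0.99, n_samples_used = 10, threshold = 10L),
                 class = "stable_pair_set")
  agree <- c(rep(TRUE, s), rep(FALSE, k - s))
  B <- structure(list(pairs = cbind(a = ifelse(agree, a, b),
                                    b = ifelse(agree, b, a)),
                      site_ids = ids, f = 0.99, n_samples_used = 10,
                      threshold = 10L),
                 class = "stable_pair_set")
  list(A = A, B = B)
}
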