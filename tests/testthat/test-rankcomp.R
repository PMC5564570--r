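# hand-built background: site "c" with 10 partners stably above and 10
# stably below (by construction of the normal matrix)
toy_background <- function() {
  ids <- c("c", sprintf("up%02d", 1:10), sprintf("dn%02d", 1:10))
  base <- c(c = 0.5, setNames(seq(0.62, 0.80, length.out = 10),
                              sprintf("up%02d", 1:10)),
            setNames(seq(0.20, 0.38, length.out = 10),
                     sprintf("dn%02d", 1:10)))
  X <- matrix(rep(base, 12), ncol = 12,
              dimnames = list(ids, sprintf("N%02d", 1:12)))
  list(ids = ids, base = base,
       sps = find_stable_pairs(beta_matrix(X, group = "normal"), f = 0.99))
}

test_that("reversal counting matches the stable background on hand-built samples", {
  bg <- toy_background()
  expect_length(partners_above(bg$sps, "c"), 10)
  expect_length(partners_below(bg$sps, "c"), 10)
  # sample identical to a typical normal: no reversals
  cnt <- count_reversals(bg$base, "c", bg$sps)
  expect_identical(cnt[c("n_above", "n_below", "r_above", "r_below")],
                   list(n_above = 10L, n_below = 10L, r_above = 0L,
                        r_below = 0L))
  # raise c above 9 of its 10 stably-above partners
  s <- bg$base
  s["c"] <- 0.79
  cnt <- count_reversals(s, "c", bg$sps)
  expect_identical(cnt$r_above, 9L)
  expect_identical(cnt$n_above, 10L)
  expect_identical(cnt$r_below, 0L)
  # a missing partner drops from numerator and denominator
  s["up10"] <- NA
  cnt <- count_reversals(s, "c", bg$sps)
  expect_identical(cnt$n_above, 9L)
  expect_identical(cnt$r_above, 9L)
  # ties are non-reversals
  s2 <- bg$base
  s2["c"] <- s2[["up01"]]
  cnt <- count_reversals(s2, "c", bg$sps)
  expect_identical(cnt$r_above, 0L)
  # unknown site is untested
  expect_false(count_reversals(bg$base, "zz", bg$sps)$tested)
})

test_that("reversal counts equal an exhaustive per-pair loop on random samples", {
  set.seed(31)
  for (rep in 1:5) {
    X <- matrix(runif(12 * 15), 12,
                dimnames = list(sprintf("s%02d", 1:12), sprintf("N%02d", 1:15)))
    sps <- find_stable_pairs(beta_matrix(X), f = 0.8)
    smp <- setNames(runif(12), rownames(X))
    smp[sample(12, 2)] <- NA
    for (site in rownames(X)) {
      cnt <- count_reversals(smp, site, sps)
      # loop oracle straight over the pair list
      ra <- rb <- na_ <- nb_ <- 0L
      for (r in seq_len(nrow(sps$pairs))) {
        a <- sps$site_ids[sps$pairs[r, 1]]; b <- sps$site_ids[sps$pairs[r, 2]]
        if (a == site && !is.na(smp[site]) && !is.na(smp[b])) {
          na_ <- na_ + 1L
          if (smp[b] < smp[site]) ra <- ra + 1L
        }
        if (b == site && !is.na(smp[site]) && !is.na(smp[a])) {
          nb_ <- nb_ + 1L
          if (smp[a] > smp[site]) rb <- rb + 1L
        }
      }
      if (!cnt$tested) next
      expect_identical(c(cnt$n_above, cnt$r_above, cnt$n_below, cnt$r_below),
                       c(na_, ra, nb_, rb))
    }
  }
})

test_that("the reversal Fisher test reproduces its worked example and degenerate cases", {
  f <- function(ra, na, rb, nb)
    fisher_dm(list(n_above = na, n_below = nb, r_above = ra, r_below = rb,
                   tested = TRUE))
  w <- f(9, 10, 0, 10)
  expect_equal(w$p, 20 / 167960, tolerance = 1e-12)
  expect_identical(w$direction_hint, "hyper")
  z <- f(0, 10, 0, 10)
  expect_identical(z$p, 1)
  expect_identical(z$direction_hint, "none")
  # one empty margin: test degenerate but defined
  expect_identical(f(0, 0, 3, 10)$direction_hint, "hypo")
  expect_true(f(0, 0, 3, 10)$p <= 1)
  # no partners at all: untested
  expect_false(fisher_dm(list(n_above = 0, n_below = 0, r_above = 0,
                              r_below = 0, tested = TRUE))$tested)
})

test_that("the reversal Fisher p equals exhaustive fixed-margin enumeration on a grid", {
  for (na in c(3, 6, 9)) for (nb in c(4, 8)) {
    for (ra in 0:na) for (rb in c(0, nb %/% 2, nb)) {
      got <- fisher_dm(list(n_above = na, n_below = nb,
                            r_above = ra, r_below = rb, tested = TRUE))$p
      expect_equal(got, oracle_fisher_p(ra, na, rb, nb), tolerance = 1e-12)
    }
  }
})

test_that("swapping the above/below margins preserves p and flips the direction hint", {
  set.seed(5)
  for (rep in 1:20) {
    na <- sample(1:12, 1); nb <- sample(1:12, 1)
    ra <- sample(0:na, 1); rb <- sample(0:nb, 1)
    a <- fisher_dm(list(n_above = na, n_below = nb, r_above = ra,
                        r_below = rb, tested = TRUE))
    b <- fisher_dm(list(n_above = nb, n_below = na, r_above = rb,
                        r_below = ra, tested = TRUE))
    expect_equal(a$p, b$p, tolerance = 1e-12)
    expect_identical(a$direction_hint,
                     c(hyper = "hypo", hypo = "hyper", none = "none")[[b$direction_hint]])
  }
})

test_that("with no hypo-side reversals the p-value never rises as hyper-side reversals grow", {
  ps <- sapply(0:10, function(ra)
    fisher_dm(list(n_above = 10, n_below = 10, r_above = ra, r_below = 0,
                   tested = TRUE))$p)
  expect_true(all(diff(ps) <= 1e-12))
})

test_that("single-sample calling flags planted disruption and respects min_partners", {
  bg <- toy_background()
  cand <- data.frame(site_id = c("c", "up05", "absent"))
  s <- bg$base
  s["c"] <- 0.95  # above all 10 stably-above partners
  calls <- suppressWarnings(
    call_sample(s, cand, bg$sps, fdr = 0.05, min_partners = 5,
                sample_id = "T1"))
  row_c <- calls[calls$site_id == "c", ]
  expect_identical(row_c$direction, "hyper")
  expect_identical(row_c$r_above, 10L)
  expect_false(calls$tested[calls$site_id == "absent"])
  # a normal-like sample yields no calls, and refinement is a fixed point
  c0 <- call_sample(bg$base, cand[1:2, , drop = FALSE], bg$sps,
                    refine_iters = 0, sample_id = "T2")
  c1 <- call_sample(bg$base, cand[1:2, , drop = FALSE], bg$sps,
                    refine_iters = 1, sample_id = "T2")
  expect_identical(c0, c1)
  expect_true(all(c0$direction == "none"))
  expect_error(call_sample(s, cand[0, ], bg$sps), "empty")
})

test_that("refinement excludes first-pass DM partners from the background counts", {
  bg <- toy_background()
  # make one stably-above partner itself wildly hypermethylated
  s <- bg$base
  s["c"] <- 0.95
  s["up01"] <- 0.99
  cand <- data.frame(site_id = c("c", "up01"))
  one <- call_sample(s, cand, bg$sps, fdr = 0.05, refine_iters = 0,
                     sample_id = "T1")
  two <- call_sample(s, cand, bg$sps, fdr = 0.05, refine_iters = 1,
                     sample_id = "T1")
  # up01 is called DM in pass one, so c loses it as a partner in pass two
  expect_identical(one$n_above[one$site_id == "c"], 10L)
  expect_identical(two$n_above[two$site_id == "c"], 9L)
})

test_that("cohort calling is per-sample independent and deterministic", {
  bg <- toy_background()
  cand <- data.frame(site_id = c("c", "up05"))
  v <- cbind(bg$base, bg$base, bg$base)
  v[1, 2:3] <- 0.95
  tum <- bm(v, sites = bg$ids, samples = c("Ta", "Tb", "Tc"), group = "tumor")
  calls <- call_cohort(tum, cand, bg$sps, fdr = 0.05)
  strip <- function(d) { rownames(d) <- NULL; d }
  # identical columns produce identical call sets
  expect_identical(strip(calls[calls$sample_id == "Tb", -1]),
                   strip(calls[calls$sample_id == "Tc", -1]))
  # permuting columns permutes output rows only
  perm <- bm_perm <- bm(v[, c(3, 1, 2)], sites = bg$ids,
                        samples = c("Tc", "Ta", "Tb"), group = "tumor")
  calls_p <- call_cohort(perm, cand, bg$sps, fdr = 0.05)
  reord <- strip(calls_p[order(match(calls_p$sample_id, c("Ta", "Tb", "Tc")),
                               calls_p$site_id), ])
  base <- strip(calls[order(match(calls$sample_id, c("Ta", "Tb", "Tc")),
                            calls$site_id), ])
  attr(reord, "per_sample_counts") <- attr(base, "per_sample_counts") <- NULL
  expect_identical(reord, base)
  # empty cohort: empty table plus a warning
  expect_warning(out <- call_cohort(tum[, 0, drop = FALSE], cand, bg$sps),
                 "empty")
  expect_identical(nrow(out), 0L)
})

test_that("precision is the positive predictive value against the paired difference", {
  calls <- data.frame(
    sample_id = "T1", site_id = sprintf("s%02d", 1:10),
    n_above = 5L, n_below = 5L, r_above = 5L, r_below = 0L,
    p = 1e-5, q = 1e-4,
    direction = c(rep("hyper", 9), "hypo"), tested = TRUE)
  tum <- bm(matrix(0.8, 10, 1), sites = sprintf("s%02d", 1:10),
            samples = "T1")
  adjv <- matrix(0.2, 10, 1)
  adjv[10, 1] <- 0.1  # paired difference positive -> gold hyper, call hypo
  adj <- bm(adjv, sites = sprintf("s%02d", 1:10), samples = "A1")
  pairing <- data.frame(tumor_id = "T1", adjacent_id = "A1")
  out <- evaluate_precision(calls, tum, adj, pairing)
  expect_equal(out$per_sample$precision, 0.9)
  expect_equal(out$mean_precision, 0.9)
  # zero paired difference at delta_min = 0 counts as a false positive
  adjv2 <- matrix(0.8, 10, 1)
  adj2 <- bm(adjv2, sites = sprintf("s%02d", 1:10), samples = "A1")
  out2 <- evaluate_precision(calls, tum, adj2, pairing)
  expect_equal(out2$per_sample$precision, 0)
  # a called sample without a pairing is skipped with a warning
  expect_warning(
    out3 <- evaluate_precision(calls, tum, adj,
                               data.frame(tumor_id = "T9",
                                          adjacent_id = "A1")),
    "without paired")
  expect_identical(nrow(out3$per_sample), 0L)
})
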