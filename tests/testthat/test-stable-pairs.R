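test_that("unanimous orderings are stable and near-unanimous ones are not at f = 0.99", {
  # site A below B in all 10 samples; C crosses around
  set.seed(9)
  X <- rbind(A = runif(10, 0.1, 0.3), B = runif(10, 0.6, 0.8),
             C = runif(10, 0, 1))
  sps <- find_stable_pairs(bm(X, sites = rownames(X)), f = 0.99)
  expect_true("A<B" %in% pair_set_keys(sps))
  # A < B in only 9 of 10 samples: 9 < ceiling(0.99 * 10) = 10
  X2 <- X
  X2["A", 1] <- 0.9
  sps2 <- find_stable_pairs(bm(X2, sites = rownames(X2)), f = 0.99)
  expect_false("A<B" %in% pair_set_keys(sps2))
})

test_that("blockwise mining equals the exhaustive double-loop oracle, with ties, NAs and small blocks", {
  set.seed(21)
  for (rep in 1:8) {
    n <- sample(5:20, 1)
    m <- sample(4:30, 1)
    X <- matrix(runif(n * m), n)
    X[sample(length(X), round(0.05 * length(X)))] <- NA
    # inject ties
    X[1, ] <- X[2, ]
    f <- sample(c(0.7, 0.9, 0.99, 1), 1)
    sps <- find_stable_pairs(bm(X), f = f, block_size = 4L)
    expect_identical(pair_set_keys(sps),
                     oracle_pair_keys(oracle_stable_pairs(X, f),
                                      sprintf("cg%03d", 1:n)))
  }
})

test_that("pair sets are antisymmetric and shrink as f rises", {
  set.seed(13)
  X <- matrix(runif(15 * 12), 15)
  prev <- NULL
  for (f in c(0.6, 0.75, 0.9, 1)) {
    sps <- find_stable_pairs(bm(X), f = f)
    keys <- pair_set_keys(sps)
    rev_keys <- paste(sub(".*<", "", keys), sub("<.*", "", keys), sep = "<")
    expect_length(intersect(keys, rev_keys), 0)
    if (!is.null(prev)) expect_true(all(keys %in% prev))
    prev <- keys
  }
  expect_error(find_stable_pairs(bm(X), f = 0.5), "0.5")
})

test_that("partner indexes are the pair set re-keyed", {
  set.seed(2)
  X <- matrix(runif(10 * 20), 10)
  sps <- find_stable_pairs(bm(X), f = 0.9)
  ids <- sps$site_ids
  for (s in ids) {
    above <- partners_above(sps, s)
    below <- partners_below(sps, s)
    for (b in above)
      expect_true(any(ids[sps$pairs[, 1]] == s & ids[sps$pairs[, 2]] == b))
    for (a in below)
      expect_true(any(ids[sps$pairs[, 1]] == a & ids[sps$pairs[, 2]] == s))
  }
  expect_identical(partners_above(sps, "not_a_site"), character())
})

test_that("concordance counts shared unordered pairs and scores direction agreement", {
  mk <- function(keys, ids) {
    a <- match(sub("<.*", "", keys), ids)
    b <- match(sub(".*<", "", keys), ids)
    structure(list(pairs = cbind(a = a, b = b), site_ids = ids, f = 0.99,
                   n_samples_used = 10, threshold = 10),
              class = "stable_pair_set")
  }
  ids <- c("p", "q", "r", "s")
  A <- mk(c("p<q", "q<r", "r<s"), ids)
  B <- mk(c("p<q", "r<q", "p<s"), ids)   # q<r reversed in B
  res <- concordance(A, B)
  expect_identical(res$k, 2L)
  expect_identical(res$s, 1L)
  expect_equal(res$concordance, 0.5)
  expect_equal(res$overlap_fraction, 2 / 3)
})

test_that("the cumulative binomial concordance p matches its closed forms and direct summation", {
  mkres <- function(k, s, Pe) {
    sets <- make_pair_sets(k, s)
    concordance(sets$A, sets$B, Pe = Pe)
  }
  expect_equal(mkres(10, 10, 0.5)$p_value, 2^-10, tolerance = 1e-12)
  expect_equal(mkres(2, 2, 0.5)$p_value, 0.25, tolerance = 1e-12)
  expect_equal(mkres(5, 0, 0.5)$p_value, 1)
  expect_equal(mkres(1, 0, 0.5)$p_value, 1)
  for (k in c(3, 7, 12)) for (s in c(0, 1, k %/% 2, k)) for (Pe in c(0.3, 0.5))
    expect_equal(mkres(k, s, Pe)$p_value, oracle_binom_tail(k, s, Pe),
                 tolerance = 1e-12)
})

test_that("zero-noise platform subsets agree perfectly on shared sites", {
  sim <- simulate_cohort(sim_config(n_sites = 40, n_normals = 10,
                                    n_tumors = 2, n_paired = 0,
                                    noise_sd = 0, effect_size = 0, seed = 6))
  sp <- split_platforms(sim$normals, 0.6)
  shared <- intersect_probes(list(sp$platformA, sp$platformB))
  a <- find_stable_pairs(shared[[1]], f = 0.99)
  b <- find_stable_pairs(shared[[2]], f = 0.99)
  res <- concordance(a, b)
  expect_identical(res$concordance, 1)
  expect_identical(res$overlap_fraction, 1)
})

test_that("stable pair TSVs record the pairs and mining metadata", {
  set.seed(3)
  X <- matrix(runif(8 * 10), 8)
  sps <- find_stable_pairs(bm(X), f = 0.9)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_stable_pairs(sps, path)
  pairs <- read.delim(path)
  expect_identical(nrow(pairs), nrow(sps$pairs))
  meta <- read.delim(paste0(path, ".meta.tsv"))
  expect_identical(meta$threshold, sps$threshold)
  expect_identical(meta$n_samples_used, 10L)
  back <- read_stable_pairs(path, site_ids = sps$site_ids)
  expect_identical(back$pairs[, "a"], sps$pairs[, "a"])
  expect_identical(back$pairs[, "b"], sps$pairs[, "b"])
  expect_identical(back$threshold, sps$threshold)
  for (s in sps$site_ids)
    expect_setequal(partners_above(back, s), partners_above(sps, s))
})
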