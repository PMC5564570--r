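---
title: "Individualized differential methylation from disrupted relative orderings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Individualized differential methylation from disrupted relative orderings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(rmodm)
```

## The problem and the idea

Group-level tests (t-tests, rank-sum tests) can say that a CpG site is
differentially methylated (DM) between a set of tumors and a set of
normals, but they cannot say whether *this particular patient's* tumor
carries the aberration — and methylation aberrations in cancer are
heterogeneous enough that the distinction matters, both for estimating
how *frequent* an aberration is across patients and for using it in a
single-sample diagnostic setting. Comparing one tumor against the
*average* of a normal pool is unreliable because absolute beta values
vary substantially between healthy individuals.

What is far more reproducible than the absolute level is the
*within-sample relative ordering*: for many pairs of CpG sites (a, b),
essentially every normal colorectal sample agrees on whether
beta(a) < beta(b). `rmodm` exploits this. It mines the ordered pairs
whose relative methylation ordering (RMO) is identical in at least a
fraction *f* (default 99%, allowing a 1% detection error rate) of a
pooled normal cohort, and then, for a single cancer sample, asks at
each candidate site *c*: of the partners stably above *c*, how many
have dropped below it, and of the partners stably below, how many have
risen above? A partner stably above *c* observed below it supports
hypermethylation of *c*; a partner stably below observed above supports
hypomethylation. Under the null hypothesis that *c* is unchanged, the
two reversal proportions should be equal; Fisher's exact test on

```
            reversed   not reversed
above-set    r_above   n_above - r_above
below-set    r_below   n_below - r_below
```

tests that asymmetry (this is the RankComp scheme, applied to
methylation orderings). P-values are Benjamini–Hochberg adjusted
*within each sample*, because each call is a claim about that sample
alone, and the direction is taken from the larger reversal proportion
at `q < 0.01`.

## Workflow and parameters

The pipeline (`run_pipeline()`, or the numbered scripts under
`analysis/`) runs:

1. `simulate_cohort()` — synthetic cohort with ground truth (below).
2. `find_stable_pairs()` — stable RMO mining on pooled normals.
   *f* = 0.99 by default; the required sample count is `ceiling(f * N)`
   (so "at least 99%" with N = 40 means unanimity). Ties and missing
   values support neither direction but stay in the denominator — the
   conservative reading. Counting is blockwise so the full n² pair grid
   is never held in memory at once. `concordance()` quantifies
   agreement between two mined lists (e.g. two platforms): of *k*
   shared unordered pairs, *s* agree in direction, and the chance
   probability of at least *s* agreements is the upper-tail cumulative
   binomial with per-pair agreement probability *Pe* = 0.5.
3. `ttest_dm()` + `intersect_concordant()` — candidate screening:
   per-site Welch t-tests in two independent datasets (BH, FDR < 0.01),
   keeping sites significant in both with the same direction. The
   package uses Welch rather than pooled variance because tumor groups
   are typically more variable than normals; a pooled-variance option
   is exposed. Direction is the sign of the difference of group means
   on the beta scale. The two "independent datasets" here are
   interleaved halves of the simulated cohort; with real data, pass two
   actual cohorts.
4. `call_cohort()` — per-sample reversal tests as above.
   `min_partners = 5` avoids vacuous 2×2 tables; sites with fewer
   usable partners are reported as untested, never as negatives.
   `refine_iters = 1` re-runs each sample's pass once with first-pass
   DM partners removed from every site's counts, so that a strongly
   disrupted partner does not contaminate the background of its
   neighbours; on a null sample this is a fixed point.
5. `evaluate_precision()` — for tumors with a paired adjacent normal,
   the gold direction is the sign of `tumor − adjacent` beta difference
   (magnitude above `delta_min`, default 0); precision is TP/(TP+FP)
   per sample. Calls whose paired difference is exactly zero or below
   `delta_min` count as false positives — the strict reading.
6. `genes_from_sites()` + `classify_frequency()` — a gene is DM in a
   sample if ≥ 1 promoter CpG is called; promoters with both
   directions in one sample are *inconsistent* and excluded from that
   sample's counts (exclusion is per sample, and the inconsistent
   fraction is reported, since a gene may be cleanly called in other
   samples). Universality is strict (`> 0.95`, "more than 95%");
   heterogeneity is the closed interval `[0.20, 0.80]`; frequencies use
   all cohort samples as denominator.
7. `enrich_cohort()` — per sample and direction, hypergeometric
   over-representation of the DM gene set in each pathway, BH within
   the (sample, direction) family, FDR < 0.1; the cross-sample
   significance frequency of each pathway is reported. The default
   universe is the pathway-covered genes intersected with the measured
   genes, and is configurable because real collections differ in how
   much of the array they cover.

```{r example}
res <- run_pipeline(pipeline_config(), out_dir = "run1")
res$mean_precision
res$gene_classes
```

## What the synthetic generator emulates

`simulate_cohort()` reproduces the statistical structure the method
relies on, with complete ground truth:

- Per-site baselines are uniform on `baseline_range` (default
  0.1–0.9). A normal sample's value is
  `inv_logit(logit(mu) + eps)`, `eps ~ N(0, noise_sd²)` with
  `noise_sd = 0.3`: additive noise on the logit keeps betas in (0, 1)
  and mimics the bounded, heteroscedastic behaviour of array betas.
  Values are clipped to `[1e-6, 1 − 1e-6]`.
- Planted events shift the logit by ±`effect_size` (default 2.0)
  before noise. *Universal* sites (5% of sites) carry their event in at
  least `ceil(0.95 · n_tumors)` tumors; *subtype* sites (15%) in a
  uniformly drawn 20–80% subset. Direction is drawn once per gene
  block (`hyper_prob = 0.5`), so promoter CpGs move coherently.
- Planted sites draw their baselines from `dm_baseline_range`
  (default 0.3–0.7). This is deliberate: cancer differential
  methylation concentrates at CpGs with intermediate, dynamic normal
  methylation, and — just as importantly — a site at the extreme end of
  the measured spectrum has stable partners on only one side, so *no*
  ordering-based method can attribute a direction to its disruption.
  Planting events in the interior produces exactly the structure the
  method assumes about real DM sites.
- Sites map to genes in consecutive blocks of `sites_per_gene = 3`;
  genes to pathways in blocks of `genes_per_pathway = 10`
  (600 sites → 200 genes → 20 pathways by default). 40 normals,
  30 tumors, 20 with paired adjacent normals drawn from the same
  normal model, sharing no planted events.
- One root seed drives fixed per-component sub-streams, so runs are
  exactly reproducible, and enlarging one component (say, adding
  normal samples) leaves the others' draws unchanged — which is how the
  null-calibration tests draw fresh normal-model samples without
  touching the mined background.

The default cohort sizes (600 sites, 40/30/20 samples) keep a full run
in a few seconds while leaving every stage statistically non-trivial;
they are stated here because every empirical number in the README was
computed at exactly these sizes.

What the generator does **not** emulate: Infinium I/II probe-chemistry
bias, batch effects, cell-type composition, spatial correlation along
the genome, and the strongly bimodal marginal distribution of real
450K betas. Passing recovery tests therefore show that the
implementation is correct under the assumed structure, not that the
method's published performance transfers to any particular real
dataset.

## Numerical and design choices

- **Stability threshold.** `ceiling(f × N)` realises "at least f"; with
  ties and missing values counted only in the denominator the rule can
  only lose support, never gain it. `f ≤ 0.5` is rejected since both
  directions could then qualify.
- **Fisher two-sidedness.** The two-sided p is the probability-mass
  convention: the sum over all tables with the observed margins whose
  probability does not exceed the observed table's (with the standard
  1 + 1e-7 relative tolerance for floating-point ties). Degenerate
  tables with one empty margin are defined (p = 1 when only one table
  is feasible); a site with no usable partners at all is untested.
- **Concordance p at scale.** The upper-tail binomial is evaluated via
  the survival function, stable for k in the hundreds of millions of
  pairs that realistic site counts produce.
- **Emergent universality.** A gene whose promoter unites several
  subtype CpGs with independent carrier sets can be DM in more than
  95% of samples even though no single site is universal; the
  classification reports what the cohort shows, so such genes
  legitimately join the universal class alongside the planted ones.
- **BH families.** Population screening adjusts across all tested
  sites within one dataset; individual calling within one sample;
  enrichment within one (sample, direction). Each family matches the
  scope of the claim being made.
- **Determinism.** Pipeline outputs carry the full configuration and
  seed, and a rerun with the same configuration is byte-identical; no
  stage writes timestamps.

## Known limitations

- Sites at the extremes of the methylation spectrum have one-sided
  partner sets: disruption there is visible (reversals occur) but its
  direction cannot be tested with power, and such sites will mostly be
  reported untested or uncalled. This is a property of the ordering
  approach, not of this implementation.
- The candidate screen restricts individualized calls to
  population-level DM sites; aberrations private to rare subtypes are
  invisible by design.
- Precision against a paired adjacent normal assumes the adjacent
  tissue approximates the patient's pre-malignant state; field effects
  in real adjacent tissue violate this in a way the simulation does
  not model.
- The t-test screen assumes approximately normal within-group betas;
  with the logit-normal generator this holds, but heavily bimodal real
  data may warrant a rank-based screen instead.
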