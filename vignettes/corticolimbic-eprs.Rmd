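---
title: "Expression-based polygenic scores from anchor-gene co-expression networks"
author: "coexprs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Expression-based polygenic scores from anchor-gene co-expression networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coexprs)
```

## The method

A conventional polygenic score weights allele counts by genotype–disease
association estimates from a GWAS. An expression-based polygenic score
(ePRS) instead weights alleles by their estimated effect on *gene
expression* in a specific tissue, restricted to the genes that form a
functional unit: the co-expression network of an anchor gene. The score is
meant to capture individual variation in the expression capacity of a
biological process (here, corticolimbic development organized around the
axon-guidance receptor gene *DCC* in prefrontal cortex and nucleus
accumbens), rather than variation in disease risk per se.

Construction proceeds in four stages per brain region:

1. **Network construction.** Every gene is correlated (Pearson, by
   default) with the anchor gene across the region's expression samples.
   Genes with $|r| \ge 0.5$ survive, each carrying $\mathrm{sign}(r)$.
   A developmental enrichment filter then keeps genes whose mean
   expression in early postnatal samples is at least 1.5-fold their adult
   mean, selecting transcripts most active while the region is still
   maturing.
2. **Variant assembly.** cis-eQTL gene–SNP pairs for the network genes
   are collected from an eQTL catalog, harmonized against the cohort's
   allele coding (strand-ambiguous A/T and C/G pairs dropped by default),
   reduced to one record per variant, and LD-clumped greedily at
   $r^2 < 0.2$ within a 250 kb window using the cohort's own dosages.
3. **Scoring.** Each retained SNP's weight is its eQTL slope multiplied
   by its gene's network sign; an individual's regional score is
   $\sum_j d_{ij} w_j$ over effect-allele dosages $d_{ij}$, with missing
   dosages mean-imputed per SNP. The combined corticolimbic score is the
   plain sum of the two regional scores.
4. **Association.** The combined score is dichotomized by median split
   for baseline group comparisons (summary t-tests, 2×2 $\chi^2$), and
   tested against outcomes by OLS adjusting for sex and genotype
   principal components, with Bonferroni adjustment per outcome family
   and a noncentral power analysis via Cohen's $f^2$.

The multiplicative sign rule in stage 3 is the only orientation-consistent
reading of "accounting for the sign of the correlation": an allele that
raises the expression of a gene *negatively* co-expressed with the anchor
moves the network away from its anchor-aligned state and must lower the
score.

## Tunable parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `min_abs_r` | 0.5 | correlation | inclusive boundary; genes at exactly 0.5 are retained |
| `min_fold` | 1.5 | expression ratio | inclusive; early (0–18 mo) vs adult (20–40 y) means |
| `eps` | 0.01 | expression units | denominator floor for silent-in-adult genes |
| `r2_max` | 0.2 | squared correlation | SNPs with $r^2 \ge 0.2$ to an index SNP are removed |
| `window_kb` | 250 | kb | common clumping default; the source pipeline does not state one |
| `prs_p_threshold` | 4.912e-5 | p-value | GWAS-threshold comparator selection |
| `top_k` | 4515 | SNPs | alternative comparator selection, size-matched to the ePRS |

Clumping priority is ascending eQTL nominal p-value (ties: larger
$|\mathrm{slope}|$, then variant id) — the only per-SNP significance
available in this design; all tie-breaks are total orders, so the retained
set is deterministic. The post-condition (no two retained SNPs within a
window at $r^2 \ge$ `r2_max`) is checkable exhaustively with
`check_clump()`.

## Numerical and policy choices

- **Fold-change denominator.** The filter uses
  `mean_early / max(mean_adult, eps)`. A floor rather than an additive
  pseudocount keeps the canonical boundary case (3.0 vs 2.0 → exactly
  1.5, retained) intact while still handling adult-silent genes.
- **Anchor membership.** The anchor is included in its own network with
  sign +1 regardless of its fold-change (`include_anchor = FALSE` to
  exclude); published network gene counts do not state whether the anchor
  is counted, so both behaviors are one flag apart.
- **Median ties.** Scores equal to the median go to the low group —
  deterministic and documented; with tied score values the groups need
  not be equal-sized, which is also why a published 96/106 split of 202
  individuals is consistent with a median split.
- **Missing dosages** are imputed with the SNP's cohort mean, the
  standard PRS convention: it preserves the score's expectation and keeps
  allele-flip invariance exact.
- **Variants shared by both regional networks** contribute to both
  regional scores, hence twice to the sum, because the regions are
  constructed independently and then summed; no per-region
  standardization or SNP-count scaling is applied (the combined score is
  a plain sum).
- **Welch vs Student.** `t_test_from_summary(variant = "auto")` applies
  an F-ratio pretest at $\alpha = 0.05$ and switches to Welch on
  rejection, a concrete version of "Welch in case of unequal variances".
- **Power conventions.** Two are implemented and deliberately *not*
  reconciled: the one-sided noncentral-t convention
  ($\lambda = f^2 n$, $df = n-2$), which yields 0.64 / 0.88 / >0.95 at
  $n$ = 202 / 398 / 4392 for $f^2 = 0.02$, and the two-sided
  noncentral-F convention, which yields ≈0.52 at $n = 202$. The t
  convention is the default because it reproduces the published values;
  the discrepancy with a nominally two-tailed analysis is a property of
  those values, not of this implementation.

## What the synthetic data emulate

The simulators generate every input the pipeline consumes, with the
generating parameters retained on the objects so downstream stages can be
tested against known ground truth.

- **Expression** is a single-factor Gaussian copula on the log scale: the
  anchor's latent factor, scaled per gene to a target correlation, plus a
  per-stage mean shift of $\log(\text{fold-change})$, then exponentiated.
  Exponentiation keeps expression positive and makes the ratio of
  arithmetic stage means equal the planted fold-change exactly in
  expectation. Because the stage indicator acts as a shared covariate,
  genes with non-unit fold-changes acquire extra stage-driven covariance:
  planted correlations are exact when fold-changes are 1 and dominated by
  the shared developmental signal when they are not. Planting tests
  therefore place passing genes far from both filter boundaries
  (correlation 0.8, fold 2) and failing genes far on the other side
  (correlation ≈0, fold 1), so sampling noise cannot flip membership.
- **Genotypes** come in equicorrelated LD blocks: each block draws one
  MAF, and each SNP copies a latent block haplotype per haplotype with
  probability $\sqrt{r}$, falling back to a fresh Bernoulli(MAF) draw.
  This gives *exact* pairwise dosage correlation $r$ within a block with
  exact Bernoulli margins — a property thresholded-Gaussian constructions
  do not have (their phi coefficients are attenuated below the latent
  correlation) — and $r = 1$ yields literally identical columns.
  Missingness is completely at random, matching the mean-imputation
  contract.
- **eQTL catalogs** place SNPs uniformly in each gene's cis window and
  draw slopes from a configurable normal distribution; **GWAS summaries**
  mix null SNPs (uniform p-values by construction) with effects drawn
  from $N(0, \sigma^2_{\text{effect}})$; **phenotypes** follow the linear
  model $y = \beta_s\,\text{score} + \beta_{sex}\,\text{sex} +
  \Sigma\beta_k PC_k + \varepsilon$.
- Seeds: one global integer seed per study; `derive_seed()` hashes it
  with a stage label so every stage has an independent, reproducible
  substream and inserting a stage never perturbs the others.

What the simulators do **not** emulate: coalescent haplotype structure
(LD decays block-wise, not with distance), imputation dosage uncertainty,
X-chromosome inheritance (autosomal transcripts only), cross-tissue
correlation of eQTL slopes (regions are simulated independently), and
confounded population structure (PCs are independent noise). Passing
tests therefore demonstrate the pipeline's *arithmetic and logic* on data
whose truth is known — not that the score predicts behavior in real
cohorts, which requires access-restricted genotype and phenotype data.

## Problem sizes used in the tests

Statistical convergence tests run at the sample size where the tolerance
is a few standard errors (e.g. correlation recovery at 10,000 expression
samples against a ±0.02 band derived from the Fisher-z interval; LD
independence at 50,000 individuals against the 1/n sampling bound). The
end-to-end demonstration uses a cohort of 5,000 individuals with planted
networks of 154 and 72 genes and ~5,000 candidate cis-SNPs, a planted
combined-score coefficient of −0.04 against unit residual noise, and
checks that the fitted coefficient lands within 3 standard errors of
truth with the low-score group showing the higher outcome mean. Power
cross-checks use 10,000 Monte-Carlo regressions per sample size; the
type-I error check uses 1,000 null replicates against a 99.9% binomial
band.

## Known limitations

- Cohort LD is the only LD used for clumping; no reference panel
  support.
- Multi-allelic variants and indels are out of scope; alleles are single
  bases and strand-ambiguous pairs are dropped rather than
  frequency-resolved.
- The mouse-to-human step of the original design is reduced to a
  user-supplied identity/symbol mapping; no homology resolution is
  performed.
- `coexpression_stability()` reports childhood-cluster preservation as
  mean within-cluster adulthood correlation; it is a descriptive
  statistic, not a permutation-calibrated preservation test.
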