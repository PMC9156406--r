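# coexprs

Expression-based polygenic scores (ePRS) from anchor-gene co-expression
networks, with a conventional GWAS-threshold PRS comparator and the full
association battery around them.

## The problem

Most polygenic scores weight alleles by genotype–disease associations.
For developmental phenotypes such as childhood impulsivity, a complementary
idea is to score the *expression capacity of a biological process*: take an
anchor gene central to the process (here the axon-guidance receptor gene
*DCC*, which organizes corticolimbic dopamine development), find the genes
co-expressed with it in the relevant tissues (prefrontal cortex and nucleus
accumbens), keep the genes most active during early postnatal development,
and weight each network SNP by its tissue-specific eQTL effect on
expression. `coexprs` implements that pipeline end to end, plus synthetic
generators for every input so the whole machine is testable without any
restricted cohort data.

For a region with post-clump SNP set $J$, individual $i$'s regional score is

$$\mathrm{ePRS}_i \;=\; \sum_{j \in J} d_{ij}\, \beta_j \,\mathrm{sign}(r_{g(j)}),$$

where $d_{ij}$ is the effect-allele dosage (missing values mean-imputed per
SNP), $\beta_j$ the eQTL slope of SNP $j$ on its gene $g(j)$, and
$r_{g(j)}$ the gene's co-expression correlation with the anchor. Network
membership requires $|r_g| \ge 0.5$ and early/adult expression fold-change
$\ge 1.5$; SNP sets are LD-clumped at $r^2 < 0.2$. The combined
corticolimbic score is the sum of the two regional scores. The comparator
PRS uses GWAS betas for SNPs passing `p < 4.912e-5` (or the top 4515 by
p-value).

## Worked example

```r
library(coexprs)

# a synthetic two-region study with planted networks of 20 and 12 genes
study  <- simulate_study(n_individuals = 1000, n_network = c(20, 12),
                         n_null = 30, snps_per_gene = 6, seed = 11)
scored <- score_study(study)
scored$manifest$PFC
#>   genes_expression      genes_network      pairs_catalog    pairs_collected
#>                 50                 20                120                120
#>   pairs_harmonized pairs_deduplicated        snps_scored
#>                120                120                 21

head(scored$score_table, 3)
#>   individual_id score_pfc score_nacc score_combined n_snps_pfc n_snps_nacc
#> 1     ind_00001 0.1807417 -0.9490011     -0.7682594         21          14
#> 2     ind_00002 0.6186741 -0.7602341     -0.1415599         21          14
#> 3     ind_00003 0.8227885  0.4762549      1.2990433         21          14
```

The manifest shows the per-stage bookkeeping: 20 network genes × 6 cis-SNPs
collected, none lost to harmonization in this fully synthetic cohort, and
21 SNPs surviving LD clumping. Scoring against a phenotype with a planted
score coefficient of −0.04:

```r
score <- setNames(scored$score_table$score_combined,
                  scored$score_table$individual_id)
set.seed(11)
sex <- rbinom(1000, 1, 0.5); pcs <- matrix(rnorm(3000), 1000, 3)
y <- simulate_phenotypes(score, sex, pcs,
                         phenotype_sim_spec(-0.04, 0.2, c(0.1, -0.05, 0.02),
                                            noise_sd = 1, seed = 12))
fit_linear_association(y, score, sex, pcs, outcome_name = "impulsivity")
#> impulsivity ~ score + sex + PC1 + PC2 + PC3: beta = -0.04575 (se 0.0293), p = 0.1192, n = 1000

power_analysis(0.02, 202)   # one-sided noncentral-t convention
#> [1] 0.6399466
```

The fitted coefficient (−0.046) recovers the planted −0.04 well within one
standard error; at this cohort size and noise level the association is not
individually significant, which is exactly what the power analysis above
says to expect for a small effect ($f^2 = 0.02$) below ~400 individuals.
`median_split()`, `t_test_from_summary()`, `chi_square_2x2()` and
`bonferroni_adjust()` cover the baseline-characteristics side of the
analysis, and `run_pipeline()` drives the same stages from files (PLINK
BED/VCF genotypes, TSV tables, YAML config).

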