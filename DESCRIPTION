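Package: coexprs
Title: Expression-Based Polygenic Scores from Anchor-Gene Co-Expression Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constructs tissue-specific expression-based polygenic scores (ePRS)
    around an anchor gene. Builds per-region anchor-gene co-expression networks
    with a correlation filter and a developmental enrichment filter, assembles
    cis-eQTL SNPs for the network genes with allele harmonization and greedy
    linkage-disequilibrium clumping, computes eQTL-slope-weighted and
    co-expression-signed allele scores plus a conventional GWAS-threshold
    polygenic score comparator, and provides the accompanying association
    statistics (median split, baseline group tests, covariate-adjusted linear
    regression, Bonferroni adjustment, and regression power analysis via
    Cohen's f-squared). A synthetic-data module simulates every pipeline input
    (block-LD genotypes, planted co-expression and developmental fold-changes,
    eQTL catalogs, GWAS summaries, phenotypes) with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
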