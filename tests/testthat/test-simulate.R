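# Synthetic-data generators: seed determinism, statistical convergence to
# the planted ground truth, and input validation.

test_that("expression simulation converges to planted anchor correlations", {
  spec <- expression_sim_spec(
    n_genes = 5, anchor_index = 1,
    target_correlations = c(1, 0.7, 0, -0.5, 0.25),
    fold_changes = rep(1, 5),
    n_samples_early = 5000, n_samples_adult = 5000,
    noise_sd = 0.1, seed = 42)
  e <- simulate_expression(spec)
  prof <- compute_coexpression(e, e$anchor_gene, "PFC")
  r <- setNames(prof$r, prof$gene_id)
  expect_identical(unname(r[e$anchor_gene]), 1)    # self-correlation exact
  # Fisher-z 99.9% half-width at n = 10000 is ~0.007 for r = 0.7; the
  # lognormal transform adds O(noise_sd^2); 0.02 covers both.
  expect_equal(unname(r[2]), 0.7, tolerance = 0.02 / 0.7)
  expect_lt(abs(r[3]), 0.04)
  expect_equal(unname(r[4]), -0.5, tolerance = 0.02 / 0.5)
})

test_that("expression simulation converges to planted fold-changes", {
  fc <- c(1, 2, 1.5, 0.8)
  spec <- expression_sim_spec(
    n_genes = 4, anchor_index = 1,
    target_correlations = c(1, 0.3, 0, 0.1), fold_changes = fc,
    n_samples_early = 4000, n_samples_adult = 4000,
    noise_sd = 0.1, seed = 7)
  e <- simulate_expression(spec)
  stage <- e$samples$stage
  ratio <- rowMeans(e$expr[, stage == "early"]) /
    rowMeans(e$expr[, stage == "adult"])
  expect_equal(unname(ratio), fc, tolerance = 0.02)
})

test_that("expression spec validates its invariants", {
  tc <- c(1, 0.5, 0)
  expect_error(expression_sim_spec(3, 1, tc, rep(1, 3), 2, 5),
               "n_samples_early")
  expect_error(expression_sim_spec(3, 2, tc, rep(1, 3), 5, 5),
               "anchor")
  expect_error(expression_sim_spec(3, 1, c(1, 1.2, 0), rep(1, 3), 5, 5),
               "target_correlations")
  expect_error(expression_sim_spec(3, 1, tc, c(1, -2, 1), 5, 5),
               "fold_changes")
})

test_that("genotype blocks realize the planted LD structure", {
  # perfect LD duplicates columns
  g1 <- simulate_genotypes(
    genotype_sim_spec(300, data.frame(size = 3, r = 1), seed = 1),
    c("a", "b", "c"))
  expect_identical(g1$dosage[, "a"], setNames(g1$dosage[, "b"], rownames(g1$dosage)))
  expect_identical(g1$dosage[, "a"], setNames(g1$dosage[, "c"], rownames(g1$dosage)))

  # r = 0 block: empirical r^2 bounded by sampling noise ~ 1/n
  g0 <- simulate_genotypes(
    genotype_sim_spec(50000, data.frame(size = 4, r = 0), seed = 2),
    sprintf("s%d", 1:4))
  cc <- cor(g0$dosage)^2
  expect_lt(max(cc[upper.tri(cc)]), 0.01)

  # intermediate r: pairwise dosage correlation near r, cross-block near 0
  gm <- simulate_genotypes(
    genotype_sim_spec(20000, data.frame(size = c(3, 3), r = c(0.6, 0.6)),
                      seed = 3),
    sprintf("m%d", 1:6))
  cc <- cor(gm$dosage)
  within <- cc[1:3, 1:3][upper.tri(diag(3))]
  across <- cc[1:3, 4:6]
  expect_equal(mean(within), 0.6, tolerance = 0.03)
  expect_lt(max(abs(across)), 0.05)
})

test_that("genotype missingness and dosage domain honor the spec", {
  g <- simulate_genotypes(
    genotype_sim_spec(500, data.frame(size = 4, r = 0.3),
                      missing_rate = 0, seed = 4),
    sprintf("x%d", 1:4))
  expect_false(anyNA(g$dosage))
  expect_true(all(g$dosage %in% 0:2))

  gm <- simulate_genotypes(
    genotype_sim_spec(2000, data.frame(size = 5, r = 0.3),
                      missing_rate = 0.1, seed = 5),
    sprintf("y%d", 1:5))
  expect_equal(mean(is.na(gm$dosage)), 0.1, tolerance = 0.15)
  expect_error(
    simulate_genotypes(genotype_sim_spec(10, data.frame(size = 3, r = 0)),
                       c("only", "two")),
    "blocks sum")
})

test_that("eQTL catalogs pair SNPs in cis and retain generating slopes", {
  ann <- data.frame(gene_id = c("g1", "g2"), chrom = c("1", "2"),
                    start = c(5e6, 8e6), end = c(5.1e6, 8.05e6))
  vm <- simulate_variant_map(ann, snps_per_gene = 5, cis_window = 1e5,
                             seed = 11)
  expect_equal(nrow(vm), 10)
  cat_ <- simulate_eqtl_catalog(vm, ann, cis_window = 1e5, seed = 11)
  expect_equal(nrow(cat_), 10)
  expect_true(all(c("slope", "pval_nominal") %in% names(cat_)))
  expect_true(all(cat_$pval_nominal > 0 & cat_$pval_nominal <= 1))

  # single gene, single SNP -> one record
  one <- simulate_eqtl_catalog(vm[1, ], ann, cis_window = 1e5, seed = 2)
  expect_equal(nrow(one), 1)

  # SNP relocated outside its gene's cis window is rejected
  bad <- vm
  bad$pos[1] <- 9e6
  expect_error(simulate_eqtl_catalog(bad, ann, cis_window = 1e5),
               "cis window")
})

test_that("catalog size is genes x snps-per-gene at emulation scale", {
  ann <- data.frame(gene_id = sprintf("g%03d", 1:154),
                    chrom = as.character(1:154),
                    start = 5e6, end = 5.1e6)
  vm <- simulate_variant_map(ann, snps_per_gene = 267, seed = 1)
  expect_equal(nrow(vm), 154 * 267)          # ~41k pairs, PFC-scale
})

test_that("phenotype simulation recovers planted coefficients noiselessly", {
  set.seed(9)
  n <- 200
  score <- rnorm(n)
  sex <- rbinom(n, 1, 0.5)
  pcs <- matrix(rnorm(n * 2), n, 2)
  spec <- phenotype_sim_spec(beta_score = -0.04, beta_sex = 0.3,
                             beta_pcs = c(0.1, -0.2), noise_sd = 1e-10,
                             seed = 3)
  y <- simulate_phenotypes(score, sex, pcs, spec)
  fit <- lm(y ~ score + sex + pcs)
  expect_equal(unname(coef(fit)["score"]), -0.04, tolerance = 1e-6)
  # reproducibility
  y2 <- simulate_phenotypes(score, sex, pcs, spec)
  expect_identical(y, y2)
  expect_error(simulate_phenotypes(score, sex[-1], pcs, spec), "length")
})

test_that("GWAS summaries have uniform null p-values at the tail", {
  gw <- simulate_gwas_summary(1e6, prop_null = 1, seed = 13)
  thr <- 4.912e-5
  hits <- sum(gw$p < thr)
  lam <- 1e6 * thr                           # expected count ~ 49
  expect_lt(abs(hits - lam), 4 * sqrt(lam))
  expect_gt(suppressWarnings(ks.test(gw$p[1:5000], "punif"))$p.value, 0.01)
  expect_equal(nrow(simulate_gwas_summary(0)), 0)
  expect_identical(simulate_gwas_summary(100, seed = 5),
                   simulate_gwas_summary(100, seed = 5))
})

test_that("every generator is bit-reproducible under a fixed seed", {
  es <- expression_sim_spec(4, 1, c(1, 0.5, 0, -0.3), rep(1, 4), 5, 5,
                            seed = 77)
  expect_identical(simulate_expression(es)$expr, simulate_expression(es)$expr)
  gs <- genotype_sim_spec(50, data.frame(size = 3, r = 0.5), seed = 77)
  expect_identical(simulate_genotypes(gs, c("a", "b", "c"))$dosage,
                   simulate_genotypes(gs, c("a", "b", "c"))$dosage)
  ann <- data.frame(gene_id = "g", chrom = "1", start = 5e6, end = 5.1e6)
  vm <- simulate_variant_map(ann, 4, seed = 77)
  expect_identical(vm, simulate_variant_map(ann, 4, seed = 77))
  expect_identical(simulate_eqtl_catalog(vm, ann, seed = 77),
                   simulate_eqtl_catalog(vm, ann, seed = 77))
})

test_that("substream seeds differ across stages but are stable", {
  expect_identical(derive_seed(1, "genotypes"), derive_seed(1, "genotypes"))
  expect_false(derive_seed(1, "genotypes") == derive_seed(1, "expression"))
  expect_false(derive_seed(1, "genotypes") == derive_seed(2, "genotypes"))
  expect_true(derive_seed(.Machine$integer.max, "x") <= .Machine$integer.max)
})
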