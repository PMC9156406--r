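# Variant assembly: cis-pair collection, allele harmonization, per-variant
# deduplication, and LD clumping against a brute-force oracle.

fake_network <- function(genes, signs) {
  data.frame(gene_id = genes, r = signs * 0.8, sign = signs)
}

test_that("cis-pair collection restricts to network genes and tags signs", {
  ann <- data.frame(gene_id = c("g1", "g2", "g3"), chrom = "1",
                    start = c(1e6, 3e6, 5e6), end = c(1.1e6, 3.1e6, 5.1e6))
  cat_ <- data.frame(gene_id = rep(c("g1", "g2", "g4"), each = 3),
                     variant_id = sprintf("v%d", 1:9), chrom = "1",
                     pos = 1:9 * 1e5, effect_allele = "A",
                     other_allele = "G", slope = 0.2,
                     pval_nominal = 0.01)
  net <- fake_network(c("g1", "g2"), c(1L, -1L))
  pairs <- collect_cis_pairs(net, cat_, ann)
  expect_equal(nrow(pairs), 6)               # 2 genes x 3 records
  expect_equal(unique(pairs$network_sign[pairs$gene_id == "g1"]), 1L)
  expect_equal(unique(pairs$network_sign[pairs$gene_id == "g2"]), -1L)

  # annotated network gene with no catalog records -> empty list
  empty <- collect_cis_pairs(fake_network("g3", 1L),
                             cat_[cat_$gene_id != "g4", ], ann)
  expect_equal(nrow(empty), 0)

  # unannotated network gene -> warning + exclusion record
  expect_warning(
    out <- collect_cis_pairs(fake_network(c("g1", "g8"), c(1L, 1L)), cat_, ann),
    "lack annotation")
  expect_equal(attr(out, "excluded_genes"), "g8")
})

test_that("allele harmonization keeps, flips, and drops correctly", {
  cohort <- data.frame(variant_id = c("v1", "v2", "v3", "v4", "v5"),
                       allele1 = c("A", "G", "A", "C", "T"),
                       allele2 = c("G", "A", "T", "A", "C"))
  pairs <- data.frame(
    variant_id = c("v1", "v2", "v3", "v4", "v5", "v6"),
    effect_allele = c("A", "A", "A", "G", "G", "A"),
    other_allele = c("G", "G", "T", "T", "A", "G"),
    payload = 1:6)
  h <- harmonize_alleles(pairs, cohort)
  kept <- setNames(h$pairs$flip, h$pairs$variant_id)
  expect_identical(kept, c(v1 = FALSE, v2 = TRUE, v4 = FALSE, v5 = TRUE))
  # v4: eQTL G/T vs cohort C/A resolves across strands, effect stays counted
  # v5: eQTL G/A vs cohort T/C resolves across strands with a swap
  expect_true(h$pairs$strand_flipped[h$pairs$variant_id == "v4"])
  expect_true(h$pairs$strand_flipped[h$pairs$variant_id == "v5"])
  drops <- setNames(h$drops$reason, h$drops$variant_id)
  expect_identical(drops[c("v3", "v6")],
                   c(v3 = "strand_ambiguous", v6 = "absent_from_cohort"))
  # payload columns survive
  expect_true("payload" %in% names(h$pairs))

  # incompatible alleles drop with their own reason
  mism <- harmonize_alleles(
    data.frame(variant_id = "v1", effect_allele = "A", other_allele = "C"),
    cohort)
  expect_equal(mism$drops$reason, "allele_mismatch")

  # ambiguous pairs kept when the policy is overridden
  keep_amb <- harmonize_alleles(
    data.frame(variant_id = "v3", effect_allele = "A", other_allele = "T"),
    cohort, drop_ambiguous = FALSE)
  expect_equal(nrow(keep_amb$pairs), 1)
})

test_that("per-variant deduplication follows the p / |slope| / gene order", {
  pairs <- data.frame(
    variant_id = c("v1", "v1", "v2", "v2", "v3"),
    gene_id = c("gA", "gB", "gB", "gA", "gC"),
    slope = c(0.2, 0.5, 0.4, -0.6, 0.1),
    pval_nominal = c(1e-8, 1e-3, 1e-4, 1e-4, 0.5))
  out <- deduplicate_snp_gene(pairs)
  expect_equal(nrow(out), 3)
  expect_equal(out$gene_id[out$variant_id == "v1"], "gA")   # smaller p wins
  expect_equal(out$slope[out$variant_id == "v2"], -0.6)     # |slope| breaks tie
  expect_equal(out$gene_id[out$variant_id == "v3"], "gC")   # singleton unchanged
  expect_equal(attr(out, "duplicates_resolved"), 2)

  tie <- deduplicate_snp_gene(data.frame(
    variant_id = "v", gene_id = c("gB", "gA"), slope = c(0.3, 0.3),
    pval_nominal = c(0.01, 0.01)))
  expect_equal(tie$gene_id, "gA")                           # lexicographic
})

clump_pairs <- function(ids, pos, p, slope = 0.3, chrom = "1") {
  data.frame(variant_id = ids, chrom = chrom, pos = pos,
             slope = slope, pval_nominal = p,
             gene_id = "g", network_sign = 1L, flip = FALSE)
}

test_that("duplicate SNPs collapse to the higher-priority one", {
  set.seed(1)
  d <- rbinom(200, 2, 0.3)
  geno <- make_geno(cbind(v001 = d, v002 = d), pos = c(1000, 2000))
  cl <- ld_clump(clump_pairs(c("v001", "v002"), c(1000, 2000),
                             c(1e-6, 1e-3)), geno)
  expect_equal(cl$retained$variant_id, "v001")
  expect_equal(cl$removed$variant_id, "v002")
  expect_equal(cl$removed$r2, 1)
})

test_that("independent SNPs all survive clumping", {
  set.seed(2)
  geno <- make_geno(sapply(1:6, function(i) rbinom(3000, 2, 0.3)))
  cl <- ld_clump(clump_pairs(colnames(geno$dosage), 1:6 * 1000,
                             runif(6)), geno)
  expect_equal(nrow(cl$retained), 6)
})

test_that("monomorphic SNPs are dropped before clumping with a reason", {
  set.seed(3)
  dos <- cbind(v001 = rbinom(100, 2, 0.4), v002 = rep(2, 100))
  geno <- make_geno(dos)
  cl <- ld_clump(clump_pairs(c("v001", "v002"), c(1000, 2000),
                             c(0.5, 1e-9)), geno)
  expect_equal(cl$monomorphic, "v002")
  expect_equal(cl$retained$variant_id, "v001")
})

test_that("10-SNP toys match the exhaustive greedy oracle", {
  for (seed in c(11, 22, 33, 44)) {
    gs <- genotype_sim_spec(400,
                            data.frame(size = c(4, 3, 3),
                                       r = c(0.8, 0.5, 0.2)),
                            seed = seed)
    geno <- simulate_genotypes(gs, sprintf("v%03d", 1:10))
    set.seed(seed)
    pairs <- clump_pairs(sprintf("v%03d", 1:10),
                         pos = rep(1:10 * 1e4, 1),
                         p = runif(10), slope = rnorm(10),
                         chrom = geno$variants$chrom)
    pairs$chrom <- geno$variants$chrom       # keep block chromosomes
    cl <- ld_clump(pairs, geno, r2_max = 0.2, window_kb = 250)
    expect_identical(sort(cl$retained$variant_id),
                     sort(oracle_clump(pairs, geno$dosage, 0.2, 250)))
    # post-condition, exhaustively
    chk <- check_clump(cl$retained, geno, 0.2, 250)
    expect_true(chk$ok)
  }
})

test_that("tightening r2_max never enlarges the retained set", {
  gs <- genotype_sim_spec(500, data.frame(size = c(5, 5), r = c(0.6, 0.3)),
                          seed = 9)
  geno <- simulate_genotypes(gs, sprintf("v%03d", 1:10))
  set.seed(9)
  pairs <- clump_pairs(sprintf("v%03d", 1:10), 1:10 * 1e4, runif(10),
                       chrom = geno$variants$chrom)
  sizes <- vapply(c(0.8, 0.5, 0.2, 0.1, 0.05),
                  function(r2) nrow(ld_clump(pairs, geno, r2_max = r2)$retained),
                  numeric(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("clumping is deterministic and errors on missing dosages", {
  gs <- genotype_sim_spec(300, data.frame(size = 6, r = 0.5), seed = 10)
  geno <- simulate_genotypes(gs, sprintf("v%03d", 1:6))
  set.seed(10)
  pairs <- clump_pairs(sprintf("v%03d", 1:6), 1:6 * 1e4, runif(6),
                       chrom = geno$variants$chrom)
  a <- ld_clump(pairs, geno)
  b <- ld_clump(pairs, geno)
  expect_identical(a$retained, b$retained)
  pairs$variant_id[1] <- "ghost"
  expect_error(ld_clump(pairs, geno), "ghost")
})
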