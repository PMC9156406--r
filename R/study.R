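# End-to-end synthetic study generator: builds, for each brain region, an
# expression matrix with a planted co-expression network, a gene annotation,
# a cis-eQTL catalog, plus one cohort genotype matrix and (optionally) GWAS
# summary statistics — everything the scoring pipeline consumes, with ground
# truth retained.

#' Simulate a complete synthetic study
#'
#' For each region, `n_network` genes (including the anchor) are planted to
#' pass both network filters: they carry high absolute correlation with the
#' anchor and an early/adult fold-change of `fold_pass`, while the remaining
#' `n_null` genes have near-zero anchor correlation and no developmental
#' enrichment. Gene bodies are laid out on autosomes with wide spacing so
#' that different genes' cis windows do not overlap. Each gene's cis SNPs
#' form one LD block of within-block correlation `block_r`.
#'
#' @param n_individuals Cohort size.
#' @param regions Character vector of region labels.
#' @param n_network Genes planted to pass both filters per region
#'   (anchor included).
#' @param n_null Non-network genes per region.
#' @param snps_per_gene cis-SNPs per network gene.
#' @param block_r Within-gene LD block correlation.
#' @param fold_pass Planted early/adult fold-change of network genes.
#' @param r_pass Planted anchor correlation magnitude of network genes
#'   (signs alternate +/- to exercise the co-expression sign).
#' @param n_samples_early,n_samples_adult Expression sample counts per stage.
#' @param noise_sd Log-scale expression noise.
#' @param maf_range,missing_rate Genotype simulation parameters.
#' @param n_gwas_snps SNPs in the simulated GWAS summary (0 to skip).
#' @param seed Global seed; stage substreams are derived from it.
#' @return A list with `regions` (per-region list: `expression`, `catalog`,
#'   `variant_map`, `anchor`), `annotation`, `genotypes`, `gwas`, and
#'   `params` (the generating arguments).
#' @export
simulate_study <- function(n_individuals = 500,
                           regions = c("PFC", "NAcc"),
                           n_network = c(154, 72),
                           n_null = 60,
                           snps_per_gene = 8,
                           block_r = 0.6,
                           fold_pass = 2,
                           r_pass = 0.8,
                           n_samples_early = 80, n_samples_adult = 80,
                           noise_sd = 0.1,
                           maf_range = c(0.1, 0.5), missing_rate = 0.01,
                           n_gwas_snps = 0,
                           seed = 1L) {
  stopifnot(length(n_network) == length(regions))
  n_null <- rep_len(n_null, length(regions))
  region_data <- list()
  annotation <- NULL
  all_variants <- NULL
  blocks <- NULL
  chrom_cursor <- 0L
  for (k in seq_along(regions)) {
    reg <- regions[k]
    n_net <- n_network[k]
    n_genes <- n_net + n_null[k]
    ids <- sprintf("%s_gene_%04d", reg, seq_len(n_genes))
    anchor_idx <- 1L
    ## planted targets: network genes correlate strongly with the anchor
    ## (alternating sign) and are developmentally enriched; null genes are
    ## neither.
    target_r <- c(1, rep_len(c(r_pass, -r_pass), n_net - 1),
                  rep(0.05, n_null[k]))
    fold <- c(rep(fold_pass, n_net), rep(1, n_null[k]))
    espec <- expression_sim_spec(
      n_genes = n_genes, anchor_index = anchor_idx,
      target_correlations = target_r, fold_changes = fold,
      n_samples_early = n_samples_early, n_samples_adult = n_samples_adult,
      noise_sd = noise_sd, region = reg, gene_ids = ids,
      seed = derive_seed(seed, paste0("expr_", reg)))
    expression <- simulate_expression(espec)

    ## annotate network genes on their own chromosome stretch, 5 Mb bodies
    ## spaced 10 Mb apart so cis windows (+/- 1 Mb) never overlap.
    ann <- data.frame(gene_id = ids[seq_len(n_net)],
                      chrom = as.character(chrom_cursor + seq_len(n_net)),
                      start = 5e6, end = 5.1e6, stringsAsFactors = FALSE)
    chrom_cursor <- chrom_cursor + n_net
    annotation <- rbind(annotation, ann)

    vmap <- simulate_variant_map(ann, snps_per_gene, cis_window = 1e5,
                                 seed = derive_seed(seed, paste0("vmap_", reg)))
    catalog <- simulate_eqtl_catalog(vmap, ann, cis_window = 1e5,
                                     seed = derive_seed(seed, paste0("eqtl_", reg)))
    region_data[[reg]] <- list(expression = expression, catalog = catalog,
                               variant_map = vmap, anchor = ids[anchor_idx])
    all_variants <- rbind(all_variants,
                          data.frame(variant_id = vmap$variant_id,
                                     chrom = vmap$chrom, pos = vmap$pos,
                                     allele1 = vmap$effect_allele,
                                     allele2 = vmap$other_allele,
                                     stringsAsFactors = FALSE))
    blocks <- rbind(blocks, data.frame(size = rep(snps_per_gene, n_net),
                                       r = block_r))
  }
  gspec <- genotype_sim_spec(n_individuals = n_individuals, blocks = blocks,
                             maf_range = maf_range,
                             missing_rate = missing_rate,
                             seed = derive_seed(seed, "genotypes"))
  genotypes <- simulate_genotypes(gspec, all_variants)
  gwas <- if (n_gwas_snps > 0) {
    simulate_gwas_summary(n_gwas_snps, seed = derive_seed(seed, "gwas"))
  } else {
    NULL
  }
  list(regions = region_data, annotation = annotation, genotypes = genotypes,
       gwas = gwas,
       params = list(n_individuals = n_individuals, regions = regions,
                     n_network = n_network, n_null = n_null,
                     snps_per_gene = snps_per_gene, block_r = block_r,
                     fold_pass = fold_pass, r_pass = r_pass,
                     noise_sd = noise_sd, seed = seed))
}

#' Score a simulated study end to end
#'
#' Runs, for each region, the full in-memory pipeline on a
#' [simulate_study()] object — network construction, cis-pair collection,
#' allele harmonization, per-variant deduplication, LD clumping, weight
#' derivation and scoring — and combines the regional scores.
#'
#' @param study A [simulate_study()] result.
#' @param min_abs_r,min_fold Network filter thresholds.
#' @param r2_max,window_kb LD clumping parameters.
#' @return A list with `score_table` (see [build_score_table()]),
#'   `networks`, `clumps`, `weights`, and a `manifest` of per-stage counts.
#' @export
score_study <- function(study, min_abs_r = 0.5, min_fold = 1.5,
                        r2_max = 0.2, window_kb = 250) {
  networks <- list()
  clumps <- list()
  weights <- list()
  scores <- list()
  manifest <- list()
  for (reg in names(study$regions)) {
    rd <- study$regions[[reg]]
    net <- build_network(rd$expression, rd$anchor, reg,
                         min_abs_r = min_abs_r, min_fold = min_fold)
    pairs <- collect_cis_pairs(net, rd$catalog, study$annotation)
    harm <- harmonize_alleles(pairs, study$genotypes$variants)
    dedup <- deduplicate_snp_gene(harm$pairs)
    clump <- ld_clump(dedup, study$genotypes, r2_max = r2_max,
                      window_kb = window_kb)
    w <- snp_weights(clump$retained, reg)
    networks[[reg]] <- net
    clumps[[reg]] <- clump
    weights[[reg]] <- w
    scores[[reg]] <- compute_region_score(study$genotypes, w)
    manifest[[reg]] <- c(genes_expression = nrow(rd$expression$expr),
                         genes_network = nrow(net),
                         pairs_catalog = nrow(rd$catalog),
                         pairs_collected = nrow(pairs),
                         pairs_harmonized = nrow(harm$pairs),
                         pairs_deduplicated = nrow(dedup),
                         snps_scored = nrow(clump$retained))
  }
  list(score_table = build_score_table(scores), networks = networks,
       clumps = clumps, weights = weights, manifest = manifest)
}
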