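# Synthetic-data generators for every pipeline input, each carrying its
# generating parameters so that downstream stages can be tested against known
# ground truth without any external download.

#' Specify a synthetic expression matrix with planted anchor correlations
#'
#' Describes a gene-by-sample expression matrix in which each gene has a
#' target Pearson correlation with a designated anchor gene and a planted
#' early/adult developmental fold-change. Expression is generated on the log
#' scale through a single-factor Gaussian construction (the anchor's latent
#' factor, scaled per gene to hit the target correlation) and exponentiated,
#' which keeps expression positive and makes the ratio of arithmetic means
#' between stages equal to the planted fold-change.
#'
#' Stage shifts act like a shared binary covariate: genes whose fold-change
#' differs from 1 acquire extra stage-driven covariance with each other. The
#' anchor correlations are therefore exactly the targets when the anchor's
#' own fold-change is 1; with a non-unit anchor fold-change they hold within
#' the stage-shift distortion (see the methods vignette).
#'
#' @param n_genes Number of genes (>= 2).
#' @param anchor_index Index of the anchor gene; its target correlation must
#'   have absolute value 1.
#' @param target_correlations Numeric vector of length `n_genes` in
#'   \[-1, 1\]: desired Pearson r of each gene with the anchor.
#' @param fold_changes Positive numeric vector of length `n_genes`: desired
#'   ratio mean(early)/mean(adult) of expression for each gene.
#' @param n_samples_early,n_samples_adult Sample counts per stage (>= 3).
#' @param noise_sd Standard deviation of log-scale expression (> 0). Small
#'   values (<= 0.25) keep the exponentiation near-linear so empirical
#'   correlations track the targets closely.
#' @param base_level Adult-stage mean expression level (arbitrary units).
#' @param region Region label attached to every sample.
#' @param gene_ids Optional character vector of gene identifiers.
#' @param seed Integer RNG seed.
#' @return An object of class `"coex_expression_spec"`.
#' @export
expression_sim_spec <- function(n_genes, anchor_index, target_correlations,
                                fold_changes, n_samples_early, n_samples_adult,
                                noise_sd = 0.1, base_level = 10, region = "PFC",
                                gene_ids = NULL, seed = 1L) {
  .assert_scalar_number(n_genes, "n_genes", 2)
  .assert_scalar_number(anchor_index, "anchor_index", 1, n_genes)
  .assert_scalar_number(n_samples_early, "n_samples_early", 3)
  .assert_scalar_number(n_samples_adult, "n_samples_adult", 3)
  .assert_scalar_number(noise_sd, "noise_sd", lo = 1e-12)
  if (length(target_correlations) != n_genes || any(abs(target_correlations) > 1)) {
    stop("`target_correlations` must have length n_genes with |r| <= 1", call. = FALSE)
  }
  if (abs(abs(target_correlations[anchor_index]) - 1) > 1e-12) {
    stop("the anchor's target correlation must be +1 or -1", call. = FALSE)
  }
  if (length(fold_changes) != n_genes || any(fold_changes <= 0)) {
    stop("`fold_changes` must have length n_genes with all values > 0", call. = FALSE)
  }
  if (is.null(gene_ids)) {
    gene_ids <- sprintf("gene_%04d", seq_len(n_genes))
  }
  stopifnot(length(gene_ids) == n_genes, !anyDuplicated(gene_ids))
  structure(list(
    n_genes = as.integer(n_genes), anchor_index = as.integer(anchor_index),
    target_correlations = as.numeric(target_correlations),
    fold_changes = as.numeric(fold_changes),
    n_samples_early = as.integer(n_samples_early),
    n_samples_adult = as.integer(n_samples_adult),
    noise_sd = noise_sd, base_level = base_level, region = region,
    gene_ids = gene_ids, seed = as.integer(seed)
  ), class = "coex_expression_spec")
}

#' Simulate an expression matrix with developmental-stage labels
#'
#' @param spec An [expression_sim_spec()].
#' @return A `"coex_expression"` object: a list with `expr` (genes x samples
#'   matrix of positive expression values), `samples` (data frame with
#'   `sample_id`, `region`, `stage` in \{early, adult\}), `anchor_gene`, and
#'   the generating `spec` retained for ground-truth tests.
#' @export
simulate_expression <- function(spec) {
  stopifnot(inherits(spec, "coex_expression_spec"))
  n_samples <- spec$n_samples_early + spec$n_samples_adult
  stage <- rep(c("early", "adult"), c(spec$n_samples_early, spec$n_samples_adult))
  r <- spec$target_correlations
  .with_seed(spec$seed, {
    f <- rnorm(n_samples)                       # anchor latent factor
    eps <- matrix(rnorm(n_samples * spec$n_genes), spec$n_genes, n_samples)
    z <- r * matrix(f, spec$n_genes, n_samples, byrow = TRUE) +
      sqrt(pmax(0, 1 - r^2)) * eps
    shift <- outer(log(spec$fold_changes), as.numeric(stage == "early"))
    expr <- exp(log(spec$base_level) + shift + spec$noise_sd * z)
  })
  dimnames(expr) <- list(spec$gene_ids,
                         sprintf("%s_s%04d", spec$region, seq_len(n_samples)))
  structure(list(
    expr = expr,
    samples = data.frame(sample_id = colnames(expr), region = spec$region,
                         stage = stage, stringsAsFactors = FALSE),
    anchor_gene = spec$gene_ids[spec$anchor_index],
    spec = spec
  ), class = "coex_expression")
}

#' @export
print.coex_expression <- function(x, ...) {
  cat(sprintf("coex_expression: %d genes x %d samples (region %s, anchor %s)\n",
              nrow(x$expr), ncol(x$expr), x$spec$region, x$anchor_gene))
  invisible(x)
}

#' Specify synthetic genotypes with block linkage disequilibrium
#'
#' Genotypes are organised in blocks; within a block every pair of SNPs has
#' (population) dosage correlation `r`, and SNPs in different blocks are
#' independent. Each block draws one minor-allele frequency from `maf_range`
#' (shared within the block, so that `r = 1` yields literally identical
#' columns). Haplotype alleles are built by copying a latent block haplotype
#' with probability `sqrt(r)` and drawing fresh Bernoulli(maf) alleles
#' otherwise, which gives exact pairwise correlation `r` with exact
#' Bernoulli(maf) margins.
#'
#' @param n_individuals Number of individuals (>= 2).
#' @param blocks Data frame with columns `size` (SNPs per block) and `r`
#'   (within-block correlation in \[0, 1\]).
#' @param maf_range Length-2 numeric, minor-allele frequency bounds in
#'   (0, 0.5\].
#' @param missing_rate Proportion of dosages set missing completely at
#'   random, in \[0, 1).
#' @param seed Integer RNG seed.
#' @return An object of class `"coex_genotype_spec"`.
#' @export
genotype_sim_spec <- function(n_individuals, blocks, maf_range = c(0.05, 0.5),
                              missing_rate = 0, seed = 1L) {
  .assert_scalar_number(n_individuals, "n_individuals", 2)
  blocks <- as.data.frame(blocks)
  stopifnot(all(c("size", "r") %in% names(blocks)),
            all(blocks$size >= 1), all(blocks$r >= 0 & blocks$r <= 1))
  if (length(maf_range) != 2 || maf_range[1] > maf_range[2] ||
      maf_range[1] <= 0 || maf_range[2] > 0.5) {
    stop("`maf_range` must be ordered bounds within (0, 0.5]", call. = FALSE)
  }
  .assert_scalar_number(missing_rate, "missing_rate", 0, 1 - 1e-12)
  structure(list(
    n_individuals = as.integer(n_individuals), blocks = blocks,
    maf_range = as.numeric(maf_range), missing_rate = missing_rate,
    seed = as.integer(seed)
  ), class = "coex_genotype_spec")
}

#' Construct a genotype dosage matrix container
#'
#' @param dosage Individuals-by-SNPs numeric matrix of effect-allele dosages
#'   in \{0, 1, 2\} with `NA` for missing; row names are individual ids and
#'   column names variant ids.
#' @param variants Data frame with `variant_id`, `chrom`, `pos`, `allele1`
#'   (the allele counted by the dosage), `allele2`, aligned to the columns.
#' @return An object of class `"coex_genotypes"`.
#' @export
genotype_matrix <- function(dosage, variants) {
  variants <- as.data.frame(variants)
  stopifnot(is.matrix(dosage),
            all(c("variant_id", "chrom", "pos", "allele1", "allele2") %in%
                  names(variants)),
            nrow(variants) == ncol(dosage),
            ncol(dosage) == 0 ||
              identical(colnames(dosage), as.character(variants$variant_id)))
  structure(list(dosage = dosage, variants = variants,
                 individuals = rownames(dosage)),
            class = "coex_genotypes")
}

#' @export
print.coex_genotypes <- function(x, ...) {
  cat(sprintf("coex_genotypes: %d individuals x %d variants (%.2f%% missing)\n",
              nrow(x$dosage), ncol(x$dosage),
              100 * mean(is.na(x$dosage))))
  invisible(x)
}

#' Simulate block-LD genotype dosages
#'
#' @param spec A [genotype_sim_spec()].
#' @param snp_ids Either a character vector of variant ids (coordinates are
#'   then auto-assigned: one chromosome per block, 5 kb SNP spacing) or a
#'   variant table (`variant_id`, `chrom`, `pos`, and optionally `allele1`,
#'   `allele2`). Its length/row count must equal the total block size.
#' @return A [genotype_matrix()] whose `variants` table carries the block
#'   index, the block `maf` and block `r` as ground truth.
#' @export
simulate_genotypes <- function(spec, snp_ids) {
  stopifnot(inherits(spec, "coex_genotype_spec"))
  n_snps <- sum(spec$blocks$size)
  n_given <- if (is.character(snp_ids)) length(snp_ids) else nrow(snp_ids)
  if (n_given != n_snps) {
    stop(sprintf("got %d snp ids but blocks sum to %d SNPs", n_given, n_snps),
         call. = FALSE)
  }
  if (is.character(snp_ids)) {
    block_of <- rep(seq_len(nrow(spec$blocks)), spec$blocks$size)
    within <- sequence(spec$blocks$size)
    variants <- data.frame(variant_id = snp_ids,
                           chrom = as.character(block_of),
                           pos = 1e4 + within * 5e3,
                           stringsAsFactors = FALSE)
  } else {
    variants <- as.data.frame(snp_ids)
    stopifnot(all(c("variant_id", "chrom", "pos") %in% names(variants)))
  }
  n <- spec$n_individuals
  .with_seed(spec$seed, {
    if (!all(c("allele1", "allele2") %in% names(variants))) {
      ## non-ambiguous purine/pyrimidine pairs by default
      pick <- sample(4, n_snps, replace = TRUE)
      variants$allele1 <- c("A", "A", "T", "T")[pick]
      variants$allele2 <- c("G", "C", "G", "C")[pick]
    }
    dosage <- matrix(NA_real_, n, n_snps)
    mafs <- numeric(n_snps)
    col0 <- 0L
    for (b in seq_len(nrow(spec$blocks))) {
      m <- spec$blocks$size[b]
      r <- spec$blocks$r[b]
      q <- sqrt(r)                               # per-haplotype copy probability
      maf <- runif(1, spec$maf_range[1], spec$maf_range[2])
      mafs[col0 + seq_len(m)] <- maf
      for (hap in 1:2) {
        base <- rbinom(n, 1, maf)
        copy <- matrix(rbinom(n * m, 1, q), n, m)
        fresh <- matrix(rbinom(n * m, 1, maf), n, m)
        alleles <- copy * base + (1 - copy) * fresh
        idx <- col0 + seq_len(m)
        dosage[, idx] <- if (hap == 1) alleles else dosage[, idx] + alleles
      }
      col0 <- col0 + m
    }
    if (spec$missing_rate > 0) {
      dosage[runif(length(dosage)) < spec$missing_rate] <- NA_real_
    }
  })
  variants$maf <- mafs
  variants$block <- rep(seq_len(nrow(spec$blocks)), spec$blocks$size)
  variants$block_r <- rep(spec$blocks$r, spec$blocks$size)
  rownames(dosage) <- sprintf("ind_%05d", seq_len(n))
  colnames(dosage) <- variants$variant_id
  genotype_matrix(dosage, variants)
}

#' Place cis-SNPs around annotated genes
#'
#' Builds a gene-to-variant map emulating a cis-eQTL design: each gene
#' receives `snps_per_gene` SNPs at positions uniform over its cis window
#' (gene body +/- `cis_window`).
#'
#' @param annotation Data frame with `gene_id`, `chrom`, `start`, `end`
#'   (1-based inclusive).
#' @param snps_per_gene Integer, SNPs placed per gene (recycled).
#' @param cis_window Window in bases each side of the gene (default 1 Mb,
#'   the usual cis-eQTL convention).
#' @param seed Integer RNG seed.
#' @return Data frame `gene_id`, `variant_id`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele`.
#' @export
simulate_variant_map <- function(annotation, snps_per_gene, cis_window = 1e6,
                                 seed = 1L) {
  annotation <- as.data.frame(annotation)
  stopifnot(all(c("gene_id", "chrom", "start", "end") %in% names(annotation)))
  k <- rep_len(as.integer(snps_per_gene), nrow(annotation))
  .with_seed(seed, {
    rows <- lapply(seq_len(nrow(annotation)), function(i) {
      g <- annotation[i, ]
      pos <- sort(sample(max(1, g$start - cis_window):(g$end + cis_window), k[i]))
      pick <- sample(4, k[i], replace = TRUE)
      data.frame(gene_id = g$gene_id,
                 variant_id = sprintf("rs_%s_%d", g$gene_id, seq_len(k[i])),
                 chrom = g$chrom, pos = pos,
                 effect_allele = c("A", "A", "T", "T")[pick],
                 other_allele = c("G", "C", "G", "C")[pick],
                 stringsAsFactors = FALSE)
    })
  })
  do.call(rbind, rows)
}

#' Simulate a cis-eQTL catalog with known slopes
#'
#' Assigns each gene-SNP pair an eQTL slope (per-effect-allele change in
#' expression) drawn from a normal distribution, plus a nominal p-value.
#' Every SNP is validated to lie within the cis window of its paired gene.
#'
#' @param variant_map Gene-SNP pairing as from [simulate_variant_map()].
#' @param annotation Gene annotation (`gene_id`, `chrom`, `start`, `end`)
#'   used to validate cis pairing.
#' @param slope_mean,slope_sd Parameters of the slope distribution.
#' @param cis_window Cis window in bases used for validation.
#' @param seed Integer RNG seed.
#' @return Data frame with columns `gene_id`, `variant_id`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele`, `slope`, `pval_nominal`. The `slope`
#'   column is itself the ground truth for downstream recovery tests.
#' @export
simulate_eqtl_catalog <- function(variant_map, annotation, slope_mean = 0,
                                  slope_sd = 0.35, cis_window = 1e6, seed = 1L) {
  variant_map <- as.data.frame(variant_map)
  annotation <- as.data.frame(annotation)
  need <- c("gene_id", "variant_id", "chrom", "pos", "effect_allele", "other_allele")
  stopifnot(all(need %in% names(variant_map)))
  .assert_scalar_number(slope_sd, "slope_sd", 0)
  ann <- annotation[match(variant_map$gene_id, annotation$gene_id), ]
  if (anyNA(ann$gene_id)) {
    stop("variant map references genes absent from the annotation", call. = FALSE)
  }
  bad <- variant_map$chrom != ann$chrom |
    variant_map$pos < ann$start - cis_window |
    variant_map$pos > ann$end + cis_window
  if (any(bad)) {
    stop(sprintf("%d SNP(s) fall outside the cis window of their paired gene (e.g. %s)",
                 sum(bad), variant_map$variant_id[which(bad)[1]]), call. = FALSE)
  }
  n <- nrow(variant_map)
  .with_seed(seed, {
    slope <- rnorm(n, slope_mean, slope_sd)
    pval <- 10^(-runif(n, 0, 8))
  })
  out <- variant_map[need]
  out$slope <- slope
  out$pval_nominal <- pval
  out
}

#' Specify a synthetic phenotype model
#'
#' @param beta_score Planted regression coefficient of the genetic score
#'   (may be zero for null simulations).
#' @param beta_sex Coefficient of the sex covariate.
#' @param beta_pcs Numeric vector of coefficients for population-structure
#'   principal components (may be empty).
#' @param noise_sd Residual standard deviation (> 0).
#' @param seed Integer RNG seed.
#' @return An object of class `"coex_phenotype_spec"`.
#' @export
phenotype_sim_spec <- function(beta_score, beta_sex = 0, beta_pcs = numeric(),
                               noise_sd = 1, seed = 1L) {
  .assert_scalar_number(beta_score, "beta_score")
  .assert_scalar_number(beta_sex, "beta_sex")
  .assert_scalar_number(noise_sd, "noise_sd", lo = 1e-12)
  structure(list(beta_score = beta_score, beta_sex = beta_sex,
                 beta_pcs = as.numeric(beta_pcs), noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "coex_phenotype_spec")
}

#' Simulate phenotypes from a linear model on score and covariates
#'
#' phenotype = beta_score * score + beta_sex * sex + sum(beta_pc * pc) +
#' Gaussian noise.
#'
#' @param scores Numeric vector of genetic scores.
#' @param sex Numeric/integer vector (e.g. 0/1 coded), same length.
#' @param pcs Matrix of principal components (columns matched to
#'   `beta_pcs`), or `NULL` when `beta_pcs` is empty.
#' @param spec A [phenotype_sim_spec()].
#' @return Numeric phenotype vector, named like `scores` if it has names.
#' @export
simulate_phenotypes <- function(scores, sex, pcs = NULL, spec) {
  stopifnot(inherits(spec, "coex_phenotype_spec"))
  n <- length(scores)
  if (length(sex) != n) stop("`sex` length differs from `scores`", call. = FALSE)
  if (length(spec$beta_pcs) > 0) {
    pcs <- as.matrix(pcs)
    if (nrow(pcs) != n || ncol(pcs) != length(spec$beta_pcs)) {
      stop("`pcs` must be n x length(beta_pcs)", call. = FALSE)
    }
  }
  mu <- spec$beta_score * scores + spec$beta_sex * sex
  if (length(spec$beta_pcs) > 0) mu <- mu + drop(pcs %*% spec$beta_pcs)
  y <- .with_seed(spec$seed, mu + rnorm(n, 0, spec$noise_sd))
  names(y) <- names(scores)
  y
}

#' Simulate GWAS summary statistics
#'
#' A fraction `prop_null` of SNPs are null: their estimated effect is pure
#' noise and their p-values are uniform on (0, 1). Non-null SNPs carry a
#' true effect drawn from N(0, `effect_sd`). Estimated effects are
#' `beta = beta_true + N(0, se)` and p-values come from the Wald z-score
#' `beta / se`.
#'
#' @param n_snps Number of SNPs (0 allowed; returns an empty table).
#' @param prop_null Proportion of null SNPs in \[0, 1\].
#' @param effect_sd Standard deviation of true non-null effects.
#' @param se Per-SNP standard error of the estimated effect.
#' @param variants Optional variant table (`variant_id`, `effect_allele`,
#'   `other_allele`) to reuse cohort variants; otherwise ids and
#'   non-ambiguous allele pairs are generated.
#' @param seed Integer RNG seed.
#' @return Data frame `variant_id`, `effect_allele`, `other_allele`, `beta`,
#'   `p`, plus ground-truth columns `beta_true` and `is_null`.
#' @export
simulate_gwas_summary <- function(n_snps, prop_null = 0.9, effect_sd = 0.05,
                                  se = 0.02, variants = NULL, seed = 1L) {
  .assert_scalar_number(n_snps, "n_snps", 0)
  .assert_scalar_number(prop_null, "prop_null", 0, 1)
  n_snps <- as.integer(n_snps)
  if (n_snps == 0L) {
    return(data.frame(variant_id = character(), effect_allele = character(),
                      other_allele = character(), beta = numeric(),
                      p = numeric(), beta_true = numeric(),
                      is_null = logical(), stringsAsFactors = FALSE))
  }
  .with_seed(seed, {
    if (is.null(variants)) {
      pick <- sample(4, n_snps, replace = TRUE)
      variants <- data.frame(
        variant_id = sprintf("gwas_snp_%06d", seq_len(n_snps)),
        effect_allele = c("A", "A", "T", "T")[pick],
        other_allele = c("G", "C", "G", "C")[pick],
        stringsAsFactors = FALSE)
    } else {
      variants <- as.data.frame(variants)[seq_len(n_snps),
                                          c("variant_id", "effect_allele",
                                            "other_allele")]
    }
    is_null <- runif(n_snps) < prop_null
    beta_true <- ifelse(is_null, 0, rnorm(n_snps, 0, effect_sd))
    beta_hat <- beta_true + rnorm(n_snps, 0, se)
  })
  z <- beta_hat / se
  out <- variants
  out$beta <- beta_hat
  out$p <- 2 * pnorm(-abs(z))
  out$beta_true <- beta_true
  out$is_null <- is_null
  out
}
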