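# ePRS computation: eQTL-slope weights signed by network co-expression,
# per-region allele scoring, combination across regions, and the
# conventional GWAS-threshold PRS comparator.

#' Derive SNP weights from clumped gene-SNP pairs
#'
#' The weight of a SNP is its eQTL slope multiplied by its gene's network
#' sign: an allele that raises the expression of a gene negatively
#' co-expressed with the anchor lowers the network-aligned score.
#'
#' @param pairs Data frame of post-clump pairs with `variant_id`,
#'   `gene_id`, `slope`, `network_sign`, `flip`.
#' @param region Region label stamped on every weight.
#' @return Data frame `variant_id`, `region`, `gene_id`, `weight`, `flip`.
#' @export
snp_weights <- function(pairs, region) {
  pairs <- as.data.frame(pairs)
  stopifnot(all(c("variant_id", "gene_id", "slope", "network_sign") %in%
                  names(pairs)))
  data.frame(variant_id = pairs$variant_id, region = region,
             gene_id = pairs$gene_id,
             weight = pairs$slope * pairs$network_sign,
             flip = if ("flip" %in% names(pairs)) pairs$flip else FALSE,
             stringsAsFactors = FALSE)
}

## Orient dosages to the effect allele (flip => 2 - dosage) and mean-impute
## missing entries per SNP.
.oriented_imputed_dosage <- function(genotypes, variant_ids, flip) {
  missing <- setdiff(variant_ids, colnames(genotypes$dosage))
  if (length(missing) > 0) {
    stop("weights reference variant(s) absent from genotypes: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  x <- genotypes$dosage[, variant_ids, drop = FALSE]
  if (any(flip)) {
    x[, flip] <- 2 - x[, flip, drop = FALSE]
  }
  cm <- colMeans(x, na.rm = TRUE)
  cm[is.nan(cm)] <- 0                      # SNP entirely missing
  na_idx <- which(is.na(x), arr.ind = TRUE)
  if (nrow(na_idx) > 0) x[na_idx] <- cm[na_idx[, 2]]
  x
}

#' Compute a regional ePRS
#'
#' Each individual's score is the dosage-weighted sum over the region's
#' clumped SNP set: `score_i = sum_j dosage_ij * weight_j`, where the
#' dosage counts the eQTL effect allele (flip-flagged variants contribute
#' via `2 - dosage`) and missing dosages are replaced by the SNP's cohort
#' mean dosage.
#'
#' @param genotypes A `"coex_genotypes"` object.
#' @param weights A [snp_weights()] data frame.
#' @param region Optional region label; when given, only that region's
#'   weights are used.
#' @return Named numeric vector of scores (names = individual ids) with
#'   attribute `n_snps`.
#' @export
compute_region_score <- function(genotypes, weights, region = NULL) {
  weights <- as.data.frame(weights)
  if (!is.null(region)) weights <- weights[weights$region == region, , drop = FALSE]
  if (anyDuplicated(weights$variant_id)) {
    stop("duplicate variant ids in weights; deduplicate per region first",
         call. = FALSE)
  }
  x <- .oriented_imputed_dosage(genotypes, weights$variant_id, weights$flip)
  score <- drop(x %*% weights$weight)
  names(score) <- rownames(genotypes$dosage)
  attr(score, "n_snps") <- nrow(weights)
  score
}

#' Combine two regional scores into the corticolimbic score
#'
#' The combined score is the exact elementwise sum of the two regional
#' scores (no standardization, no SNP-count scaling), after aligning
#' individuals by id.
#'
#' @param score_a,score_b Named numeric vectors over the same individuals.
#' @return Named numeric vector of sums in the order of `score_a`.
#' @export
combine_regions <- function(score_a, score_b) {
  if (is.null(names(score_a)) || is.null(names(score_b))) {
    if (length(score_a) != length(score_b)) {
      stop("unnamed scores of different lengths cannot be aligned", call. = FALSE)
    }
    return(as.numeric(score_a) + as.numeric(score_b))
  }
  if (!setequal(names(score_a), names(score_b))) {
    stop("individual sets differ between the two regional scores", call. = FALSE)
  }
  out <- as.numeric(score_a) + as.numeric(score_b[names(score_a)])
  names(out) <- names(score_a)
  out
}

#' Assemble the per-individual score table
#'
#' @param region_scores Named list of regional score vectors (as from
#'   [compute_region_score()]), e.g. `list(PFC = ..., NAcc = ...)`.
#' @return Data frame with `individual_id`, one `score_<region>` column per
#'   region, `score_combined` (their sum), and `n_snps_<region>` counts.
#' @export
build_score_table <- function(region_scores) {
  stopifnot(is.list(region_scores), length(region_scores) >= 1,
            !is.null(names(region_scores)))
  ids <- names(region_scores[[1]])
  out <- data.frame(individual_id = ids, stringsAsFactors = FALSE)
  combined <- rep(0, length(ids))
  for (reg in names(region_scores)) {
    s <- region_scores[[reg]]
    if (!setequal(names(s), ids)) {
      stop("individual sets differ across regions", call. = FALSE)
    }
    s <- s[ids]
    out[[paste0("score_", tolower(reg))]] <- as.numeric(s)
    combined <- combined + as.numeric(s)
  }
  out$score_combined <- combined
  for (reg in names(region_scores)) {
    out[[paste0("n_snps_", tolower(reg))]] <-
      attr(region_scores[[reg]], "n_snps") %||% NA_integer_
  }
  out
}

#' Conventional GWAS-threshold polygenic score
#'
#' Comparator score: SNPs are selected from GWAS summary statistics either
#' by nominal p-value below a threshold or as the top `top_k` by ascending
#' p-value, harmonized to the cohort's alleles, and summed as
#' `dosage x GWAS beta` with the same missing-dosage mean imputation as the
#' ePRS.
#'
#' @param genotypes A `"coex_genotypes"` object.
#' @param gwas Data frame with `variant_id`, `effect_allele`,
#'   `other_allele`, `beta`, `p`.
#' @param p_threshold Select SNPs with `p < p_threshold` (ignored when
#'   `top_k` is given).
#' @param top_k Select exactly the `top_k` most significant SNPs (ties by
#'   variant id); `NULL` to use the threshold.
#' @param drop_ambiguous Drop strand-ambiguous SNPs during harmonization.
#' @return Named numeric score vector with attributes `n_selected` (SNPs
#'   passing selection) and `n_scored` (SNPs remaining after
#'   harmonization).
#' @export
compute_conventional_prs <- function(genotypes, gwas, p_threshold = 4.912e-5,
                                     top_k = NULL, drop_ambiguous = TRUE) {
  gwas <- as.data.frame(gwas)
  stopifnot(all(c("variant_id", "effect_allele", "other_allele", "beta", "p") %in%
                  names(gwas)))
  if (is.null(top_k) && is.null(p_threshold)) {
    stop("either `p_threshold` or `top_k` must be given", call. = FALSE)
  }
  if (!is.null(top_k)) {
    .assert_scalar_number(top_k, "top_k", 1)
    sel <- gwas[order(gwas$p, gwas$variant_id), , drop = FALSE]
    sel <- utils::head(sel, top_k)
  } else {
    .assert_scalar_number(p_threshold, "p_threshold", 0, 1)
    sel <- gwas[gwas$p < p_threshold, , drop = FALSE]
  }
  n_selected <- nrow(sel)
  harm <- harmonize_alleles(sel, genotypes$variants,
                            drop_ambiguous = drop_ambiguous)
  kept <- harm$pairs
  if (nrow(kept) == 0) {
    score <- rep(0, nrow(genotypes$dosage))
    names(score) <- rownames(genotypes$dosage)
  } else {
    x <- .oriented_imputed_dosage(genotypes, kept$variant_id, kept$flip)
    score <- drop(x %*% kept$beta)
    names(score) <- rownames(genotypes$dosage)
  }
  attr(score, "n_selected") <- n_selected
  attr(score, "n_scored") <- nrow(kept)
  score
}
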