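# Assembly of the SNP set behind each regional score: cis eQTL pairs for
# network genes, allele harmonization against the cohort, per-variant
# deduplication, and greedy LD clumping.

#' Collect cis gene-SNP pairs for the network genes
#'
#' Restricts an eQTL catalog to the genes of a co-expression network and
#' tags every record with its gene's network sign (the sign of the gene's
#' correlation with the anchor), which later orients the SNP weight.
#'
#' @param network A `"coex_network"` (or data frame with `gene_id`, `sign`).
#' @param catalog eQTL catalog data frame (`gene_id`, `variant_id`, `chrom`,
#'   `pos`, `effect_allele`, `other_allele`, `slope`, `pval_nominal`).
#' @param annotation Gene annotation (`gene_id`, `chrom`, `start`, `end`).
#'   Network genes absent from the annotation are excluded with a warning.
#' @return Data frame of catalog records for annotated network genes with an
#'   added `network_sign` column; attributes `excluded_genes` (unannotated)
#'   and `pairs_per_gene` (count table).
#' @export
collect_cis_pairs <- function(network, catalog, annotation) {
  network <- as.data.frame(network)
  catalog <- as.data.frame(catalog)
  annotation <- as.data.frame(annotation)
  stopifnot(all(c("gene_id", "sign") %in% names(network)),
            all(c("gene_id", "variant_id", "slope", "pval_nominal") %in%
                  names(catalog)))
  unannotated <- setdiff(network$gene_id, annotation$gene_id)
  if (length(unannotated) > 0) {
    warning(length(unannotated), " network gene(s) lack annotation and are excluded: ",
            paste(utils::head(unannotated, 5), collapse = ", "))
  }
  genes <- setdiff(network$gene_id, unannotated)
  out <- catalog[catalog$gene_id %in% genes, , drop = FALSE]
  out$network_sign <- network$sign[match(out$gene_id, network$gene_id)]
  rownames(out) <- NULL
  structure(out, excluded_genes = unannotated,
            pairs_per_gene = table(factor(out$gene_id, levels = genes)))
}

#' Harmonize eQTL alleles against cohort genotype alleles
#'
#' Matches each record's effect/other allele pair against the cohort's
#' counted/other allele pair. Records are kept with `flip = FALSE` when the
#' effect allele is the cohort's counted allele, kept with `flip = TRUE`
#' when the pair matches after swapping (the dosage then enters the score
#' as `2 - dosage`), resolved across strands for non-ambiguous pairs, and
#' dropped with a reason code otherwise. Strand-ambiguous pairs (A/T, C/G)
#' are dropped by default because their orientation cannot be inferred from
#' allele labels.
#'
#' @param pairs Data frame with `variant_id`, `effect_allele`,
#'   `other_allele` (plus any payload columns, kept).
#' @param variant_table Cohort variant table with `variant_id`, `allele1`
#'   (the allele counted by the dosage), `allele2`.
#' @param drop_ambiguous Drop strand-ambiguous pairs (default `TRUE`).
#' @return A list of class `"coex_harmonized"`: `pairs` (kept records with
#'   logical `flip` and `strand_flipped` columns) and `drops` (data frame
#'   `variant_id`, `reason` with reasons `absent_from_cohort`,
#'   `strand_ambiguous`, `allele_mismatch`).
#' @export
harmonize_alleles <- function(pairs, variant_table, drop_ambiguous = TRUE) {
  pairs <- as.data.frame(pairs)
  variant_table <- as.data.frame(variant_table)
  stopifnot(all(c("variant_id", "effect_allele", "other_allele") %in% names(pairs)),
            all(c("variant_id", "allele1", "allele2") %in% names(variant_table)))
  i <- match(pairs$variant_id, variant_table$variant_id)
  a1 <- variant_table$allele1[i]
  a2 <- variant_table$allele2[i]
  ea <- pairs$effect_allele
  oa <- pairs$other_allele
  reason <- rep(NA_character_, nrow(pairs))
  flip <- rep(FALSE, nrow(pairs))
  strand <- rep(FALSE, nrow(pairs))

  absent <- is.na(i)
  reason[absent] <- "absent_from_cohort"
  amb <- !absent & .is_strand_ambiguous(ea, oa)
  if (drop_ambiguous) reason[amb] <- "strand_ambiguous"

  open <- is.na(reason)
  same <- open & ea == a1 & oa == a2
  swap <- open & ea == a2 & oa == a1
  flip[swap] <- TRUE
  cs <- open & !same & !swap & .complement(ea) == a1 & .complement(oa) == a2
  cw <- open & !same & !swap & .complement(ea) == a2 & .complement(oa) == a1
  strand[cs | cw] <- TRUE
  flip[cw] <- TRUE
  reason[open & !(same | swap | cs | cw)] <- "allele_mismatch"

  kept <- is.na(reason)
  out <- pairs[kept, , drop = FALSE]
  out$flip <- flip[kept]
  out$strand_flipped <- strand[kept]
  rownames(out) <- NULL
  drops <- data.frame(variant_id = pairs$variant_id[!kept],
                      reason = reason[!kept], stringsAsFactors = FALSE)
  structure(list(pairs = out, drops = drops), class = "coex_harmonized")
}

#' @export
print.coex_harmonized <- function(x, ...) {
  cat(sprintf("coex_harmonized: %d kept (%d flipped), %d dropped\n",
              nrow(x$pairs), sum(x$pairs$flip), nrow(x$drops)))
  if (nrow(x$drops) > 0) print(table(x$drops$reason))
  invisible(x)
}

#' Resolve variants paired with several network genes
#'
#' A variant can be a cis-eQTL for more than one network gene but must
#' contribute to the regional score once. Within each region the record
#' with the smallest nominal eQTL p-value is kept; ties are broken by
#' larger `|slope|`, then lexicographic gene id.
#'
#' @param pairs Harmonized pairs data frame (`variant_id`, `gene_id`,
#'   `slope`, `pval_nominal`, ...).
#' @return The deduplicated data frame, one row per variant, with an
#'   attribute `duplicates_resolved` giving the number of dropped records.
#' @export
deduplicate_snp_gene <- function(pairs) {
  pairs <- as.data.frame(pairs)
  ord <- order(pairs$variant_id, pairs$pval_nominal, -abs(pairs$slope),
               pairs$gene_id)
  pairs <- pairs[ord, , drop = FALSE]
  keep <- !duplicated(pairs$variant_id)
  out <- pairs[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, duplicates_resolved = sum(!keep))
}

#' Greedy LD clumping of candidate SNPs
#'
#' Standard greedy clumping on the analysis cohort's own genotypes: SNPs
#' are ranked by ascending eQTL nominal p-value (ties: larger `|slope|`,
#' then variant id); each index SNP in turn is retained and all
#' still-unassigned SNPs within `window_kb` on the same chromosome whose
#' squared dosage correlation with it reaches `r2_max` are removed.
#' Monomorphic SNPs (zero dosage variance) are dropped before clumping.
#' After a run, no two retained SNPs within a window have `r^2 >= r2_max`
#' (assertable via [check_clump()]).
#'
#' @param pairs Data frame with `variant_id`, `chrom`, `pos`, `slope`,
#'   `pval_nominal` (payload columns kept).
#' @param genotypes A `"coex_genotypes"` object providing dosages for every
#'   variant in `pairs`.
#' @param r2_max Squared-correlation threshold; SNPs with `r^2 >= r2_max`
#'   to a retained index SNP are removed (default 0.2).
#' @param window_kb Clumping window in kb each side of the index SNP
#'   (default 250).
#' @return A list of class `"coex_clump"`: `retained` (pairs rows kept),
#'   `removed` (data frame `variant_id`, `index_snp`, `r2`), and
#'   `monomorphic` (variant ids dropped pre-clump).
#' @export
ld_clump <- function(pairs, genotypes, r2_max = 0.2, window_kb = 250) {
  .assert_scalar_number(r2_max, "r2_max", 0, 1)
  .assert_scalar_number(window_kb, "window_kb", 0)
  pairs <- as.data.frame(pairs)
  stopifnot(all(c("variant_id", "chrom", "pos", "slope", "pval_nominal") %in%
                  names(pairs)))
  missing <- setdiff(pairs$variant_id, colnames(genotypes$dosage))
  if (length(missing) > 0) {
    stop("no genotype dosages for variant(s): ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  dos <- genotypes$dosage[, pairs$variant_id, drop = FALSE]
  v <- apply(dos, 2, var, na.rm = TRUE)
  mono <- is.na(v) | v == 0
  mono_ids <- pairs$variant_id[mono]
  pairs <- pairs[!mono, , drop = FALSE]
  dos <- dos[, !mono, drop = FALSE]

  n <- nrow(pairs)
  ord <- order(pairs$pval_nominal, -abs(pairs$slope), pairs$variant_id)
  status <- rep(0L, n)                      # 0 pending, 1 retained, -1 removed
  removed <- vector("list", n)
  win <- window_kb * 1000
  for (i in ord) {
    if (status[i] != 0L) next
    status[i] <- 1L
    cand <- which(status == 0L & pairs$chrom == pairs$chrom[i] &
                    abs(pairs$pos - pairs$pos[i]) <= win)
    if (length(cand) == 0) next
    r2 <- suppressWarnings(
      cor(dos[, cand, drop = FALSE], dos[, i], use = "pairwise.complete.obs")[, 1])^2
    hit <- cand[!is.na(r2) & r2 >= r2_max]
    if (length(hit) > 0) {
      status[hit] <- -1L
      removed[[i]] <- data.frame(variant_id = pairs$variant_id[hit],
                                 index_snp = pairs$variant_id[i],
                                 r2 = r2[match(hit, cand)],
                                 stringsAsFactors = FALSE)
    }
  }
  retained <- pairs[status == 1L, , drop = FALSE]
  rownames(retained) <- NULL
  removed <- do.call(rbind, removed[!vapply(removed, is.null, logical(1))])
  if (is.null(removed)) {
    removed <- data.frame(variant_id = character(), index_snp = character(),
                          r2 = numeric(), stringsAsFactors = FALSE)
  }
  structure(list(retained = retained, removed = removed,
                 monomorphic = mono_ids, r2_max = r2_max,
                 window_kb = window_kb),
            class = "coex_clump")
}

#' @export
print.coex_clump <- function(x, ...) {
  cat(sprintf("coex_clump: %d retained, %d removed (r2 >= %g within %g kb), %d monomorphic\n",
              nrow(x$retained), nrow(x$removed), x$r2_max, x$window_kb,
              length(x$monomorphic)))
  invisible(x)
}

#' Verify the clumping post-condition exhaustively
#'
#' Checks every pair of retained SNPs within the clumping window and
#' reports the maximum squared dosage correlation found.
#'
#' @param retained Data frame of retained pairs (`variant_id`, `chrom`,
#'   `pos`).
#' @param genotypes A `"coex_genotypes"` object.
#' @inheritParams ld_clump
#' @return A list with `ok` (logical: no within-window pair reaches
#'   `r2_max`) and `max_r2` (the largest within-window r^2, `-Inf` when no
#'   pair falls within a window).
#' @export
check_clump <- function(retained, genotypes, r2_max = 0.2, window_kb = 250) {
  retained <- as.data.frame(retained)
  dos <- genotypes$dosage[, retained$variant_id, drop = FALSE]
  win <- window_kb * 1000
  max_r2 <- -Inf
  n <- nrow(retained)
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      j <- which(retained$chrom[(i + 1):n] == retained$chrom[i] &
                   abs(retained$pos[(i + 1):n] - retained$pos[i]) <= win) + i
      if (length(j) == 0) next
      r2 <- suppressWarnings(
        cor(dos[, j, drop = FALSE], dos[, i],
            use = "pairwise.complete.obs")[, 1])^2
      max_r2 <- max(max_r2, r2, na.rm = TRUE)
    }
  }
  list(ok = max_r2 < r2_max, max_r2 = max_r2)
}
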