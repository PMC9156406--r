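# Anchor-gene co-expression network construction: correlation filter,
# developmental enrichment filter, and the developmental co-expression
# stability analysis.

#' Correlate every gene with the anchor gene
#'
#' Computes, for each gene in the expression matrix, its correlation with
#' the anchor gene across the samples of one region.
#'
#' @param expr A `"coex_expression"` object (see [simulate_expression()]) or
#'   a list with `expr` (genes x samples matrix) and `samples` (data frame
#'   with `sample_id`, `region`, `stage`).
#' @param anchor Gene id of the anchor.
#' @param region Region label; only that region's samples are used.
#' @param method Correlation estimator, `"pearson"` (default) or
#'   `"spearman"`.
#' @return A `"coex_profile"` object: data frame `gene_id`, `r` for all
#'   genes with defined correlation, with attributes `anchor`, `region`,
#'   `excluded` (data frame of genes with undefined correlation, e.g.
#'   constant expression, with a reason).
#' @export
compute_coexpression <- function(expr, anchor, region,
                                 method = c("pearson", "spearman")) {
  method <- match.arg(method)
  mat <- expr$expr
  samples <- expr$samples
  keep <- samples$region == region
  if (sum(keep) < 3) stop("need >= 3 samples in region ", region, call. = FALSE)
  if (!anchor %in% rownames(mat)) {
    stop("anchor gene '", anchor, "' not found in expression matrix", call. = FALSE)
  }
  x <- t(mat[, keep, drop = FALSE])
  sds <- apply(x, 2, sd)
  if (sds[anchor] == 0) stop("anchor gene has constant expression", call. = FALSE)
  constant <- sds == 0
  r <- rep(NA_real_, ncol(x))
  names(r) <- colnames(x)
  r[!constant] <- suppressWarnings(
    cor(x[, !constant, drop = FALSE], x[, anchor], method = method)[, 1])
  out <- data.frame(gene_id = names(r)[!constant], r = unname(r[!constant]),
                    stringsAsFactors = FALSE)
  excluded <- data.frame(gene_id = names(r)[constant],
                         reason = rep("constant_expression", sum(constant)),
                         stringsAsFactors = FALSE)
  structure(out, anchor = anchor, region = region, method = method,
            excluded = excluded, class = c("coex_profile", "data.frame"))
}

#' Retain genes by absolute co-expression with the anchor
#'
#' A gene is retained iff `|r| >= min_abs_r` (boundary inclusive); each
#' retained gene carries the sign of its correlation, later used to orient
#' eQTL weights.
#'
#' @param profile A `"coex_profile"` from [compute_coexpression()].
#' @param min_abs_r Minimum absolute correlation (default 0.5).
#' @return Data frame `gene_id`, `r`, `sign` of the retained genes.
#' @export
apply_coexpression_filter <- function(profile, min_abs_r = 0.5) {
  .assert_scalar_number(min_abs_r, "min_abs_r", 0, 1)
  keep <- abs(profile$r) >= min_abs_r
  out <- data.frame(gene_id = profile$gene_id[keep], r = profile$r[keep],
                    stringsAsFactors = FALSE)
  out$sign <- ifelse(out$r >= 0, 1L, -1L)
  out
}

#' Developmental enrichment: early/adult expression fold-change filter
#'
#' For each candidate gene, the fold-change is mean(early expression)
#' divided by the adult mean floored at the pseudocount `eps`
#' (`mean_early / max(mean_adult, eps)`); a gene is retained iff the
#' fold-change is at least `min_fold` (boundary inclusive). The floor
#' guards against genes silent in adulthood without perturbing ordinary
#' fold-changes at the boundary.
#'
#' @param expr A `"coex_expression"`-like object with both early and adult
#'   samples.
#' @param candidates Character vector of gene ids, or a data frame with a
#'   `gene_id` column (e.g. the output of [apply_coexpression_filter()]).
#' @param min_fold Minimum early/adult fold-change (default 1.5).
#' @param eps Pseudocount floor for the adult mean (default 0.01
#'   expression units).
#' @return The enrichment table: data frame `gene_id`, `mean_early`,
#'   `mean_adult`, `fold_change`, `retained`.
#' @export
apply_developmental_filter <- function(expr, candidates, min_fold = 1.5,
                                       eps = 0.01) {
  .assert_scalar_number(min_fold, "min_fold", 0)
  genes <- if (is.data.frame(candidates)) candidates$gene_id else candidates
  stage <- expr$samples$stage
  if (!any(stage == "adult")) stop("no adult samples in expression matrix", call. = FALSE)
  if (!any(stage == "early")) stop("no early samples in expression matrix", call. = FALSE)
  missing <- setdiff(genes, rownames(expr$expr))
  if (length(missing) > 0) {
    stop("candidate gene(s) absent from expression matrix: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  m <- expr$expr[genes, , drop = FALSE]
  mean_early <- rowMeans(m[, stage == "early", drop = FALSE])
  mean_adult <- rowMeans(m[, stage == "adult", drop = FALSE])
  fold <- mean_early / pmax(mean_adult, eps)
  data.frame(gene_id = genes, mean_early = unname(mean_early),
             mean_adult = unname(mean_adult), fold_change = unname(fold),
             retained = unname(fold >= min_fold), stringsAsFactors = FALSE)
}

#' Build the anchor-gene co-expression network for one region
#'
#' Composes the two filters: genes correlated with the anchor at
#' `|r| >= min_abs_r` whose early/adult expression fold-change is at least
#' `min_fold`. The anchor itself is included with sign +1 by default.
#'
#' @inheritParams compute_coexpression
#' @inheritParams apply_coexpression_filter
#' @inheritParams apply_developmental_filter
#' @param include_anchor Include the anchor gene in its own network
#'   regardless of its fold-change (default `TRUE`).
#' @return A `"coex_network"` object: data frame `gene_id`, `r`, `sign`,
#'   `fold_change`, with attributes `anchor`, `region`, `min_abs_r`,
#'   `min_fold`. Emits a warning (not an error) when the network is empty.
#' @export
build_network <- function(expr, anchor, region, min_abs_r = 0.5,
                          min_fold = 1.5, include_anchor = TRUE, eps = 0.01,
                          method = c("pearson", "spearman")) {
  profile <- compute_coexpression(expr, anchor, region, method = method)
  cand <- apply_coexpression_filter(profile, min_abs_r)
  enrich <- apply_developmental_filter(expr, cand, min_fold, eps)
  keep <- enrich$retained
  net <- data.frame(gene_id = cand$gene_id[keep], r = cand$r[keep],
                    sign = cand$sign[keep],
                    fold_change = enrich$fold_change[keep],
                    stringsAsFactors = FALSE)
  if (include_anchor && !anchor %in% net$gene_id) {
    fc <- enrich$fold_change[match(anchor, enrich$gene_id)]
    if (is.na(fc)) {
      e <- apply_developmental_filter(expr, anchor, min_fold, eps)
      fc <- e$fold_change
    }
    net <- rbind(data.frame(gene_id = anchor, r = 1, sign = 1L,
                            fold_change = fc, stringsAsFactors = FALSE), net)
  } else if (!include_anchor) {
    net <- net[net$gene_id != anchor, , drop = FALSE]
  }
  rownames(net) <- NULL
  if (nrow(net) == 0) {
    warning("co-expression network for region ", region, " is empty")
  }
  structure(net, anchor = anchor, region = region, min_abs_r = min_abs_r,
            min_fold = min_fold, enrichment = enrich,
            class = c("coex_network", "data.frame"))
}

#' @export
print.coex_network <- function(x, ...) {
  cat(sprintf("coex_network: %d genes (region %s, anchor %s, |r| >= %g, fold >= %g)\n",
              nrow(x), attr(x, "region"), attr(x, "anchor"),
              attr(x, "min_abs_r"), attr(x, "min_fold")))
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("...\n")
  invisible(x)
}

#' Developmental stability of network co-expression
#'
#' Compares the gene-gene co-expression of the network between childhood
#' and adulthood. Genes are ordered by hierarchical clustering of the
#' childhood correlation matrix (average linkage on distance 1 - r by
#' default); the adulthood matrix is reported in the SAME childhood leaf
#' order so preserved clusters are visually and numerically comparable.
#' For each childhood-defined cluster the preservation statistic is the
#' mean off-diagonal within-cluster correlation recomputed in adulthood.
#'
#' @param expr_child,expr_adult `"coex_expression"`-like objects over the
#'   same gene set (samples may differ).
#' @param network A `"coex_network"` or character vector of gene ids.
#' @param linkage Hierarchical clustering linkage (default `"average"`).
#' @param cut_height Dendrogram cut height on the 1 - r scale defining
#'   clusters (default 0.5, i.e. mean within-cluster r above 0.5).
#' @param method Correlation estimator.
#' @return A `"coex_stability"` list: `cor_child` and `cor_adult` (both in
#'   childhood leaf order), `order` (gene ids in leaf order), `clusters`
#'   (data frame `gene_id`, `cluster`), and `preservation` (data frame
#'   `cluster`, `n_genes`, `child_mean_r`, `adult_mean_r`; singleton
#'   clusters have `NA` means).
#' @export
coexpression_stability <- function(expr_child, expr_adult, network,
                                   linkage = "average", cut_height = 0.5,
                                   method = c("pearson", "spearman")) {
  method <- match.arg(method)
  genes <- if (is.data.frame(network)) network$gene_id else network
  for (nm in list(child = expr_child, adult = expr_adult)) {
    if (!all(genes %in% rownames(nm$expr))) {
      stop("network genes missing from one of the expression matrices", call. = FALSE)
    }
  }
  cc <- cor(t(expr_child$expr[genes, , drop = FALSE]), method = method)
  ca <- cor(t(expr_adult$expr[genes, , drop = FALSE]), method = method)
  hc <- hclust(as.dist(1 - cc), method = linkage)
  ord <- genes[hc$order]
  clusters <- cutree(hc, h = cut_height)
  mean_offdiag <- function(m) {
    if (nrow(m) < 2) return(NA_real_)
    mean(m[upper.tri(m)])
  }
  pres <- do.call(rbind, lapply(sort(unique(clusters)), function(k) {
    g <- genes[clusters == k]
    data.frame(cluster = k, n_genes = length(g),
               child_mean_r = mean_offdiag(cc[g, g, drop = FALSE]),
               adult_mean_r = mean_offdiag(ca[g, g, drop = FALSE]))
  }))
  structure(list(cor_child = cc[ord, ord], cor_adult = ca[ord, ord],
                 order = ord,
                 clusters = data.frame(gene_id = genes,
                                       cluster = unname(clusters),
                                       stringsAsFactors = FALSE),
                 preservation = pres,
                 linkage = linkage, cut_height = cut_height),
            class = "coex_stability")
}

#' Plot childhood/adulthood co-expression heatmaps side by side
#'
#' @param x A `"coex_stability"` object.
#' @param ... Passed to [graphics::image()].
#' @export
plot.coex_stability <- function(x, ...) {
  op <- par(mfrow = c(1, 2), mar = c(1, 1, 2, 1))
  on.exit(par(op))
  pal <- grDevices::hcl.colors(64, "RdBu", rev = TRUE)
  n <- nrow(x$cor_child)
  image(seq_len(n), seq_len(n), x$cor_child[, n:1], col = pal,
        zlim = c(-1, 1), axes = FALSE, xlab = "", ylab = "",
        main = "childhood", ...)
  image(seq_len(n), seq_len(n), x$cor_adult[, n:1], col = pal,
        zlim = c(-1, 1), axes = FALSE, xlab = "", ylab = "",
        main = "adulthood (childhood order)", ...)
  invisible(x)
}
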