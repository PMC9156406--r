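# Independent brute-force oracles: written as explicit elementwise loops so
# they share no code path with the vectorized implementations they check.

# Pearson correlation from the textbook formula.
oracle_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  num <- 0
  dx <- 0
  dy <- 0
  for (i in seq_len(n)) {
    num <- num + (x[i] - mx) * (y[i] - my)
    dx <- dx + (x[i] - mx)^2
    dy <- dy + (y[i] - my)^2
  }
  num / sqrt(dx * dy)
}

# Network construction by explicit threshold loops over a genes x samples
# matrix with a stage vector.
oracle_network <- function(mat, stage, anchor, min_abs_r, min_fold,
                           eps = 0.01, include_anchor = TRUE) {
  genes <- rownames(mat)
  out <- character()
  for (g in genes) {
    r <- oracle_pearson(mat[g, ], mat[anchor, ])
    if (is.na(r) || abs(r) < min_abs_r) next
    fold <- mean(mat[g, stage == "early"]) /
      max(mean(mat[g, stage == "adult"]), eps)
    if (fold >= min_fold) out <- c(out, g)
  }
  if (include_anchor && !anchor %in% out) out <- c(anchor, out)
  sort(out)
}

# Score by an explicit double loop with per-SNP mean imputation and
# flip-aware orientation.
oracle_score <- function(dosage, weights) {
  n <- nrow(dosage)
  score <- numeric(n)
  for (j in seq_len(nrow(weights))) {
    d <- dosage[, weights$variant_id[j]]
    if (weights$flip[j]) d <- 2 - d
    m <- mean(d, na.rm = TRUE)
    for (i in seq_len(n)) {
      dij <- if (is.na(d[i])) m else d[i]
      score[i] <- score[i] + dij * weights$weight[j]
    }
  }
  names(score) <- rownames(dosage)
  score
}

# Greedy clumping re-derived with scalar loops: rank by (p, -|slope|, id),
# retain each surviving index, knock out in-window correlates.
oracle_clump <- function(pairs, dosage, r2_max, window_kb) {
  ord <- order(pairs$pval_nominal, -abs(pairs$slope), pairs$variant_id)
  state <- rep("pending", nrow(pairs))
  for (i in ord) {
    if (state[i] != "pending") next
    state[i] <- "retained"
    for (j in seq_len(nrow(pairs))) {
      if (state[j] != "pending") next
      if (pairs$chrom[j] != pairs$chrom[i]) next
      if (abs(pairs$pos[j] - pairs$pos[i]) > window_kb * 1000) next
      r <- suppressWarnings(cor(dosage[, pairs$variant_id[i]],
                                dosage[, pairs$variant_id[j]],
                                use = "pairwise.complete.obs"))
      if (!is.na(r) && r^2 >= r2_max) state[j] <- "removed"
    }
  }
  pairs$variant_id[state == "retained"]
}

# Two-variable OLS (outcome ~ score + one covariate) in closed form via
# normal equations.
oracle_ols2 <- function(y, x1, x2) {
  X <- cbind(1, x1, x2)
  unname(solve(t(X) %*% X, t(X) %*% y)[2, 1])
}

# Small hand-built expression container.
make_expr <- function(mat, stage, region = "PFC") {
  colnames(mat) <- sprintf("s%02d", seq_len(ncol(mat)))
  structure(list(expr = mat,
                 samples = data.frame(sample_id = colnames(mat),
                                      region = region, stage = stage,
                                      stringsAsFactors = FALSE)),
            class = "coex_expression")
}

# Small genotype container from a dosage matrix (one chromosome, 1 kb
# spacing unless positions are given).
make_geno <- function(dosage, chrom = NULL, pos = NULL,
                      a1 = NULL, a2 = NULL) {
  m <- ncol(dosage)
  if (is.null(colnames(dosage))) colnames(dosage) <- sprintf("v%03d", 1:m)
  if (is.null(rownames(dosage))) rownames(dosage) <- sprintf("i%03d", seq_len(nrow(dosage)))
  genotype_matrix(dosage, data.frame(
    variant_id = colnames(dosage),
    chrom = chrom %||% rep("1", m),
    pos = pos %||% (seq_len(m) * 1000),
    allele1 = a1 %||% rep("A", m),
    allele2 = a2 %||% rep("G", m),
    stringsAsFactors = FALSE))
}

`%||%` <- function(x, y) if (is.null(x)) y else x
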