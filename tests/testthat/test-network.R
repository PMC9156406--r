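# Network construction: correlation filter, developmental filter, brute
# force equivalence, monotonicity, and developmental stability.

test_that("anchor correlations match the direct Pearson formula on toys", {
  anchor <- c(1, 2, 3, 4, 5)
  mat <- rbind(anchor = anchor,
               double = c(2, 4, 6, 8, 10),
               reversed = c(5, 4, 3, 2, 1),
               bump = c(1, 1, 2, 1, 1))
  e <- make_expr(mat, stage = rep(c("early", "adult"), c(3, 2)))
  prof <- compute_coexpression(e, "anchor", "PFC")
  r <- setNames(prof$r, prof$gene_id)
  expect_equal(unname(r["double"]), 1)
  expect_equal(unname(r["reversed"]), -1)
  expect_equal(unname(r["bump"]), oracle_pearson(mat["bump", ], anchor))
})

test_that("constant-expression genes are excluded with a reason", {
  mat <- rbind(anchor = c(1, 2, 3, 4), flat = c(2, 2, 2, 2))
  e <- make_expr(mat, stage = rep(c("early", "adult"), each = 2))
  prof <- compute_coexpression(e, "anchor", "PFC")
  expect_false("flat" %in% prof$gene_id)
  exc <- attr(prof, "excluded")
  expect_equal(exc$gene_id, "flat")
  expect_equal(exc$reason, "constant_expression")
  expect_error(compute_coexpression(e, "nope", "PFC"), "not found")
})

test_that("correlation filter boundary is inclusive and signs are kept", {
  prof <- data.frame(gene_id = c("a", "b", "c", "d"),
                     r = c(0.50, -0.50, 0.499, 0.9))
  out <- apply_coexpression_filter(prof, min_abs_r = 0.5)
  expect_setequal(out$gene_id, c("a", "b", "d"))
  expect_equal(out$sign[out$gene_id == "a"], 1L)
  expect_equal(out$sign[out$gene_id == "b"], -1L)
})

test_that("developmental filter boundary, exclusion and zero-adult floor", {
  # means: early 3.0/2.9/1.0, adult 2.0/2.0/0.0
  mat <- rbind(a = c(3, 3, 2, 2), b = c(2.9, 2.9, 2, 2), c = c(1, 1, 0, 0))
  e <- make_expr(mat, stage = rep(c("early", "adult"), each = 2))
  enr <- apply_developmental_filter(e, c("a", "b", "c"), min_fold = 1.5,
                                    eps = 0.01)
  expect_equal(enr$fold_change, c(1.5, 1.45, 100))
  expect_equal(enr$retained, c(TRUE, FALSE, TRUE))
  e_no_adult <- make_expr(mat, stage = rep("early", 4))
  expect_error(apply_developmental_filter(e_no_adult, "a"), "adult")
})

test_that("build_network matches a brute-force reimplementation", {
  for (seed in c(101, 202, 303)) {
    set.seed(seed)
    n_genes <- 20
    n_samp <- 20
    mat <- matrix(exp(rnorm(n_genes * n_samp, sd = 0.6)), n_genes, n_samp,
                  dimnames = list(sprintf("g%02d", 1:n_genes), NULL))
    mat[1, ] <- mat[1, ] * (1 + 0.5 * seq_len(n_samp))   # spread the anchor
    stage <- rep(c("early", "adult"), each = n_samp / 2)
    e <- make_expr(mat, stage)
    for (thr in list(c(0.3, 1.2), c(0.5, 1.5))) {
      net <- suppressWarnings(
        build_network(e, "g01", "PFC", min_abs_r = thr[1], min_fold = thr[2]))
      expect_identical(sort(net$gene_id),
                       oracle_network(mat, stage, "g01", thr[1], thr[2]))
    }
  }
})

test_that("stored network signs equal the signs of recomputed correlations", {
  set.seed(5)
  mat <- matrix(exp(rnorm(15 * 12, sd = 0.5)), 15, 12,
                dimnames = list(sprintf("g%02d", 1:15), NULL))
  e <- make_expr(mat, rep(c("early", "adult"), each = 6))
  net <- suppressWarnings(build_network(e, "g01", "PFC", min_abs_r = 0.2,
                                        min_fold = 0))
  prof <- compute_coexpression(e, "g01", "PFC")
  for (i in seq_len(nrow(net))) {
    r <- prof$r[prof$gene_id == net$gene_id[i]]
    expect_equal(net$sign[i], ifelse(r >= 0, 1L, -1L))
  }
})

test_that("raising either threshold never adds a gene", {
  set.seed(8)
  mat <- matrix(exp(rnorm(18 * 16, sd = 0.5)), 18, 16,
                dimnames = list(sprintf("g%02d", 1:18), NULL))
  e <- make_expr(mat, rep(c("early", "adult"), each = 8))
  genes_at <- function(r, f) {
    suppressWarnings(build_network(e, "g01", "PFC", min_abs_r = r,
                                   min_fold = f))$gene_id
  }
  for (r in c(0.1, 0.3, 0.5)) {
    for (f in c(0.8, 1.0, 1.5)) {
      base <- genes_at(r, f)
      expect_true(all(genes_at(r + 0.2, f) %in% base))
      expect_true(all(genes_at(r, f + 0.5) %in% base))
    }
  }
})

test_that("networks planted to the published sizes are recovered exactly", {
  st <- simulate_study(n_individuals = 50, n_network = c(154, 72),
                       n_null = 40, snps_per_gene = 2,
                       n_samples_early = 60, n_samples_adult = 60, seed = 21)
  net_pfc <- build_network(st$regions$PFC$expression, st$regions$PFC$anchor,
                           "PFC")
  net_nacc <- build_network(st$regions$NAcc$expression,
                            st$regions$NAcc$anchor, "NAcc")
  expect_equal(nrow(net_pfc), 154)
  expect_equal(nrow(net_nacc), 72)
})

test_that("a null anchor yields only the anchor (or nothing) as configured", {
  spec <- expression_sim_spec(10, 1, c(1, rep(0, 9)), rep(1, 10), 30, 30,
                              seed = 4)
  e <- simulate_expression(spec)
  net <- build_network(e, e$anchor_gene, "PFC")
  expect_equal(net$gene_id, e$anchor_gene)
  expect_warning(
    net0 <- build_network(e, e$anchor_gene, "PFC", include_anchor = FALSE),
    "empty")
  expect_equal(nrow(net0), 0)
})

test_that("stability analysis preserves childhood order and detects decay", {
  # two planted clusters in childhood; only cluster 1 persists in adulthood
  set.seed(31)
  n <- 40
  f1 <- rnorm(n)
  f2 <- rnorm(n)
  child <- rbind(
    g1 = f1 + rnorm(n, sd = 0.3), g2 = f1 + rnorm(n, sd = 0.3),
    g3 = f1 + rnorm(n, sd = 0.3), g4 = f2 + rnorm(n, sd = 0.3),
    g5 = f2 + rnorm(n, sd = 0.3), g6 = f2 + rnorm(n, sd = 0.3))
  h1 <- rnorm(n)
  adult <- rbind(
    g1 = h1 + rnorm(n, sd = 0.3), g2 = h1 + rnorm(n, sd = 0.3),
    g3 = h1 + rnorm(n, sd = 0.3),
    g4 = rnorm(n), g5 = rnorm(n), g6 = rnorm(n))
  ec <- make_expr(child, rep("early", n))
  ea <- make_expr(adult, rep("adult", n))
  st <- coexpression_stability(ec, ea, sprintf("g%d", 1:6), cut_height = 0.5)

  expect_identical(colnames(st$cor_adult), st$order)       # same order
  expect_identical(colnames(st$cor_child), colnames(st$cor_adult))

  pres <- st$preservation
  k1 <- st$clusters$cluster[st$clusters$gene_id == "g1"]
  k2 <- st$clusters$cluster[st$clusters$gene_id == "g4"]
  expect_gt(pres$adult_mean_r[pres$cluster == k1],
            pres$adult_mean_r[pres$cluster == k2])

  # identity case: adulthood statistic equals the childhood one exactly
  stid <- coexpression_stability(ec, ec, sprintf("g%d", 1:6))
  expect_equal(stid$preservation$adult_mean_r,
               stid$preservation$child_mean_r)
  expect_error(coexpression_stability(ec, ea, c("g1", "missing")), "missing")
})

test_that("independent adult noise drives preservation toward zero", {
  set.seed(77)
  n <- 2000
  f <- rnorm(n)
  child <- rbind(a = f + rnorm(n, sd = 0.4), b = f + rnorm(n, sd = 0.4),
                 c = f + rnorm(n, sd = 0.4))
  adult <- rbind(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  st <- coexpression_stability(make_expr(child, rep("early", n)),
                               make_expr(adult, rep("adult", n)),
                               c("a", "b", "c"), cut_height = 0.9)
  big <- st$preservation[which.max(st$preservation$n_genes), ]
  expect_gt(big$child_mean_r, 0.7)
  expect_lt(abs(big$adult_mean_r), 3 / sqrt(n))
})
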