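test_that("log-normalization conserves the scale factor and handles edge cases", {
  counts <- matrix(c(7L, 0L, 0L, 3L, 0L, 2L), 3, 2,
                   dimnames = list(c("gA", "gB", "gC"), c("c1", "c2")))
  em <- expression_matrix(counts, "counts")
  ln <- log_normalize(em)
  # a cell expressing a single gene maps that gene to the full scale factor
  expect_equal(expm1(unclass(ln)["gA", "c1"]), 1e4)
  # all-zero gene stays zero
  expect_true(all(unclass(ln)["gB", ] == 0))
  # hand-computed values on the toy
  expected <- log1p(sweep(counts, 2, colSums(counts), "/") * 1e4)
  expect_equal(unclass(ln), expected, tolerance = 1e-12,
               ignore_attr = TRUE)
  # column totals of de-logged values equal the scale factor
  expect_equal(unname(colSums(expm1(unclass(ln)))), c(1e4, 1e4))

  bad <- expression_matrix(
    matrix(c(1L, 2L, 0L, 0L), 2, 2,
           dimnames = list(c("g1", "g2"), c("ok", "empty"))), "counts")
  expect_error(log_normalize(bad), "empty")
})

test_that("wilcoxon rank-sum matches exact enumeration and the normal approximation", {
  # exact branch: all 20 rank assignments of {1,2,3} vs {4,5,6}
  r <- wilcoxon_rank_sum(1:3, 4:6)
  expect_equal(r$p, 0.1)
  expect_equal(r$statistic, 0)

  # enumeration oracle for random small samples without ties
  withr::with_seed(1, {
    for (i in 1:5) {
      x <- sample(1:50, 4); y <- sample(51:100, 5)
      pool <- c(x, y)
      combos <- combn(9, 4)
      u_obs <- sum(rank(pool)[1:4]) - 10
      u_all <- apply(combos, 2, function(ix) sum(rank(pool)[ix]) - 10)
      p_exact <- if (u_obs > 10) 2 * mean(u_all >= u_obs) else 2 * mean(u_all <= u_obs)
      expect_equal(wilcoxon_rank_sum(x, y)$p, min(1, p_exact))
    }
  })

  # identical multisets give p = 1
  expect_equal(wilcoxon_rank_sum(c(1, 2, 2, 3), c(1, 2, 2, 3))$p, 1,
               tolerance = 0.05)
  expect_equal(wilcoxon_rank_sum(rep(2, 5), rep(2, 4))$p, 1)

  # approximate branch agrees with stats::wilcox.test (ties, correction)
  withr::with_seed(2, {
    x <- round(rnorm(15, 0, 2)); y <- round(rnorm(18, 0.5, 2))
    ref <- suppressWarnings(wilcox.test(x, y, exact = FALSE, correct = TRUE))
    got <- wilcoxon_rank_sum(x, y)
    expect_equal(got$p, ref$p.value, tolerance = 1e-10)
    expect_equal(got$statistic, unname(ref$statistic))
  })

  # exact and approximate p agree within 0.03 for small untied samples
  withr::with_seed(3, {
    for (i in 1:10) {
      x <- runif(5); y <- runif(6)
      exact <- wilcoxon_rank_sum(x, y)$p
      approx <- suppressWarnings(
        wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value)
      expect_lt(abs(exact - approx), 0.03)
    }
  })

  # permutation invariance within groups
  x <- c(3, 1, 4, 1, 5); y <- c(9, 2, 6)
  expect_identical(wilcoxon_rank_sum(x, y), wilcoxon_rank_sum(rev(x), sample(y)))
})

test_that("average log2 fold change follows the de-log / pseudocount convention", {
  # group1 de-logged mean 3, group2 mean 0 -> log2(4/1) = 2
  v <- toy_lognorm(matrix(c(log1p(3), log1p(3), 0, 0), 1, 4))
  expect_equal(unname(avg_log2fc(v, c("s1", "s2"), c("s3", "s4"))), 2)

  # two groups with identical expression give 0 for every gene
  base <- matrix(runif(6), 3, 2)
  m <- toy_lognorm(cbind(base, base))
  expect_equal(unname(avg_log2fc(m, c("s1", "s2"), c("s3", "s4"))),
               rep(0, 3))

  # independent one-liner oracle on a random 20-gene toy
  withr::with_seed(4, {
    x <- toy_lognorm(matrix(abs(rnorm(20 * 8)), 20, 8))
    g1 <- paste0("s", 1:4); g2 <- paste0("s", 5:8)
    oracle <- log2((rowMeans(exp(unclass(x)[, g1]) - 1) + 1) /
                   (rowMeans(exp(unclass(x)[, g2]) - 1) + 1))
    expect_equal(avg_log2fc(x, g1, g2), oracle, tolerance = 1e-10)
  })
  expect_error(avg_log2fc(m, character(), "s1"), "non-empty")
  expect_error(avg_log2fc(m, "s1", "s1"), "disjoint")
})

test_that("marker symmetry: swapping groups negates log2FC and swaps pct", {
  ln <- fixture_lognorm()
  cells <- colnames(ln)
  g1 <- cells[1:40]; g2 <- cells[41:100]
  a <- find_markers(ln, g1, g2, min_pct = 0, logfc_threshold = 0)
  b <- find_markers(ln, g2, g1, min_pct = 0, logfc_threshold = 0)
  b <- b[match(a$gene, b$gene), ]
  expect_equal(a$avg_log2FC, -b$avg_log2FC)
  expect_equal(a$pct_1, b$pct_2)
  expect_equal(a$p, b$p)
})

test_that("marker detection applies filters and recovers planted markers", {
  sc <- fixture_sc()
  ln <- fixture_lognorm()
  meta <- sc$cell_meta
  res_cells <- meta$cell_id[meta$subcluster_id == "SC1"]
  rest <- setdiff(meta$cell_id, res_cells)
  rec <- find_markers(ln, res_cells, rest)
  planted <- sc$truth$planted_genes$resistance
  hits <- rec$gene[rec$p_adj < 0.05 & rec$avg_log2FC > 0]
  expect_gte(mean(planted %in% hits), 0.9)

  # a gene expressed in 5% of cells in both groups is filtered at min_pct 0.1
  n1 <- 40; n2 <- 40
  x <- matrix(0, 2, n1 + n2,
              dimnames = list(c("rare", "common"),
                              sprintf("c%02d", 1:(n1 + n2))))
  x["rare", c(1:2, n1 + (1:2))] <- 3      # 5% detection in each group
  x["common", ] <- rnorm(n1 + n2, 2)
  em <- toy_lognorm(x)
  rec2 <- suppressWarnings(
    find_markers(em, colnames(x)[1:n1], colnames(x)[n1 + 1:n2],
                 min_pct = 0.1, logfc_threshold = 0))
  expect_false("rare" %in% rec2$gene)

  # no genes passing -> empty result with warning
  expect_warning(
    out <- find_markers(em, colnames(x)[1:n1], colnames(x)[n1 + 1:n2],
                        min_pct = 0.99, logfc_threshold = 10),
    "no genes")
  expect_equal(nrow(out), 0)
})

test_that("p_adj is valid and BH-monotone", {
  ln <- fixture_lognorm()
  cells <- colnames(ln)
  rec <- find_markers(ln, cells[1:50], cells[51:120], min_pct = 0,
                      logfc_threshold = 0, adjust = "BH")
  expect_true(all(rec$p_adj >= rec$p - 1e-12))
  ord <- order(rec$p)
  expect_true(all(diff(rec$p_adj[ord]) >= -1e-12))
})

test_that("one-vs-rest markers reduce to pairwise contrasts and respect labels", {
  ln <- fixture_lognorm()
  cells <- colnames(ln)
  labs <- setNames(rep(c("A", "B"), length.out = length(cells)), cells)
  all_m <- find_all_markers(ln, labs, only_positive = FALSE)
  direct <- find_markers(ln, cells[labs == "A"], cells[labs == "B"])
  expect_equal(all_m$A$gene, direct$gene)
  expect_equal(all_m$A$p, direct$p)

  # permuting the label names permutes the outputs consistently
  labs2 <- setNames(ifelse(labs == "A", "B", "A"), cells)
  all_m2 <- find_all_markers(ln, labs2, only_positive = FALSE)
  expect_equal(all_m$A$gene, all_m2$B$gene)
  expect_error(find_all_markers(ln, setNames(rep("A", length(cells)), cells)),
               "2 clusters")
})

test_that("disjoint planted cluster markers dominate the per-cluster top 10", {
  # three balanced clusters with disjoint boosted marker blocks
  withr::with_seed(8, {
    n_genes <- 60; per <- 30
    counts <- matrix(rnbinom(n_genes * 3 * per, size = 2, mu = 2),
                     n_genes, 3 * per,
                     dimnames = list(sprintf("g%02d", 1:n_genes),
                                     sprintf("c%02d", 1:(3 * per))))
    labs <- rep(c("K1", "K2", "K3"), each = per)
    blocks <- list(K1 = 1:10, K2 = 11:20, K3 = 21:30)
    for (k in names(blocks)) {
      idx <- blocks[[k]]
      counts[idx, labs == k] <-
        rnbinom(length(idx) * per, size = 2, mu = 20)
    }
    em <- expression_matrix(counts, "counts")
    ln <- log_normalize(em)
    res <- find_all_markers(ln, setNames(labs, colnames(counts)))
    for (k in names(blocks)) {
      top10 <- head(res[[k]][order(res[[k]]$p_adj, res[[k]]$gene), "gene"], 10)
      expect_true(all(top10 %in% rownames(counts)[blocks[[k]]]))
    }
  })
})

test_that("ranking and truncation follow the key, tie rule and cap", {
  rec <- data.frame(gene = c("gB", "gA", "gC", "gD"),
                    avg_log2FC = c(1.5, -1.5, 0.7, 0.2),
                    pct_1 = 0.5, pct_2 = 0.1,
                    p = c(0.01, 0.01, 0.2, 0.5),
                    p_adj = c(0.04, 0.04, 0.4, 0.9),
                    stringsAsFactors = FALSE)
  dl <- rank_and_truncate(rec, "abs_log2fc_desc", id = "toy")
  # equal |log2FC| broken lexicographically by gene id
  expect_equal(dl$records$gene, c("gA", "gB", "gC", "gD"))
  # fewer records than the cap: all retained
  expect_equal(nrow(dl$records), 4)

  dl2 <- rank_and_truncate(rec, "padj_asc", max_n = 2)
  expect_equal(dl2$records$gene, c("gA", "gB"))

  # idempotence
  dl3 <- rank_and_truncate(dl$records, "abs_log2fc_desc")
  expect_equal(dl3$records, dl$records)
  expect_error(rank_and_truncate(rec[0, ], "padj_asc"), "non-empty")
})
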