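test_that("union genelist unites passing sets with provenance", {
  rec <- data.frame(de_list_id = "L",
                    set_id = c("S1", "S2", "S3"), source = "GOBP",
                    auc = 0.7, roc_p = c(0.001, 0.002, 0.2),
                    roc_p_adj = c(0.01, 0.03, 0.4))
  col <- geneset_collection(list(S1 = c("A", "B"), S2 = c("B", "C"),
                                 S3 = c("X", "Y")))
  u <- build_union_genelist(rec, col)
  expect_equal(as.character(u), c("A", "B", "C"))
  expect_setequal(attr(u, "provenance")$B, c("S1", "S2"))

  # raising the threshold never shrinks the union
  u2 <- build_union_genelist(rec, col, alpha_adj = 0.5)
  expect_true(all(u %in% u2))
  expect_error(build_union_genelist(rec, col, alpha_adj = 1e-6), "no gene set")
})

test_that("fold-change gates intersect as printed thresholds dictate", {
  gates <- fold_change_gates(c("CD4T", "Treg", "Mono"),
                             c("gt", "gt", "lt"), c(-0.1, -0.3, 0.1))
  de <- list(
    CD4T = data.frame(gene = c("keep", "dropMono", "dropCD4T"),
                      avg_log2FC = c(-0.05, 0.3, -0.5)),
    Treg = data.frame(gene = c("keep", "dropMono", "dropCD4T"),
                      avg_log2FC = c(-0.2, 0.1, 0)),
    Mono = data.frame(gene = c("keep", "dropMono", "dropCD4T"),
                      avg_log2FC = c(0.05, 0.2, 0)))
  out <- build_intersect_genelist(de, gates)
  # -0.05 > -0.1, -0.2 > -0.3, 0.05 < 0.1 -> retained
  expect_equal(out, "keep")
  # a gene failing any single gate is excluded regardless of the others
  expect_false("dropMono" %in% out)

  # gates at (gt, -Inf) reduce to the identity
  wide <- fold_change_gates(names(de), rep("gt", 3), rep(-Inf, 3))
  expect_setequal(build_intersect_genelist(de, wide),
                  c("keep", "dropMono", "dropCD4T"))

  # untested genes fail by default, pass with the flag
  de2 <- de
  de2$CD4T <- de2$CD4T[de2$CD4T$gene != "keep", ]
  expect_error(build_intersect_genelist(de2, gates), "survivors")
  out2 <- build_intersect_genelist(de2, gates,
                                   universe = c("keep", "dropMono",
                                                "dropCD4T"),
                                   untested_pass = TRUE)
  expect_equal(out2, "keep")
  expect_error(build_intersect_genelist(de, gates[1:2, ]), "cover exactly")
})

test_that("candidate assembly intersects union, gates and cohort genes", {
  u <- structure(c("A", "B", "C", "D"),
                 provenance = list(A = "S1", B = "S1", C = "S2", D = "S2"))
  cand <- assemble_candidates(u, c("A", "B", "C", "Z"), c("A", "B", "C", "Q"))
  expect_equal(cand$genelist, c("A", "B", "C"))
  expect_equal(names(cand$provenance), c("A", "B", "C"))
  # a union gene missing from the cohort is excluded
  cand2 <- assemble_candidates(u, c("A", "B", "C", "D"), c("A", "B", "C"))
  expect_false("D" %in% cand2$genelist)
  expect_error(assemble_candidates(u, c("Z1", "Z2", "Z3"), c("A", "B")),
               "fewer than 3")
})

test_that("greedy elimination follows the leave-one-out cycle exactly", {
  # deterministic stub scorer: quality = planted overlap, perturbed by a
  # seed-independent gene-specific value so ties are rare
  planted <- c("g1", "g3", "g5")
  stub <- function(genes, seed) {
    sum(genes %in% planted) + sum(match(genes, paste0("g", 1:9)) %% 7) / 100
  }
  trace <- greedy_backward_elimination(paste0("g", 1:6), auc_fun = stub,
                                       min_size = 3, seed = 1)
  it <- trace$iterations
  expect_equal(it$panel_size, c(5, 4, 3))
  expect_equal(trace$n_evaluations, 6 + 5 + 4)
  # removed gene never remains in its panel
  for (i in seq_len(nrow(it))) {
    expect_false(it$removed_gene[i] %in%
                   strsplit(it$genes[i], ",")[[1]])
  }

  # independent greedy oracle sharing the same scorer and seed derivation
  oracle_panel <- sort(paste0("g", 1:6))
  oracle_rows <- list()
  i <- 0
  while (length(oracle_panel) > 3) {
    i <- i + 1
    scores <- sapply(oracle_panel, function(g)
      stub(setdiff(oracle_panel, g), derive_seed(1, "cycle", i, g)))
    best <- max(scores)
    rm_g <- sort(oracle_panel[scores == best])[1]
    oracle_panel <- setdiff(oracle_panel, rm_g)
    oracle_rows[[i]] <- c(rm_g, paste(oracle_panel, collapse = ","))
  }
  expect_equal(it$removed_gene, vapply(oracle_rows, `[[`, "", 1))
  expect_equal(it$genes, vapply(oracle_rows, `[[`, "", 2))

  # boundary: 4 genes, min_size 3 -> exactly one iteration
  tr4 <- greedy_backward_elimination(paste0("g", 1:4), auc_fun = stub,
                                     min_size = 3, seed = 1)
  expect_equal(nrow(tr4$iterations), 1)
  expect_error(greedy_backward_elimination(paste0("g", 1:2), auc_fun = stub),
               "smaller than min_size")
})

test_that("input order never changes the trace; ties break lexicographically", {
  stub <- function(genes, seed) length(genes)  # fully tied scorer
  tr_a <- greedy_backward_elimination(c("gB", "gA", "gC", "gD"),
                                      auc_fun = stub, seed = 2)
  tr_b <- greedy_backward_elimination(c("gD", "gC", "gB", "gA"),
                                      auc_fun = stub, seed = 2)
  expect_identical(tr_a$iterations, tr_b$iterations)
  expect_equal(tr_a$iterations$removed_gene[1], "gA")

  # real scorer: shuffled candidate order reproduces the same trace
  bulk <- fixture_bulk(); sc <- fixture_sc()
  genes <- c(sc$truth$planted_genes$resistance[1:6],
             setdiff(rownames(bulk$expr),
                     unlist(sc$truth$planted_genes))[1:4])
  t1 <- greedy_backward_elimination(genes, bulk$expr,
                                    bulk$sample_meta$response,
                                    n_rep = 10, seed = 3)
  t2 <- greedy_backward_elimination(sample(genes), bulk$expr,
                                    bulk$sample_meta$response,
                                    n_rep = 10, seed = 3)
  expect_identical(t1$iterations, t2$iterations)
  # evaluation-count identity: n + (n-1) + ... + (m+1)
  expect_equal(t1$n_evaluations, sum(seq(length(genes), 4)))
})

test_that("non-monotone AUC traces are preserved, not smoothed", {
  # crafted scorer: AUC dips at size 5 then rises again at size 4
  quality <- c(`6` = 0.80, `5` = 0.70, `4` = 0.85, `3` = 0.75)
  stub <- function(genes, seed) quality[[as.character(length(genes))]]
  tr <- greedy_backward_elimination(paste0("g", 1:7), auc_fun = stub,
                                    min_size = 3, seed = 1)
  expect_equal(tr$iterations$best_auc, c(0.80, 0.70, 0.85, 0.75))
  expect_false(all(diff(tr$iterations$best_auc) <= 0))
})

test_that("signature selection honours the delta and target-size rules", {
  it <- data.frame(iteration = 1:5, panel_size = c(7, 6, 5, 4, 3),
                   removed_gene = paste0("r", 1:5),
                   best_auc = c(0.90, 0.92, 0.915, 0.80, 0.70),
                   genes = c("a,b,c,d,e,f,g", "a,b,c,d,e,f", "a,b,c,d,e",
                             "a,b,c,d", "a,b,c"))
  tr <- structure(list(iterations = it), class = "cycle_trace")
  # delta = 0: global max AUC, smallest among ties
  expect_equal(select_signature(tr, delta = 0)$size, 6)
  # default delta keeps the smaller panel within 0.01 of the max
  expect_equal(select_signature(tr, delta = 0.01)$size, 5)
  # delta = 1 collapses to the smallest recorded panel
  expect_equal(select_signature(tr, delta = 1)$size, 3)
  sel <- select_signature(tr, target_size = 4)
  expect_equal(sel$genes, c("a", "b", "c", "d"))
  expect_equal(sel$auc_at_selection, 0.80)
  expect_error(select_signature(tr, target_size = 99), "no panel")
})
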