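# Shared fixtures, built once per test run. Sizes are chosen so the whole
# suite stays fast while leaving enough cells/samples for the statistical
# assertions to be stable.

fx <- new.env()

fixture_sc <- function() {
  if (is.null(fx$sc)) {
    fx$sc <- generate_single_cell_dataset(
      n_genes = 300, n_cells = 240, n_subclusters = 3,
      truth_params = synthetic_truth_params(), seed = 42)
  }
  fx$sc
}

fixture_bulk <- function() {
  if (is.null(fx$bulk)) {
    fx$bulk <- generate_bulk_cohort(100, 0.3, fixture_sc()$truth, seed = 42)
  }
  fx$bulk
}

fixture_lognorm <- function() {
  if (is.null(fx$lognorm)) fx$lognorm <- log_normalize(fixture_sc()$expr)
  fx$lognorm
}

# A tiny lognorm matrix with hand-chosen values; existing dimnames win.
toy_lognorm <- function(values, genes = NULL, obs = NULL) {
  if (is.null(genes)) {
    genes <- rownames(values) %||% paste0("g", seq_len(nrow(values)))
  }
  if (is.null(obs)) {
    obs <- colnames(values) %||% paste0("s", seq_len(ncol(values)))
  }
  dimnames(values) <- list(genes, obs)
  expression_matrix(values, "lognorm")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# Perfectly separable two-class cohort: class means differ strongly on
# every panel gene.
separable_cohort <- function(n_per_class = 20, n_genes = 6, delta = 5,
                             seed = 7) {
  withr::with_seed(seed, {
    n <- 2 * n_per_class
    x <- matrix(rnorm(n_genes * n), n_genes, n,
                dimnames = list(sprintf("g%02d", seq_len(n_genes)),
                                sprintf("s%02d", seq_len(n))))
    labels <- rep(c("NR", "R"), each = n_per_class)
    x[, labels == "NR"] <- x[, labels == "NR"] + delta
    list(expr = expression_matrix(x, "lognorm"), labels = labels)
  })
}

# Label-free cohort: pure noise expression plus arbitrary labels.
null_cohort <- function(n = 40, n_genes = 30, seed = 11) {
  withr::with_seed(seed, {
    x <- matrix(rnorm(n_genes * n), n_genes, n,
                dimnames = list(sprintf("g%02d", seq_len(n_genes)),
                                sprintf("s%02d", seq_len(n))))
    list(expr = expression_matrix(x, "lognorm"),
         labels = rep(c("NR", "R"), length.out = n))
  })
}

# Brute-force AUC: fraction of concordant (positive, negative) score pairs,
# ties counted one half.
auc_bruteforce <- function(score, positive) {
  ok <- !is.na(score)
  score <- score[ok]; positive <- positive[ok]
  zp <- score[positive]; zn <- score[!positive]
  conc <- 0
  for (a in zp) for (b in zn) conc <- conc + (a > b) + 0.5 * (a == b)
  conc / (length(zp) * length(zn))
}
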