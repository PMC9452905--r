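#' Union of member genes of predictive gene sets
#'
#' Unites the genes of every set whose screen-adjusted ROC p falls below
#' `alpha_adj`, recording which set(s) contributed each gene.
#'
#' @param records Screen records (from [screen_genesets()], with
#'   `roc_p_adj`).
#' @param collections A [geneset_collection()] or list of them.
#' @param alpha_adj Adjusted-p threshold (default 0.05).
#' @return Character vector of genes with a `provenance` attribute
#'   (named list gene -> contributing set ids).
#' @export
build_union_genelist <- function(records, collections, alpha_adj = 0.05) {
  if (inherits(collections, "geneset_collection")) collections <- list(collections)
  pass <- unique(records$set_id[records$roc_p_adj < alpha_adj])
  if (!length(pass)) stop("no gene set passes the adjusted ROC p threshold")
  prov <- list()
  for (col in collections) {
    for (sid in intersect(pass, names(col$sets))) {
      for (g in col$sets[[sid]]) prov[[g]] <- c(prov[[g]], sid)
    }
  }
  genes <- sort(names(prov))
  structure(genes, provenance = prov[genes])
}

#' Fold-change gates for the per-subtype intersect list
#'
#' @param subtype_ids Character vector of subtype ids.
#' @param comparators `"gt"` or `"lt"` per subtype.
#' @param thresholds Numeric avg_log2FC thresholds (NR vs R) per subtype.
#' @return A data.frame of class `fold_change_gates`.
#' @export
fold_change_gates <- function(subtype_ids, comparators, thresholds) {
  stopifnot(length(subtype_ids) == length(comparators),
            length(subtype_ids) == length(thresholds),
            all(comparators %in% c("gt", "lt")),
            !anyDuplicated(subtype_ids))
  structure(data.frame(subtype_id = subtype_ids, comparator = comparators,
                       threshold = thresholds, stringsAsFactors = FALSE),
            class = c("fold_change_gates", "data.frame"))
}

#' Intersect per-subtype fold-change-gated gene lists
#'
#' For each subtype, genes of its nonresponder-vs-responder DE table that
#' satisfy the subtype's gate are retained; the result is the intersection
#' across all subtypes. Genes absent from a subtype's table (not tested)
#' fail that subtype's gate unless `untested_pass = TRUE`.
#'
#' @param de_tables Named list: subtype id -> DE record data.frame (NR vs R,
#'   with columns gene and avg_log2FC).
#' @param gates A [fold_change_gates()] covering exactly the subtypes in
#'   `de_tables`.
#' @param universe Gene universe used when `untested_pass = TRUE`.
#' @param untested_pass Let untested genes pass the gate (default FALSE).
#' @return Character vector of genes passing every gate.
#' @export
build_intersect_genelist <- function(de_tables, gates, universe = NULL,
                                     untested_pass = FALSE) {
  stopifnot(inherits(gates, "fold_change_gates"))
  if (!setequal(names(de_tables), gates$subtype_id)) {
    stop("gates must cover exactly the subtypes of `de_tables`")
  }
  survivors <- lapply(gates$subtype_id, function(sid) {
    tab <- de_tables[[sid]]
    g <- gates[gates$subtype_id == sid, ]
    ok <- if (g$comparator == "gt") tab$avg_log2FC > g$threshold
          else tab$avg_log2FC < g$threshold
    passing <- tab$gene[ok]
    if (untested_pass) {
      if (is.null(universe)) stop("`universe` required when untested_pass = TRUE")
      passing <- union(passing, setdiff(universe, tab$gene))
    }
    passing
  })
  out <- Reduce(intersect, survivors)
  if (!length(out)) {
    counts <- paste(sprintf("%s=%d", gates$subtype_id, lengths(survivors)),
                    collapse = ", ")
    stop("empty intersection; per-gate survivors: ", counts)
  }
  sort(out)
}

#' Assemble the candidate gene list
#'
#' Three-way intersection of the union list (genes of predictive sets), the
#' intersect list (fold-change-gated genes) and the genes measured in the
#' reference cohort.
#'
#' @param union_genelist From [build_union_genelist()].
#' @param intersect_genelist From [build_intersect_genelist()].
#' @param cohort_genes Genes measured in the reference cohort.
#' @return A list of class `candidate_genelist`: union_genelist,
#'   intersect_genelist, genelist, provenance.
#' @export
assemble_candidates <- function(union_genelist, intersect_genelist,
                                cohort_genes) {
  stopifnot(length(union_genelist) > 0, length(intersect_genelist) > 0,
            length(cohort_genes) > 0)
  genes <- intersect(intersect(union_genelist, intersect_genelist),
                     cohort_genes)
  if (length(genes) < 3) {
    stop("candidate genelist has fewer than 3 genes (classifier floor)")
  }
  prov <- attr(union_genelist, "provenance")
  structure(list(union_genelist = as.character(union_genelist),
                 intersect_genelist = intersect_genelist,
                 genelist = sort(genes),
                 provenance = prov[sort(genes)]),
            class = "candidate_genelist")
}

#' Greedy leave-one-out backward elimination maximizing AUC
#'
#' The cycle algorithm: with a current panel of k genes, all k subsets of
#' size k-1 are evaluated by multiple random validation (each subset under a
#' deterministic seed derived from the master seed, the iteration and the
#' removed gene); the subset with the largest AUC survives to the next
#' cycle. Ties remove the lexicographically smallest gene among the
#' maximizers. The cycle repeats until removing another gene would leave
#' fewer than `min_size` genes. The input gene order never affects the
#' result: the panel is sorted internally.
#'
#' @param genelist Candidate genes (>= `min_size`).
#' @param cohort_expr Lognorm [expression_matrix()] of the reference cohort.
#' @param labels Response labels.
#' @param n_rep,train_frac Validator settings for each subset evaluation
#'   (defaults 50 and 2/3 -- the elimination only needs the AUC ordering of
#'   subsets, so fewer splits than the reporting validator are used).
#' @param min_size Smallest panel recorded (default 3).
#' @param seed Integer master seed.
#' @param auc_fun Optional scorer override `function(genes, seed) -> auc`
#'   (used for bookkeeping tests and custom validators); defaults to
#'   [panel_auc()] on the cohort.
#' @param class_pos,class_neg Class names.
#' @return A list of class `cycle_trace` with `iterations`, a data.frame
#'   (iteration, panel_size, removed_gene, best_auc, genes as comma-joined
#'   ids), `n_evaluations`, `seed`, and validator settings.
#' @export
greedy_backward_elimination <- function(genelist, cohort_expr = NULL,
                                        labels = NULL, n_rep = 50,
                                        train_frac = 2 / 3, min_size = 3,
                                        seed = 1, auc_fun = NULL,
                                        class_pos = "NR", class_neg = "R") {
  panel <- sort(unique(as.character(genelist)))
  if (length(panel) < min_size) stop("genelist smaller than min_size")
  if (is.null(auc_fun)) {
    if (is.null(cohort_expr) || is.null(labels)) {
      stop("cohort_expr and labels required without a custom auc_fun")
    }
    auc_fun <- function(genes, subset_seed) {
      panel_auc(cohort_expr, labels, genes, n_rep = n_rep,
                train_frac = train_frac, seed = subset_seed,
                class_pos = class_pos, class_neg = class_neg)
    }
  }
  iters <- list()
  n_eval <- 0L
  it <- 0L
  while (length(panel) > min_size) {
    it <- it + 1L
    aucs <- vapply(panel, function(g) {
      auc_fun(setdiff(panel, g), derive_seed(seed, "cycle", it, g))
    }, 0)
    n_eval <- n_eval + length(panel)
    best <- max(aucs)
    removed <- sort(panel[aucs == best])[1L]  # lexicographic tie-break
    panel <- setdiff(panel, removed)
    iters[[it]] <- data.frame(
      iteration = it, panel_size = length(panel), removed_gene = removed,
      best_auc = best, genes = paste(panel, collapse = ","),
      stringsAsFactors = FALSE)
  }
  structure(list(iterations = do.call(rbind, iters), n_evaluations = n_eval,
                 seed = seed, n_rep = n_rep, train_frac = train_frac,
                 min_size = min_size), class = "cycle_trace")
}

#' @export
print.cycle_trace <- function(x, ...) {
  it <- x$iterations
  cat(sprintf("<cycle_trace> %d iterations (%d evaluations), sizes %d..%d, max AUC %.3f\n",
              nrow(it), x$n_evaluations, max(it$panel_size),
              min(it$panel_size), max(it$best_auc)))
  invisible(x)
}

#' Select the signature panel from a cycle trace
#'
#' The `target_size` rule returns the panel recorded at that size; the
#' `delta` rule formalizes "balance the highest reliability and fewest
#' genes": the smallest panel whose AUC is within `delta` of the trace
#' maximum.
#'
#' @param trace A `cycle_trace`.
#' @param target_size Exact panel size to return (overrides `delta`).
#' @param delta AUC tolerance below the trace maximum (default 0.01).
#' @return A list of class `signature_panel`: genes, size,
#'   auc_at_selection, selection_rule.
#' @export
select_signature <- function(trace, target_size = NULL, delta = 0.01) {
  it <- trace$iterations
  if (is.null(it) || !nrow(it)) stop("empty trace")
  if (!is.null(target_size)) {
    row <- it[it$panel_size == target_size, , drop = FALSE]
    if (!nrow(row)) stop("no panel of size ", target_size, " in the trace")
    rule <- paste0("target_size=", target_size)
  } else {
    best <- max(it$best_auc)
    ok <- it[it$best_auc >= best - delta, , drop = FALSE]
    row <- ok[which.min(ok$panel_size), , drop = FALSE]
    rule <- paste0("delta=", delta)
  }
  structure(list(genes = strsplit(row$genes, ",", fixed = TRUE)[[1L]],
                 size = row$panel_size, auc_at_selection = row$best_auc,
                 selection_rule = rule), class = "signature_panel")
}

#' @export
print.signature_panel <- function(x, ...) {
  cat(sprintf("<signature_panel> %d genes (rule %s), AUC at selection %.3f\n",
              x$size, x$selection_rule, x$auc_at_selection))
  invisible(x)
}
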