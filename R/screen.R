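#' Screen enriched gene sets for cohort-level predictiveness
#'
#' For every (DE list, enriched set) pair, runs the nearest-centroid
#' multiple random validation with the set as the gene panel and records the
#' Welch ROC p-value; Benjamini-Hochberg adjustment is applied across the
#' whole screen. A set appearing under two DE lists receives the same seed
#' (derived from the set id alone), so its ROC p is identical wherever it
#' appears.
#'
#' @param enriched_map Named list: DE list id -> character vector of set ids.
#' @param collections A [geneset_collection()] or list of them supplying the
#'   member genes of every screened set.
#' @param cohort_expr Lognorm [expression_matrix()] of the bulk cohort.
#' @param cohort_labels Response labels (`R`/`NR`; others ignored).
#' @param n_rep,train_frac Validator settings (defaults 100 and 2/3).
#' @param seed Integer seed.
#' @return A data.frame of screen records: de_list_id, set_id, source, auc,
#'   roc_p, roc_p_adj.
#' @export
screen_genesets <- function(enriched_map, collections, cohort_expr,
                            cohort_labels, n_rep = 100, train_frac = 2 / 3,
                            seed = 1) {
  if (!length(enriched_map)) stop("enriched_map is empty")
  if (inherits(collections, "geneset_collection")) collections <- list(collections)
  set_genes <- list()
  set_source <- character()
  for (col in collections) {
    for (id in names(col$sets)) {
      set_genes[[id]] <- col$sets[[id]]
      set_source[id] <- col$source
    }
  }
  rows <- list()
  cache <- new.env(parent = emptyenv())
  for (lid in names(enriched_map)) {
    for (sid in enriched_map[[lid]]) {
      if (is.null(set_genes[[sid]])) stop("unknown set id: ", sid)
      if (!exists(sid, envir = cache, inherits = FALSE)) {
        rep <- multiple_random_validation(
          cohort_expr, cohort_labels, set_genes[[sid]],
          n_rep = n_rep, train_frac = train_frac,
          seed = derive_seed(seed, "screen", sid), n_boot = 0)
        assign(sid, list(auc = rep$auc, p = rep$p_roc), envir = cache)
      }
      r <- get(sid, envir = cache)
      rows[[length(rows) + 1L]] <- data.frame(
        de_list_id = lid, set_id = sid, source = set_source[sid],
        auc = r$auc, roc_p = r$p, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$roc_p_adj <- stats::p.adjust(out$roc_p, "BH")
  rownames(out) <- NULL
  out
}

#' Flag predictive DE gene lists
#'
#' A DE gene list is called significant when no less than half (or `frac`)
#' of its enriched gene sets have ROC p-values below `alpha`; exactly half
#' counts as a pass.
#'
#' @param records Screen records from [screen_genesets()].
#' @param alpha ROC p threshold (default 0.05).
#' @param frac Required passing fraction (default 0.5).
#' @param use_fdr Use the BH-adjusted `roc_p_adj` instead of raw `roc_p`.
#' @param all_lists Optional character vector of every DE list id screened;
#'   lists with zero enriched sets then appear with `significant = FALSE`
#'   and `flagged = TRUE`.
#' @return A data.frame of verdicts: de_list_id, n_sets, n_pass, frac_pass,
#'   significant, flagged.
#' @export
flag_de_lists <- function(records, alpha = 0.05, frac = 0.5, use_fdr = FALSE,
                          all_lists = NULL) {
  pcol <- if (use_fdr) records$roc_p_adj else records$roc_p
  ids <- union(unique(records$de_list_id), all_lists)
  out <- do.call(rbind, lapply(ids, function(lid) {
    sel <- records$de_list_id == lid
    n <- sum(sel)
    np <- sum(pcol[sel] < alpha)
    data.frame(de_list_id = lid, n_sets = n, n_pass = np,
               frac_pass = if (n > 0) np / n else 0,
               significant = n > 0 && np / n >= frac,
               flagged = n == 0, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Locate the subcluster expressing the predictive gene sets
#'
#' Scores every significant set per cell with [gsva_score()], finds the
#' subcluster with the highest mean score per set, and calls the consensus
#' subcluster by majority vote across sets (one-vs-rest Wilcoxon p reported
#' per set). No majority, or no scorable sets, yields an ambiguous call.
#'
#' @param sc_expr Lognorm [expression_matrix()] of single cells.
#' @param subcluster_labels Subcluster id per cell (aligned with columns).
#' @param significant_sets A [geneset_collection()] (or named gene list) of
#'   the predictive sets.
#' @param tau,min_size Passed to [gsva_score()].
#' @return A list of class `subcluster_call`: subcluster_id (NA when
#'   ambiguous), ambiguous (flag), per_set (data.frame: set_id, top
#'   subcluster, mean score, one-vs-rest Wilcoxon p).
#' @export
locate_predictive_subcluster <- function(sc_expr, subcluster_labels,
                                         significant_sets, tau = 1,
                                         min_size = 2) {
  if (inherits(significant_sets, "geneset_collection")) {
    n_sets <- length(significant_sets$sets)
  } else {
    n_sets <- length(significant_sets)
  }
  if (!n_sets) stop("no significant sets supplied")
  labs <- as.character(subcluster_labels)
  if (length(unique(labs)) < 2) stop("need at least 2 subclusters")
  scores <- tryCatch(
    suppressWarnings(gsva_score(sc_expr, significant_sets, tau = tau,
                                min_size = min_size)),
    error = function(e) NULL)
  if (is.null(scores)) {
    return(structure(list(subcluster_id = NA_character_, ambiguous = TRUE,
                          per_set = NULL), class = "subcluster_call"))
  }
  per_set <- do.call(rbind, lapply(rownames(scores), function(sid) {
    row <- scores[sid, ]
    mu <- tapply(row, labs, mean)
    top <- names(mu)[which.max(mu)]
    p <- wilcoxon_rank_sum(row[labs == top], row[labs != top])$p
    data.frame(set_id = sid, subcluster_id = top,
               mean_score = max(mu), p_vs_rest = p,
               stringsAsFactors = FALSE)
  }))
  votes <- table(per_set$subcluster_id)
  winner <- names(votes)[which.max(votes)]
  ambiguous <- max(votes) <= nrow(per_set) / 2 && length(votes) > 1
  structure(list(
    subcluster_id = if (ambiguous) NA_character_ else winner,
    ambiguous = ambiguous, per_set = per_set), class = "subcluster_call")
}
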