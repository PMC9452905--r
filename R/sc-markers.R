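#' Library-size log-normalization
#'
#' Each cell's counts are divided by the cell total, multiplied by
#' `scale_factor` and log-transformed with a pseudocount of 1:
#' `log(count / total * scale_factor + 1)` in the configured base. The
#' column sums of the un-logged normalized values equal `scale_factor`.
#'
#' @param counts A counts-layer [expression_matrix()].
#' @param scale_factor Library-size target (default 10000).
#' @param base Log base (default natural; the fold-change convention
#'   downstream de-logs before averaging, so results are insensitive to it).
#' @return A lognorm [expression_matrix()] with the base recorded.
#' @export
log_normalize <- function(counts, scale_factor = 1e4, base = exp(1)) {
  stopifnot(inherits(counts, "expr_matrix"))
  if (expr_layer(counts) != "counts") stop("input must be a counts layer")
  totals <- colSums(counts)
  if (any(totals == 0)) {
    stop("zero-total cell(s): ", paste(colnames(counts)[totals == 0], collapse = ", "))
  }
  vals <- log1p(sweep(as_plain_matrix(counts), 2L, totals, "/") * scale_factor) /
    log(base)
  expression_matrix(vals, "lognorm", logbase = base)
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Reports the Mann-Whitney U statistic for `x` and a two-sided p-value:
#' exact (via the null U distribution) when `length(x) + length(y) <= 12`
#' and there are no ties, otherwise the normal approximation with tie and
#' continuity corrections.
#'
#' @param x,y Numeric vectors (non-empty).
#' @return A list with `statistic` (U) and `p`.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  m <- length(x); n <- length(y)
  stopifnot(m >= 1, n >= 1)
  z <- c(x, y)
  r <- rank(z)
  U <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  ties <- table(z)
  has_ties <- any(ties > 1)
  if (all(z == z[1L])) return(list(statistic = U, p = 1))
  if (m + n <= 12 && !has_ties) {
    p <- if (U > m * n / 2) {
      2 * stats::pwilcox(U - 1, m, n, lower.tail = FALSE)
    } else {
      2 * stats::pwilcox(U, m, n)
    }
    return(list(statistic = U, p = min(1, p)))
  }
  mu <- m * n / 2
  tie_term <- sum(ties^3 - ties)
  N <- m + n
  sigma2 <- m * n / 12 * ((N + 1) - tie_term / (N * (N - 1)))
  if (sigma2 <= 0) return(list(statistic = U, p = 1))
  d <- U - mu
  d <- sign(d) * max(0, abs(d) - 0.5)  # continuity correction
  p <- 2 * stats::pnorm(-abs(d) / sqrt(sigma2))
  list(statistic = U, p = min(1, p))
}

# De-log a lognorm matrix back to normalized expression scale.
delog <- function(lognorm) {
  expr_logbase(lognorm)^as_plain_matrix(lognorm) - 1
}

#' Per-gene average log2 fold change between two cell groups
#'
#' De-logs the normalized expression, averages within each group, adds a
#' pseudocount and takes the log2 ratio -- the convention of current
#' single-cell toolkits, so values are comparable with published marker
#' tables.
#'
#' @param lognorm A lognorm [expression_matrix()].
#' @param group1,group2 Observation ids (disjoint, non-empty).
#' @param pseudocount Added to each de-logged group mean (default 1).
#' @return Named numeric vector, one value per gene (group1 vs group2).
#' @export
avg_log2fc <- function(lognorm, group1, group2, pseudocount = 1) {
  stopifnot(inherits(lognorm, "expr_matrix"), expr_layer(lognorm) == "lognorm")
  if (!length(group1) || !length(group2)) stop("groups must be non-empty")
  if (length(intersect(group1, group2))) stop("groups must be disjoint")
  x <- delog(lognorm)
  m1 <- rowMeans(x[, group1, drop = FALSE])
  m2 <- rowMeans(x[, group2, drop = FALSE])
  log2(m1 + pseudocount) - log2(m2 + pseudocount)
}

#' Marker detection between two cell groups
#'
#' Genes are tested only if detected in at least `min_pct` of cells in one
#' of the groups and their absolute average log2 fold change reaches
#' `logfc_threshold`; p-values come from [wilcoxon_rank_sum()] and are
#' adjusted over the tested genes.
#'
#' @inheritParams avg_log2fc
#' @param min_pct Minimum detection fraction in the better group (default 0.1).
#' @param logfc_threshold Minimum |avg_log2FC| (default 0.25).
#' @param adjust `"bonferroni"` (cluster-marker default) or `"BH"`.
#' @param only_positive Keep only group1-up markers.
#' @return A data.frame of DE records: gene, avg_log2FC, pct_1, pct_2, p,
#'   p_adj, ordered by p then gene.
#' @export
find_markers <- function(lognorm, group1, group2, min_pct = 0.1,
                         logfc_threshold = 0.25,
                         adjust = c("bonferroni", "BH"),
                         only_positive = FALSE) {
  adjust <- match.arg(adjust)
  stopifnot(min_pct >= 0, logfc_threshold >= 0)
  lfc <- avg_log2fc(lognorm, group1, group2)
  x1 <- as_plain_matrix(lognorm)[, group1, drop = FALSE]
  x2 <- as_plain_matrix(lognorm)[, group2, drop = FALSE]
  pct1 <- rowMeans(x1 > 0)
  pct2 <- rowMeans(x2 > 0)
  test <- pmax(pct1, pct2) >= min_pct & abs(lfc) >= logfc_threshold
  if (only_positive) test <- test & lfc > 0
  if (!any(test)) {
    warning("no genes pass the prefilters")
    return(data.frame(gene = character(), avg_log2FC = numeric(),
                      pct_1 = numeric(), pct_2 = numeric(), p = numeric(),
                      p_adj = numeric(), stringsAsFactors = FALSE))
  }
  idx <- which(test)
  p <- vapply(idx, function(i) wilcoxon_rank_sum(x1[i, ], x2[i, ])$p, 0)
  out <- data.frame(gene = rownames(lognorm)[idx], avg_log2FC = lfc[idx],
                    pct_1 = pct1[idx], pct_2 = pct2[idx], p = p,
                    p_adj = pmin(1, stats::p.adjust(p, adjust)),
                    row.names = NULL, stringsAsFactors = FALSE)
  out[order(out$p, out$gene), , drop = FALSE]
}

#' One-vs-rest marker detection for every cluster
#'
#' @inheritParams find_markers
#' @param cluster_labels Named character vector or factor: observation id ->
#'   cluster.
#' @param only_positive Keep only up-regulated markers (default TRUE,
#'   matching marker-heatmap usage).
#' @return Named list (cluster id -> DE record data.frame, with a `cluster`
#'   column and a `low_confidence` attribute for singleton clusters).
#' @export
find_all_markers <- function(lognorm, cluster_labels, min_pct = 0.1,
                             logfc_threshold = 0.25,
                             adjust = c("bonferroni", "BH"),
                             only_positive = TRUE) {
  adjust <- match.arg(adjust)
  labs <- as.character(cluster_labels)
  if (is.null(names(cluster_labels))) names(labs) <- colnames(lognorm)
  else names(labs) <- names(cluster_labels)
  cl <- sort(unique(labs))
  if (length(cl) < 2) stop("need at least 2 clusters")
  out <- lapply(cl, function(cid) {
    g1 <- names(labs)[labs == cid]
    g2 <- names(labs)[labs != cid]
    rec <- suppressWarnings(
      find_markers(lognorm, g1, g2, min_pct = min_pct,
                   logfc_threshold = logfc_threshold, adjust = adjust,
                   only_positive = only_positive))
    if (nrow(rec)) rec$cluster <- cid
    attr(rec, "low_confidence") <- length(g1) < 2
    rec
  })
  stats::setNames(out, cl)
}

#' Rank and truncate a DE record table into a directed gene list
#'
#' Stable sort by the chosen key with lexicographic gene-id tie-breaks,
#' truncated to at most `max_n` genes (all genes are kept if fewer) -- the
#' convention used when submitting lists to enrichment tools that cap the
#' query size.
#'
#' @param records DE record data.frame (from [find_markers()]).
#' @param ranking_key `"abs_log2fc_desc"` or `"padj_asc"`.
#' @param max_n Truncation cap (default 500).
#' @param id List identifier (e.g. `"Mono.R"`).
#' @return A list of class `de_gene_list` with fields id, records,
#'   ranking_key, truncation.
#' @export
rank_and_truncate <- function(records, ranking_key = c("abs_log2fc_desc",
                                                       "padj_asc"),
                              max_n = 500, id = "de_list") {
  ranking_key <- match.arg(ranking_key)
  if (!nrow(records)) stop("records must be non-empty")
  ord <- switch(ranking_key,
    abs_log2fc_desc = order(-abs(records$avg_log2FC), records$gene),
    padj_asc = order(records$p_adj, records$gene))
  out <- records[ord, , drop = FALSE]
  out <- utils::head(out, max_n)
  rownames(out) <- NULL
  structure(list(id = id, records = out, ranking_key = ranking_key,
                 truncation = max_n),
            class = "de_gene_list")
}

#' @export
print.de_gene_list <- function(x, ...) {
  cat(sprintf("<de_gene_list> %s: %d genes (key=%s, cap=%d)\n",
              x$id, nrow(x$records), x$ranking_key, x$truncation))
  invisible(x)
}

#' Write DE records to TSV
#'
#' @param records DE record data.frame.
#' @param path Output path.
#' @param cluster,direction Optional annotation columns.
#' @export
write_de_table <- function(records, path, cluster = NA, direction = NA) {
  out <- records
  names(out)[names(out) == "pct_1"] <- "pct.1"
  names(out)[names(out) == "pct_2"] <- "pct.2"
  names(out)[names(out) == "p"] <- "p_val"
  names(out)[names(out) == "p_adj"] <- "p_val_adj"
  if (!"cluster" %in% names(out)) out$cluster <- cluster
  out$direction <- direction
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
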