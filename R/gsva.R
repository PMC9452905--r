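#' Single-sample gene-set variation scores
#'
#' GSVA-style scoring: per gene, a Gaussian-kernel cumulative density across
#' observations (bandwidth = per-gene SD / 4) maps expression to (0, 1);
#' per observation, genes are ranked by these values and converted to
#' symmetric rank statistics `|p/2 - rank|`; per set, a weighted random walk
#' down the ranking (hit increments proportional to the rank statistic to
#' the power `tau`, miss decrements uniform) yields the enrichment score.
#' With `es_mode = "maxdiff"` the score is the sum of the maximum positive
#' and minimum negative deviations of the walk; with `"absmax"` it is the
#' single largest-magnitude deviation. Both are bounded in \[-1, 1\] because
#' hit and miss increments are normalized to unit total mass.
#'
#' @param expr A lognorm [expression_matrix()] or plain matrix
#'   (genes x observations, >= 2 observations).
#' @param sets A [geneset_collection()] or named list of gene vectors.
#' @param tau Weighting exponent on the symmetric rank statistic (default 1).
#' @param min_size Minimum measured set size scored (default 2).
#' @param es_mode `"maxdiff"` (default) or `"absmax"`.
#' @return A matrix of class `gsva_matrix` (sets x observations) in
#'   \[-1, 1\].
#' @export
gsva_score <- function(expr, sets, tau = 1, min_size = 2,
                       es_mode = c("maxdiff", "absmax")) {
  es_mode <- match.arg(es_mode)
  X <- as_plain_matrix(expr)
  if (ncol(X) < 2) stop("need at least 2 observations")
  if (inherits(sets, "geneset_collection")) sets <- sets$sets
  sets <- lapply(sets, function(g) intersect(unique(g), rownames(X)))
  sizes <- lengths(sets)
  if (any(sizes < min_size)) {
    warning(sum(sizes < min_size), " set(s) below the size floor dropped")
    sets <- sets[sizes >= min_size]
  }
  if (!length(sets)) stop("no scorable sets remain")

  cdf <- cpp_gauss_cdf(X)
  dimnames(cdf) <- dimnames(X)
  const <- apply(cdf, 1L, function(r) anyNA(r))
  if (any(const)) {
    warning(sum(const), " constant gene(s) excluded from ranking")
    cdf <- cdf[!const, , drop = FALSE]
  }
  if (nrow(cdf) < 2) stop("fewer than 2 variable genes: cannot rank")
  p <- nrow(cdf)
  genes <- rownames(cdf)
  scores <- matrix(NA_real_, length(sets), ncol(cdf),
                   dimnames = list(names(sets), colnames(cdf)))
  hit_mask <- lapply(sets, function(g) genes %in% g)
  for (j in seq_len(ncol(cdf))) {
    r <- rank(-cdf[, j], ties.method = "average")  # 1 = highest expression
    stat <- abs(p / 2 - r + 0.5)
    ord <- order(r)
    stat_o <- stat[ord]
    for (s in seq_along(sets)) {
      hits <- hit_mask[[s]][ord]
      K <- sum(hits)
      if (K < 1 || K >= p) { scores[s, j] <- 0; next }
      w <- stat_o^tau * hits
      inc <- w / sum(w) - (!hits) / (p - K)
      walk <- cumsum(inc)
      scores[s, j] <- if (es_mode == "maxdiff") {
        max(walk, 0) + min(walk, 0)
      } else {
        walk[which.max(abs(walk))]
      }
    }
  }
  structure(scores, class = c("gsva_matrix", "matrix", "array"))
}

#' Compare one row of gene-set scores between two groups
#'
#' Two-sided Wilcoxon rank-sum test of a score row between two label
#' groups, with group medians.
#'
#' @param scores_row Numeric vector of scores (one set).
#' @param labels Group labels aligned with the scores.
#' @param groups Length-2 character vector naming the groups to compare.
#' @return A list with `p`, `median_a`, `median_b` (groups\[1\] and \[2\]).
#' @export
score_group_test <- function(scores_row, labels, groups = c("NR", "R")) {
  a <- scores_row[labels == groups[1L]]
  b <- scores_row[labels == groups[2L]]
  if (!length(a) || !length(b)) stop("both groups must be present")
  w <- wilcoxon_rank_sum(a, b)
  list(p = w$p, median_a = stats::median(a), median_b = stats::median(b))
}
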