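#' Gene-set collection
#'
#' @param sets Named list of character vectors (set id -> member genes).
#' @param name Collection name.
#' @param source One of `"GOBP"`, `"Hallmark"`, `"KEGG"`, `"Reactome"`,
#'   `"synthetic"`.
#' @param descriptions Optional named character vector of set descriptions.
#' @return An object of class `geneset_collection`.
#' @export
geneset_collection <- function(sets, name = "collection",
                               source = c("synthetic", "GOBP", "Hallmark",
                                          "KEGG", "Reactome"),
                               descriptions = NULL) {
  source <- match.arg(source)
  if (is.null(names(sets)) || anyDuplicated(names(sets))) {
    stop("set ids must be unique and named")
  }
  sets <- lapply(sets, function(g) {
    if (anyDuplicated(g)) {
      warning("duplicate genes within a set removed")
      g <- unique(g)
    }
    as.character(g)
  })
  if (is.null(descriptions)) {
    descriptions <- stats::setNames(rep("", length(sets)), names(sets))
  }
  structure(list(name = name, source = source, sets = sets,
                 descriptions = descriptions[names(sets)]),
            class = "geneset_collection")
}

#' @export
print.geneset_collection <- function(x, ...) {
  cat(sprintf("<geneset_collection> %s (%s): %d sets\n",
              x$name, x$source, length(x$sets)))
  invisible(x)
}

#' @export
length.geneset_collection <- function(x) length(x$sets)

#' Read / write GMT files
#'
#' The GMT format stores one gene set per tab-separated line:
#' `set_id<TAB>description<TAB>gene1<TAB>gene2...`.
#'
#' @param path File path.
#' @param name,source Passed to [geneset_collection()].
#' @return [read_gmt()] returns a `geneset_collection`.
#' @export
read_gmt <- function(path, name = basename(path), source = "synthetic") {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad)) stop("GMT parse error: fewer than 3 fields at line ", bad[1L])
  ids <- vapply(fields, `[[`, "", 1L)
  desc <- stats::setNames(vapply(fields, `[[`, "", 2L), ids)
  sets <- stats::setNames(lapply(fields, function(f) f[-c(1L, 2L)]), ids)
  geneset_collection(sets, name = name, source = source, descriptions = desc)
}

#' @rdname read_gmt
#' @param collection A `geneset_collection`.
#' @export
write_gmt <- function(collection, path) {
  lines <- vapply(names(collection$sets), function(id) {
    paste(c(id, collection$descriptions[[id]], collection$sets[[id]]),
          collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Drop gene sets with too few measured genes
#'
#' Set size is evaluated after restriction to the measured gene universe, so
#' a 5-gene set with only 2 measured members is removed at the default floor.
#'
#' @param collection A `geneset_collection`.
#' @param measured Character vector of measured genes.
#' @param min_genes Minimum measured set size retained (default 3, the
#'   classifier's input floor).
#' @return A filtered `geneset_collection`.
#' @export
filter_min_genes <- function(collection, measured, min_genes = 3) {
  keep <- vapply(collection$sets,
                 function(g) sum(g %in% measured) >= min_genes, NA)
  geneset_collection(collection$sets[keep], name = collection$name,
                     source = collection$source,
                     descriptions = collection$descriptions[keep])
}

#' Hypergeometric over-representation analysis
#'
#' Tests each set of each collection for over-representation in `query`
#' relative to `universe` with the hypergeometric upper-tail probability
#' P(X >= k). Benjamini-Hochberg q-values are computed over all tested sets
#' within each collection; records with `q < q_cutoff` are returned, at most
#' `top` per source collection, ordered by (q, p, set_id).
#'
#' @param query Character vector of query genes (subset of `universe`).
#' @param collections A `geneset_collection` or a list of them.
#' @param universe Character vector: the measured gene universe.
#' @param q_cutoff BH q-value cutoff (default 0.05).
#' @param top Maximum sets returned per source collection (default 10).
#' @return A data.frame with columns set_id, source, k, K, n, N, p_hyper, q.
#' @export
overrepresentation <- function(query, collections, universe,
                               q_cutoff = 0.05, top = 10) {
  if (inherits(collections, "geneset_collection")) {
    collections <- list(collections)
  }
  universe <- unique(universe)
  query <- unique(query)
  if (!all(query %in% universe)) stop("query must be a subset of the universe")
  if (!length(query)) {
    warning("empty query: no enrichment computed")
    return(empty_enrichment())
  }
  N <- length(universe)
  n <- length(query)
  out <- lapply(collections, function(col) {
    if (!length(col$sets)) return(empty_enrichment())
    K <- vapply(col$sets, function(g) sum(unique(g) %in% universe), 0L)
    k <- vapply(col$sets, function(g) sum(unique(g) %in% query), 0L)
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    q <- stats::p.adjust(p, "BH")
    rec <- data.frame(set_id = names(col$sets), source = col$source,
                      k = k, K = K, n = n, N = N, p_hyper = p, q = q,
                      row.names = NULL, stringsAsFactors = FALSE)
    rec <- rec[rec$q < q_cutoff, , drop = FALSE]
    rec <- rec[order(rec$q, rec$p_hyper, rec$set_id), , drop = FALSE]
    utils::head(rec, top)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

empty_enrichment <- function() {
  data.frame(set_id = character(), source = character(), k = integer(),
             K = integer(), n = integer(), N = integer(),
             p_hyper = numeric(), q = numeric(), stringsAsFactors = FALSE)
}

#' Preranked gene-set enrichment analysis
#'
#' Classic weighted Kolmogorov-Smirnov enrichment: walking down the ranked
#' list, hits increment the running sum proportionally to `|stat|^weight`
#' (normalized over the set) and misses decrement it by `1/(N-K)`. The
#' enrichment score is the extremum of the walk; the normalized score and
#' permutation p-value come from gene-label permutations of matching sign.
#'
#' @param genes Character vector of unique gene ids, sorted by decreasing
#'   ranking statistic.
#' @param stats Numeric ranking statistics aligned with `genes`
#'   (non-increasing).
#' @param set Character vector: the gene set.
#' @param weight Exponent on `|stat|` for hit increments (default 1).
#' @param n_perm Gene-label permutations for NES/p (default 1000).
#' @param seed Integer seed for the permutations.
#' @return A list (class `gsea_record`) with `set_id` (attr), `ES`, `NES`,
#'   `p_perm`, `leading_edge`, `size`.
#' @export
preranked_gsea <- function(genes, stats, set, weight = 1, n_perm = 1000,
                           seed = 1) {
  stopifnot(length(genes) == length(stats), !anyDuplicated(genes))
  if (is.unsorted(rev(stats))) stop("`stats` must be sorted non-increasing")
  hit <- genes %in% set
  K <- sum(hit)
  if (K < 3) {
    warning("set has fewer than 3 genes in the ranked universe: skipped")
    return(NULL)
  }
  N <- length(genes)
  if (K == N) {
    return(structure(list(ES = 0, NES = 0, p_perm = 1,
                          leading_edge = character(), size = K),
                     class = "gsea_record"))
  }
  es_of <- function(hit_idx) {
    w <- abs(stats[hit_idx])^weight
    if (sum(w) == 0) w <- rep(1, length(w))  # all-zero stats: unweighted
    inc <- rep(-1 / (N - K), N)
    inc[hit_idx] <- w / sum(w)
    walk <- cumsum(inc)
    i <- which.max(abs(walk))
    walk[i]
  }
  walk_extreme <- function(hit_idx) {
    w <- abs(stats[hit_idx])^weight
    if (sum(w) == 0) w <- rep(1, length(w))
    inc <- rep(-1 / (N - K), N)
    inc[hit_idx] <- w / sum(w)
    cumsum(inc)
  }
  walk <- walk_extreme(which(hit))
  i_ext <- which.max(abs(walk))
  es <- walk[i_ext]
  hit_pos <- which(hit)
  leading <- if (es >= 0) genes[hit_pos[hit_pos <= i_ext]]
             else genes[hit_pos[hit_pos >= i_ext]]
  perm_es <- local_seed_eval(derive_seed(seed, "gsea"), {
    vapply(seq_len(n_perm), function(i) es_of(sort(sample.int(N, K))), 0)
  })
  same <- perm_es[sign(perm_es) == sign(es) | perm_es == 0]
  p <- (1 + sum(abs(same) >= abs(es))) / (1 + length(same))
  nes <- if (length(same) && mean(abs(same)) > 0) es / mean(abs(same)) else 0
  structure(list(ES = es, NES = nes, p_perm = p,
                 leading_edge = leading, size = K),
            class = "gsea_record")
}

#' Run preranked GSEA over a collection with BH adjustment
#'
#' @inheritParams preranked_gsea
#' @param collection A `geneset_collection`.
#' @return A data.frame (set_id, source, size, ES, NES, p_perm, q,
#'   leading_edge as comma-joined genes) sorted by decreasing |NES|.
#' @export
preranked_gsea_collection <- function(genes, stats, collection, weight = 1,
                                      n_perm = 1000, seed = 1) {
  recs <- lapply(names(collection$sets), function(id) {
    r <- suppressWarnings(
      preranked_gsea(genes, stats, collection$sets[[id]], weight = weight,
                     n_perm = n_perm, seed = derive_seed(seed, "gseaset", id)))
    if (is.null(r)) return(NULL)
    data.frame(set_id = id, source = collection$source, size = r$size,
               ES = r$ES, NES = r$NES, p_perm = r$p_perm,
               leading_edge = paste(r$leading_edge, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, recs)
  if (is.null(out)) return(out)
  out$q <- stats::p.adjust(out$p_perm, "BH")
  out <- out[order(-abs(out$NES)), , drop = FALSE]
  rownames(out) <- NULL
  out
}
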