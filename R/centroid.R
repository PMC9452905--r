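#' Fit a nearest-centroid classifier on a gene panel
#'
#' Genes are standardized with training-data means and SDs; each class
#' centroid is the class mean of the standardized expression. Panel genes
#' absent from the matrix are dropped with a warning; zero-variance genes
#' are dropped and recorded. Fewer than 3 usable genes is an error (the
#' classifier's input floor).
#'
#' @param expr A lognorm [expression_matrix()] (genes x samples) or plain
#'   matrix.
#' @param labels Character vector of class labels aligned with the columns
#'   of `expr`.
#' @param genes Character vector: the gene panel.
#' @param class_pos Positive class (default `"NR"`, nonresponders).
#' @param class_neg Negative class (default `"R"`).
#' @return An object of class `centroid_model`.
#' @export
fit_nearest_centroid <- function(expr, labels, genes,
                                 class_pos = "NR", class_neg = "R") {
  X <- as_plain_matrix(expr)
  stopifnot(length(labels) == ncol(X))
  if (!all(c(class_pos, class_neg) %in% labels)) {
    stop("both classes must be present in `labels`")
  }
  missing <- setdiff(genes, rownames(X))
  if (length(missing)) {
    warning(length(missing), " panel gene(s) absent from the matrix: dropped")
  }
  genes <- intersect(genes, rownames(X))
  keep <- labels %in% c(class_pos, class_neg)
  X <- X[genes, keep, drop = FALSE]
  labels <- labels[keep]
  mu <- rowMeans(X)
  sd <- apply(X, 1L, stats::sd)
  dropped <- genes[sd < 1e-12]
  genes <- genes[sd >= 1e-12]
  if (length(genes) < 3) stop("fewer than 3 usable panel genes remain")
  Z <- (X[genes, , drop = FALSE] - mu[genes]) / sd[genes]
  structure(list(
    genes = genes, class_pos = class_pos, class_neg = class_neg,
    scale = list(mean = mu[genes], sd = sd[genes]),
    centroid_pos = rowMeans(Z[, labels == class_pos, drop = FALSE]),
    centroid_neg = rowMeans(Z[, labels == class_neg, drop = FALSE]),
    dropped_zero_var = dropped), class = "centroid_model")
}

#' Continuous nearest-centroid prediction score
#'
#' `z = d(x, centroid_neg) - d(x, centroid_pos)` with Euclidean distance on
#' standardized genes: larger scores mean closer to the positive
#' (nonresponder) centroid.
#'
#' @param model A `centroid_model`.
#' @param x Named numeric vector (one sample) or a genes x samples matrix.
#' @return Numeric score(s).
#' @export
prediction_score <- function(model, x) {
  if (is.matrix(x)) {
    return(apply(x, 2L, function(col) prediction_score(model, col)))
  }
  v <- (x[model$genes] - model$scale$mean) / model$scale$sd
  d_pos <- sqrt(sum((v - model$centroid_pos)^2))
  d_neg <- sqrt(sum((v - model$centroid_neg)^2))
  unname(d_neg - d_pos)
}

#' Midrank Mann-Whitney AUC
#'
#' AUC of `score` for separating the positive class, identical to the
#' probability that a random positive outranks a random negative (ties
#' counted half).
#'
#' @param score Numeric scores.
#' @param positive Logical vector: positive-class membership.
#' @return AUC in \[0, 1\].
#' @export
auc_midrank <- function(score, positive) {
  ok <- !is.na(score)
  score <- score[ok]; positive <- positive[ok]
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(score)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Ordered (FPR, TPR) points over all score thresholds.
roc_points <- function(score, positive) {
  ord <- order(score, decreasing = TRUE)
  s <- score[ord]; y <- positive[ord]
  tp <- cumsum(y); fp <- cumsum(!y)
  last <- !duplicated(rev(s))  # keep the last index of each tied block
  keep <- rev(last)
  data.frame(threshold = c(Inf, s[keep]),
             fpr = c(0, fp[keep] / sum(!positive)),
             tpr = c(0, tp[keep] / sum(positive)))
}

#' Wilson score confidence interval for a binomial proportion
#'
#' The score interval without continuity correction, the convention used for
#' the sensitivity/specificity intervals reported by classification tests.
#'
#' @param successes Number of successes (0..n).
#' @param n Number of trials (>= 1).
#' @param conf Confidence level (default 0.95).
#' @return Numeric `c(lo, hi)`.
#' @export
#' @examples
#' wilson_ci(7, 7)  # c(0.6457, 1) -> the printed 65-100%
wilson_ci <- function(successes, n, conf = 0.95) {
  if (n < 1) stop("n must be >= 1")
  stopifnot(successes >= 0, successes <= n)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  phat <- successes / n
  denom <- 1 + z^2 / n
  center <- (phat + z^2 / (2 * n)) / denom
  half <- z * sqrt(phat * (1 - phat) / n + z^2 / (4 * n^2)) / denom
  c(lo = max(0, center - half), hi = min(1, center + half))
}

#' Welch t-test p-value for a ROC score separation
#'
#' Two-sided Welch t (Satterthwaite degrees of freedom) comparing the
#' continuous prediction scores between the two classes.
#'
#' @param z Numeric scores.
#' @param labels Class labels.
#' @param class_pos,class_neg Class names (defaults NR / R).
#' @return Two-sided p-value.
#' @export
roc_pvalue_welch <- function(z, labels, class_pos = "NR", class_neg = "R") {
  a <- z[labels == class_pos]
  b <- z[labels == class_neg]
  if (length(a) < 2 || length(b) < 2) stop("need >= 2 samples per class")
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    return(if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0)
  }
  stats::t.test(a, b)$p.value
}

#' Nearest-centroid multiple random validation
#'
#' Repeatedly splits the cohort into stratified random train/test halves
#' (`train_frac` of each class trains, the rest is held out), fits the
#' centroid model on the training split and scores the held-out samples.
#' Each sample's continuous prediction score is the mean over the
#' repetitions in which it was held out; ROC, AUC (midrank Mann-Whitney with
#' a stratified bootstrap percentile CI), Welch t p-value and
#' sensitivity/specificity at the Youden-optimal cutoff (Wilson CIs) are
#' computed on these aggregated scores.
#'
#' @inheritParams fit_nearest_centroid
#' @param n_rep Number of random splits (default 100).
#' @param train_frac Training fraction per class (default 2/3).
#' @param seed Integer seed (drives the split RNG deterministically).
#' @param n_boot Bootstrap replicates for the AUC CI (default 2000; 0
#'   disables).
#' @return A list of class `validation_report`: z, labels, roc, auc, auc_ci,
#'   p_roc, sens, spec, sens_ci, spec_ci, cutoff, n_rep, train_frac, seed,
#'   all_held_out.
#' @export
multiple_random_validation <- function(expr, labels, genes, n_rep = 100,
                                       train_frac = 2 / 3, seed = 1,
                                       class_pos = "NR", class_neg = "R",
                                       n_boot = 2000) {
  stopifnot(n_rep >= 1, train_frac > 0, train_frac < 1)
  X <- as_plain_matrix(expr)
  stopifnot(length(labels) == ncol(X))
  keep <- labels %in% c(class_pos, class_neg)
  X <- X[, keep, drop = FALSE]
  labels <- labels[keep]
  genes <- intersect(genes, rownames(X))
  if (length(genes) < 3) stop("fewer than 3 panel genes measured")
  Xg <- X[genes, , drop = FALSE]
  y <- as.integer(labels == class_pos)
  if (sum(y) < 2 || sum(1 - y) < 2) stop("each class needs >= 2 samples")

  core <- cpp_mrv(Xg, y, as.integer(n_rep), train_frac,
                  derive_seed(seed, "split", class_pos),
                  derive_seed(seed, "split", class_neg))
  z <- ifelse(core$zcnt > 0, core$zsum / core$zcnt, NA_real_)
  names(z) <- colnames(Xg)
  all_held_out <- all(core$zcnt > 0)
  if (!all_held_out) {
    warning("some samples were never held out; their scores are NA")
  }
  ok <- !is.na(z)
  zs <- z[ok]; pos <- y[ok] == 1
  auc <- auc_midrank(zs, pos)
  roc <- roc_points(zs, pos)
  youden <- which.max(roc$tpr - roc$fpr)
  cutoff <- roc$threshold[youden]
  pred_pos <- zs >= cutoff
  sens_k <- sum(pred_pos & pos); sens_n <- sum(pos)
  spec_k <- sum(!pred_pos & !pos); spec_n <- sum(!pos)

  auc_ci <- c(NA_real_, NA_real_)
  if (n_boot > 0) {
    auc_ci <- local_seed_eval(derive_seed(seed, "aucboot"), {
      ip <- which(pos); ineg <- which(!pos)
      bs <- vapply(seq_len(n_boot), function(i) {
        sp <- sample(ip, length(ip), TRUE)
        sn <- sample(ineg, length(ineg), TRUE)
        auc_midrank(c(zs[sp], zs[sn]),
                    c(rep(TRUE, length(sp)), rep(FALSE, length(sn))))
      }, 0)
      stats::quantile(bs, c(0.025, 0.975), names = FALSE)
    })
  }

  structure(list(
    z = z, labels = labels, roc = roc, auc = auc,
    auc_ci = c(lo = auc_ci[1L], hi = auc_ci[2L]),
    p_roc = roc_pvalue_welch(zs, labels[ok], class_pos, class_neg),
    cutoff = cutoff,
    sens = sens_k / sens_n, sens_ci = wilson_ci(sens_k, sens_n),
    spec = spec_k / spec_n, spec_ci = wilson_ci(spec_k, spec_n),
    n_rep = n_rep, train_frac = train_frac, seed = seed,
    class_pos = class_pos, class_neg = class_neg,
    all_held_out = all_held_out), class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf(paste0(
    "<validation_report> n=%d, AUC=%.3f (%.3f-%.3f), p(Welch)=%.3g\n",
    "  sens=%.1f%% (%.1f-%.1f), spec=%.1f%% (%.1f-%.1f) at cutoff %.3f\n"),
    length(x$z), x$auc, x$auc_ci[1L], x$auc_ci[2L], x$p_roc,
    100 * x$sens, 100 * x$sens_ci[1L], 100 * x$sens_ci[2L],
    100 * x$spec, 100 * x$spec_ci[1L], 100 * x$spec_ci[2L], x$cutoff))
  invisible(x)
}

#' AUC of a gene panel under multiple random validation
#'
#' Thin fast path used by the screening and elimination stages: runs the
#' split/score core and returns only the aggregated-score AUC.
#'
#' @inheritParams multiple_random_validation
#' @return AUC in \[0, 1\].
#' @export
panel_auc <- function(expr, labels, genes, n_rep = 50, train_frac = 2 / 3,
                      seed = 1, class_pos = "NR", class_neg = "R") {
  X <- as_plain_matrix(expr)
  keep <- labels %in% c(class_pos, class_neg)
  X <- X[, keep, drop = FALSE]
  labels <- labels[keep]
  genes <- intersect(genes, rownames(X))
  if (length(genes) < 3) stop("fewer than 3 panel genes measured")
  y <- as.integer(labels == class_pos)
  core <- cpp_mrv(X[genes, , drop = FALSE], y, as.integer(n_rep), train_frac,
                  derive_seed(seed, "split", class_pos),
                  derive_seed(seed, "split", class_neg))
  z <- ifelse(core$zcnt > 0, core$zsum / core$zcnt, NA_real_)
  auc_midrank(z, y == 1)
}

#' Convert prediction scores to nonresponse probabilities
#'
#' One-covariate logistic regression of nonresponder status on the
#' continuous prediction score. Complete separation is flagged and the
#' coefficients are clipped at `clip`.
#'
#' @param z Numeric prediction scores.
#' @param labels Class labels.
#' @param class_pos Positive (nonresponder) class.
#' @param clip Coefficient bound applied on separation (default 20).
#' @param max_iter IRLS iteration cap (default 100).
#' @return A list of class `risk_probability`: intercept, slope,
#'   probability (per sample), separated (flag), converged.
#' @export
score_to_probability <- function(z, labels, class_pos = "NR", clip = 20,
                                 max_iter = 100) {
  y <- as.integer(labels == class_pos)
  if (all(y == 1) || all(y == 0)) stop("both classes must be present")
  if (stats::var(z) == 0) {
    # constant score carries no information: slope 0, probability = prevalence
    return(structure(list(intercept = stats::qlogis(mean(y)), slope = 0,
                          probability = rep(mean(y), length(z)),
                          separated = FALSE, converged = TRUE),
                     class = "risk_probability"))
  }
  sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm(y ~ z, family = stats::binomial(),
               control = stats::glm.control(maxit = max_iter)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        sep <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  if (!fit$converged) stop("logistic fit failed to converge after ", max_iter,
                           " iterations (deviance ", signif(fit$deviance, 4), ")")
  b <- unname(stats::coef(fit))
  if (any(abs(b) > clip)) sep <- TRUE
  b <- pmin(pmax(b, -clip), clip)
  structure(list(intercept = b[1L], slope = b[2L],
                 probability = stats::plogis(b[1L] + b[2L] * z),
                 separated = sep, converged = fit$converged),
            class = "risk_probability")
}
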