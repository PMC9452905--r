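#' Kaplan-Meier product-limit estimate
#'
#' Backed by [survival::survfit()]; censored observations at an event time
#' are counted at risk for that event (events before censorings at equal
#' times). The median is the first time the survival curve drops to or
#' below 0.5 (NA when it never does).
#'
#' @param times Non-negative follow-up times.
#' @param events Event indicators (1 = event, 0 = censored).
#' @return A list of class `km_curve`: time, n_risk, n_event, n_censor,
#'   survival, median_survival.
#' @export
km_estimate <- function(times, events) {
  stopifnot(length(times) > 0, length(times) == length(events),
            all(times >= 0), all(events %in% c(0, 1)))
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  med <- unname(summary(fit)$table["median"])
  structure(list(time = fit$time, n_risk = fit$n.risk,
                 n_event = fit$n.event, n_censor = fit$n.censor,
                 survival = fit$surv,
                 median_survival = if (is.na(med)) NA_real_ else med),
            class = "km_curve")
}

#' Two-group log-rank test
#'
#' Standard (O - E)^2 / V chi-square with one degree of freedom, summing the
#' hypergeometric mean and variance of group-A events over the distinct
#' event times. The signed standardized statistic `z = (O - E) / sqrt(V)`
#' (positive when group A has excess events) is also returned; it drives
#' the maximally selected cutpoint scan.
#'
#' @param timesA,eventsA,timesB,eventsB Per-group follow-up data.
#' @return A list of class `logrank_result`: chi2, df (1), p, z.
#' @export
logrank_test <- function(timesA, eventsA, timesB, eventsB) {
  stopifnot(length(timesA) > 0, length(timesB) > 0)
  time <- c(timesA, timesB)
  event <- c(eventsA, eventsB)
  grpA <- c(rep(TRUE, length(timesA)), rep(FALSE, length(timesB)))
  if (sum(event) == 0) {
    return(structure(list(chi2 = 0, df = 1L, p = 1, z = 0),
                     class = "logrank_result"))
  }
  dt <- sort(unique(time[event == 1]))
  O <- E <- V <- 0
  for (t in dt) {
    at <- time >= t
    n <- sum(at)
    nA <- sum(at & grpA)
    d <- sum(event == 1 & time == t)
    dA <- sum(event == 1 & time == t & grpA)
    O <- O + dA
    E <- E + d * nA / n
    if (n > 1) V <- V + d * (nA / n) * (1 - nA / n) * (n - d) / (n - 1)
  }
  if (V <= 0) {
    return(structure(list(chi2 = 0, df = 1L, p = 1, z = 0),
                     class = "logrank_result"))
  }
  z <- (O - E) / sqrt(V)
  chi2 <- z^2
  structure(list(chi2 = chi2, df = 1L, p = stats::pchisq(chi2, 1, lower.tail = FALSE),
                 z = z), class = "logrank_result")
}

#' Dichotomize a score for survival comparison
#'
#' `method = "median"` cuts at the sample median with ties assigned to the
#' low group (scores <= median are "low"). `method = "maxstat"` scans every
#' candidate cutpoint leaving at least `minprop` of the samples on each
#' side and picks the one maximizing the absolute standardized log-rank
#' statistic (the maximally selected rank statistic). The log-rank p-value
#' at a maximally selected cutpoint is anti-conservative (the cutpoint was
#' chosen to maximize the statistic); the returned object carries a
#' `selection_bias_warning` field stating this.
#'
#' @param scores Numeric per-sample scores.
#' @param method `"median"` or `"maxstat"`.
#' @param times,events Survival data (required for `"maxstat"`).
#' @param minprop Minimum group proportion for `"maxstat"` (default 0.1).
#' @return A list of class `dichotomy`: method, cutpoint, group (factor
#'   `"low"`/`"high"`), and for maxstat the scan statistics and the bias
#'   warning.
#' @export
dichotomize <- function(scores, method = c("median", "maxstat"),
                        times = NULL, events = NULL, minprop = 0.1) {
  method <- match.arg(method)
  if (length(unique(scores)) < 2) stop("constant scores: no valid split")
  if (method == "median") {
    cut <- stats::median(scores)
    group <- factor(ifelse(scores <= cut, "low", "high"),
                    levels = c("low", "high"))
    if (length(unique(group)) < 2) stop("median split leaves one group empty")
    return(structure(list(method = method, cutpoint = cut, group = group,
                          minprop = NA_real_), class = "dichotomy"))
  }
  if (is.null(times) || is.null(events)) {
    stop("maxstat requires `times` and `events`")
  }
  n <- length(scores)
  lo_min <- ceiling(minprop * n)
  cand <- sort(unique(scores))
  cand <- cand[-length(cand)]  # a cut at the max would leave "high" empty
  stat <- vapply(cand, function(c) {
    low <- scores <= c
    if (sum(low) < lo_min || sum(!low) < lo_min) return(NA_real_)
    abs(logrank_test(times[low], events[low], times[!low], events[!low])$z)
  }, 0)
  if (all(is.na(stat))) stop("no admissible cutpoint at minprop = ", minprop)
  cut <- cand[which.max(stat)]
  group <- factor(ifelse(scores <= cut, "low", "high"),
                  levels = c("low", "high"))
  structure(list(method = method, cutpoint = cut, group = group,
                 minprop = minprop,
                 scan = data.frame(cutpoint = cand, abs_z = stat),
                 selection_bias_warning = paste(
                   "log-rank p at a maximally selected cutpoint is",
                   "anti-conservative; interpret with caution")),
            class = "dichotomy")
}

#' Univariate Cox proportional-hazards regression
#'
#' Backed by [survival::coxph()] with Breslow tie handling (which makes the
#' score test at beta = 0 coincide with the log-rank chi-square for a binary
#' covariate). Monotone partial likelihood (infinite beta) is flagged and
#' the coefficient clipped at `clip`; a constant covariate returns beta = 0,
#' HR = 1.
#'
#' @param x Numeric covariate.
#' @param times,events Survival data (>= 1 event).
#' @param max_iter Newton-Raphson iteration cap (default 50).
#' @param tol Convergence tolerance (default 1e-9).
#' @param clip Coefficient bound applied on monotone likelihood (default 20).
#' @return A list of class `cox_fit`: beta, hr, ci95, p_wald, se, n_iter,
#'   converged, monotone.
#' @export
cox_univariate <- function(x, times, events, max_iter = 50, tol = 1e-9,
                           clip = 20) {
  stopifnot(length(x) == length(times), sum(events) >= 1)
  if (stats::var(x) == 0) {
    return(structure(list(beta = 0, hr = 1, ci95 = c(lo = 1, hi = 1),
                          p_wald = 1, se = NA_real_, n_iter = 0L,
                          converged = TRUE, monotone = FALSE),
                     class = "cox_fit"))
  }
  monotone <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(times, events) ~ x, ties = "breslow",
                    control = survival::coxph.control(iter.max = max_iter,
                                                      eps = tol)),
    warning = function(w) {
      msg <- conditionMessage(w)
      if (grepl("infinite|converge|beta may be infinite", msg)) {
        monotone <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  beta <- unname(stats::coef(fit))
  se <- sqrt(unname(stats::vcov(fit)[1L, 1L]))
  if (monotone) beta <- pmin(pmax(beta, -clip), clip)
  zq <- stats::qnorm(0.975)
  structure(list(beta = beta, hr = exp(beta),
                 ci95 = c(lo = exp(beta - zq * se), hi = exp(beta + zq * se)),
                 p_wald = 2 * stats::pnorm(-abs(beta / se)), se = se,
                 n_iter = fit$iter, converged = !monotone,
                 monotone = monotone), class = "cox_fit")
}
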