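#' Parameters of the synthetic ground truth
#'
#' Defines the planted structure shared by the single-cell and bulk
#' generators: marker programs (a log2-scale mean shift applied to planted
#' genes inside their subcluster), an abundance shift (logit-scale
#' difference in the resistance-subtype fraction between nonresponders and
#' responders), and a survival link (log-hazard per standard deviation of
#' the true resistance-subtype fraction).
#'
#' @param marker_effect Log2 mean shift of planted marker genes in their own
#'   subcluster (default 2: planted genes are 4x up in their subcluster).
#' @param abundance_shift Logit shift of the resistance-subtype fraction in
#'   nonresponders relative to responders (default 1.5 logits). The response
#'   subtype receives the same shift in responders.
#' @param hazard_coef Log hazard ratio per SD of the true resistance fraction
#'   (default 0.7).
#' @param censor_rate Target fraction of censored survival times (default 0.2).
#' @param n_marker_genes Planted marker genes per role (default 30).
#' @param dispersion Negative-binomial dispersion (1/size) shared by all
#'   genes (default 0.5).
#' @return A list of class `synthetic_truth_params`.
#' @export
synthetic_truth_params <- function(marker_effect = 2, abundance_shift = 1.5,
                                   hazard_coef = 0.7, censor_rate = 0.2,
                                   n_marker_genes = 30, dispersion = 0.5) {
  stopifnot(marker_effect >= 0, censor_rate >= 0, censor_rate < 1,
            n_marker_genes >= 1, dispersion > 0)
  structure(list(marker_effect = marker_effect,
                 abundance_shift = abundance_shift,
                 hazard_coef = hazard_coef,
                 censor_rate = censor_rate,
                 n_marker_genes = n_marker_genes,
                 dispersion = dispersion),
            class = "synthetic_truth_params")
}

#' Generate a single-cell dataset with planted subcluster marker programs
#'
#' Counts are drawn gene-wise from a negative binomial whose log-mean is
#' shifted by `marker_effect` (log2 scale) for planted genes inside their
#' own subcluster. Subcluster 1 plays the resistance role and subcluster 2
#' the response role; cells from nonresponder patients are over-represented
#' in the resistance subcluster by `abundance_shift` logits (and responder
#' cells in the response subcluster).
#'
#' @param n_genes Number of genes (>= 200).
#' @param n_cells Number of cells (>= 100).
#' @param n_subclusters Number of subclusters (>= 2).
#' @param truth_params A [synthetic_truth_params()] object.
#' @param seed Integer seed; identical seed and parameters reproduce the
#'   output bit for bit.
#' @param n_patients Number of patients, split between R and NR (default 8).
#' @return A list with `expr` (counts [expression_matrix()]), `cell_meta`
#'   (data.frame: cell_id, patient_id, response, cluster_id, subcluster_id)
#'   and `truth` (a `synthetic_truth` list recording planted subcluster
#'   roles, planted genes per role, per-subtype mean profiles and the
#'   generative parameters).
#' @export
generate_single_cell_dataset <- function(n_genes, n_cells, n_subclusters = 3,
                                         truth_params = synthetic_truth_params(),
                                         seed = 1, n_patients = 8) {
  stopifnot(n_genes >= 200, n_cells >= 100, n_subclusters >= 2,
            inherits(truth_params, "synthetic_truth_params"))
  tp <- truth_params
  n_roles <- min(2L, n_subclusters)
  if (tp$n_marker_genes * n_roles > n_genes) {
    stop("planted gene lists exceed n_genes")
  }
  local_seed_eval(derive_seed(seed, "sc"), {
    genes <- sprintf("G%04d", seq_len(n_genes))
    cells <- sprintf("CELL%05d", seq_len(n_cells))
    subclusters <- sprintf("SC%d", seq_len(n_subclusters))
    roles <- rep("neutral", n_subclusters)
    roles[1L] <- "resistance"
    if (n_subclusters >= 2L) roles[2L] <- "response"
    names(roles) <- subclusters

    # disjoint planted marker programs for the resistance and response roles
    planted <- list(
      resistance = genes[seq_len(tp$n_marker_genes)],
      response = if (n_roles >= 2L)
        genes[tp$n_marker_genes + seq_len(tp$n_marker_genes)] else character()
    )

    patients <- sprintf("P%02d", seq_len(n_patients))
    pat_resp <- rep(c("NR", "R"), length.out = n_patients)
    cell_patient <- sample(patients, n_cells, replace = TRUE)
    cell_resp <- pat_resp[match(cell_patient, patients)]

    # subcluster assignment probabilities, tilted by response status
    base_p <- rep(1 / n_subclusters, n_subclusters)
    tilt <- function(p, idx, shift) {
      p[idx] <- stats::plogis(stats::qlogis(p[idx]) + shift)
      p / sum(p)
    }
    p_nr <- tilt(base_p, 1L, tp$abundance_shift)
    p_r <- if (n_subclusters >= 2L) tilt(base_p, 2L, tp$abundance_shift) else base_p
    cell_sub <- character(n_cells)
    is_nr <- cell_resp == "NR"
    cell_sub[is_nr] <- sample(subclusters, sum(is_nr), TRUE, prob = p_nr)
    cell_sub[!is_nr] <- sample(subclusters, sum(!is_nr), TRUE, prob = p_r)

    # baseline gene means (log-normal, scRNA-like sparsity) and NB sampling
    mu0 <- exp(stats::rnorm(n_genes, mean = log(0.3), sd = 1))
    names(mu0) <- genes
    size <- 1 / tp$dispersion

    # genes x subclusters matrix of NB means (the subtype profiles)
    profiles <- matrix(mu0, n_genes, n_subclusters,
                       dimnames = list(genes, subclusters))
    fold <- 2^tp$marker_effect
    profiles[planted$resistance, 1L] <- profiles[planted$resistance, 1L] * fold
    if (length(planted$response)) {
      profiles[planted$response, 2L] <- profiles[planted$response, 2L] * fold
    }

    counts <- matrix(0L, n_genes, n_cells, dimnames = list(genes, cells))
    for (s in seq_len(n_subclusters)) {
      idx <- which(cell_sub == subclusters[s])
      if (!length(idx)) next
      counts[, idx] <- stats::rnbinom(n_genes * length(idx), size = size,
                                      mu = profiles[, s])
    }

    cell_meta <- data.frame(
      cell_id = cells, patient_id = cell_patient, response = cell_resp,
      cluster_id = "CT1", subcluster_id = cell_sub,
      stringsAsFactors = FALSE)

    truth <- structure(list(
      planted_subclusters = roles,
      planted_genes = planted,
      marker_effect = tp$marker_effect,
      abundance_shift = tp$abundance_shift,
      hazard_coef = tp$hazard_coef,
      censor_rate = tp$censor_rate,
      dispersion = tp$dispersion,
      subtype_profiles = profiles,
      gene_ids = genes), class = "synthetic_truth")

    list(expr = expression_matrix(counts, "counts"),
         cell_meta = cell_meta, truth = truth)
  })
}

#' Generate a bulk cohort as a mixture of subtype profiles
#'
#' Each sample's expression is a convex mixture of the subtype mean profiles
#' recorded in `sc_truth`, plus Gaussian noise on the log scale. The
#' resistance-subtype fraction is logit-shifted by `abundance_shift` for
#' nonresponders; overall survival follows an exponential hazard whose log
#' equals `hazard_coef` times the standardized true resistance fraction,
#' censored by independent uniform times calibrated to `censor_rate`.
#'
#' @param n_samples Cohort size.
#' @param prop_responders Fraction of responders, in (0, 1).
#' @param sc_truth A `synthetic_truth` from [generate_single_cell_dataset()].
#' @param noise_sd SD of log-scale Gaussian noise (default 0.3).
#' @param seed Integer seed.
#' @param ne_frac Fraction of samples relabeled NE (not evaluable); NE
#'   samples keep their survival fields (default 0).
#' @return A list with `expr` (lognorm [expression_matrix()]), `sample_meta`
#'   (sample_id, response, os_time, os_event, pfs_time, pfs_event) and
#'   `true_fraction` (named vector of the planted resistance fractions).
#' @export
generate_bulk_cohort <- function(n_samples, prop_responders, sc_truth,
                                 noise_sd = 0.3, seed = 1, ne_frac = 0) {
  stopifnot(inherits(sc_truth, "synthetic_truth"),
            n_samples >= 4, noise_sd >= 0, ne_frac >= 0, ne_frac < 1)
  if (prop_responders <= 0 || prop_responders >= 1) {
    stop("prop_responders must lie strictly inside (0, 1)")
  }
  local_seed_eval(derive_seed(seed, "bulk"), {
    profiles <- sc_truth$subtype_profiles
    n_sub <- ncol(profiles)
    samples <- sprintf("S%04d", seq_len(n_samples))
    n_r <- round(prop_responders * n_samples)
    n_r <- min(max(n_r, 1L), n_samples - 1L)
    response <- c(rep("R", n_r), rep("NR", n_samples - n_r))

    # resistance fraction: baseline logit-normal, shifted for NR
    f0 <- 1 / n_sub
    lf <- stats::qlogis(f0) + stats::rnorm(n_samples, 0, 0.5) +
      sc_truth$abundance_shift * (response == "NR")
    f_res <- stats::plogis(lf)

    # remaining mass split among the other subtypes by a Dirichlet draw
    w <- matrix(0, n_sub, n_samples)
    w[1L, ] <- f_res
    if (n_sub > 1L) {
      g <- matrix(stats::rgamma((n_sub - 1L) * n_samples, shape = 5),
                  n_sub - 1L, n_samples)
      g <- sweep(g, 2L, colSums(g), "/")
      w[-1L, ] <- sweep(g, 2L, 1 - f_res, "*")
    }

    mixed <- profiles %*% w
    vals <- log1p(mixed) + stats::rnorm(length(mixed), 0, noise_sd)
    dimnames(vals) <- list(rownames(profiles), samples)

    # exponential survival linked to the standardized resistance fraction
    zf <- as.numeric(scale(f_res))
    base_rate <- log(2) / 30  # median OS 30 months at zf = 0
    os_rate <- base_rate * exp(sc_truth$hazard_coef * zf)
    os_t <- stats::rexp(n_samples, rate = os_rate)
    pfs_rate <- 2 * base_rate * exp(sc_truth$hazard_coef * zf)
    pfs_t <- stats::rexp(n_samples, rate = pfs_rate)

    censor_with <- function(t, rates, target) {
      if (target <= 0) {
        return(list(time = t, event = rep(1L, length(t))))
      }
      # choose the uniform upper bound u so the expected censored fraction
      # E[(1 - exp(-rate*u)) / (rate*u)] matches the target
      pc <- function(u) mean((1 - exp(-rates * u)) / (rates * u)) - target
      u <- stats::uniroot(pc, c(1e-6, 1e6), tol = 1e-8)$root
      cens <- stats::runif(length(t), 0, u)
      list(time = pmin(t, cens), event = as.integer(t <= cens))
    }
    os <- censor_with(os_t, os_rate, sc_truth$censor_rate)
    pfs <- censor_with(pfs_t, pfs_rate, sc_truth$censor_rate)

    if (ne_frac > 0) {
      n_ne <- round(ne_frac * n_samples)
      response[sample(n_samples, n_ne)] <- "NE"
    }

    meta <- data.frame(sample_id = samples, response = response,
                       os_time = os$time, os_event = os$event,
                       pfs_time = pfs$time, pfs_event = pfs$event,
                       stringsAsFactors = FALSE)
    names(f_res) <- samples
    list(expr = expression_matrix(vals, "lognorm"),
         sample_meta = meta, true_fraction = f_res)
  })
}

#' Generate a gene-set collection with planted and decoy sets
#'
#' One set per planted role (resistance/response), optionally diluted with
#' random non-planted genes, plus `n_decoy_sets` random sets drawn from the
#' gene universe.
#'
#' @param sc_truth A `synthetic_truth`.
#' @param n_decoy_sets Number of random decoy sets.
#' @param set_size_range Length-2 integer range of decoy set sizes (>= 3).
#' @param seed Integer seed.
#' @param dilution Number of random extra genes appended to each planted set
#'   (default 0).
#' @return A [geneset_collection()] with source `"synthetic"`.
#' @export
generate_geneset_collection <- function(sc_truth, n_decoy_sets = 20,
                                        set_size_range = c(10, 40),
                                        seed = 1, dilution = 0) {
  stopifnot(inherits(sc_truth, "synthetic_truth"),
            length(set_size_range) == 2L, set_size_range[1L] >= 3)
  genes <- sc_truth$gene_ids
  if (set_size_range[2L] > length(genes)) {
    stop("requested set size exceeds the gene universe")
  }
  local_seed_eval(derive_seed(seed, "gmt"), {
    sets <- list()
    desc <- character()
    planted_all <- unlist(sc_truth$planted_genes, use.names = FALSE)
    for (role in names(sc_truth$planted_genes)) {
      pg <- sc_truth$planted_genes[[role]]
      if (!length(pg)) next
      extra <- if (dilution > 0)
        sample(setdiff(genes, planted_all), dilution) else character()
      id <- paste0("PLANTED_", toupper(role))
      sets[[id]] <- c(pg, extra)
      desc[id] <- paste0("planted ", role, " program")
    }
    if (n_decoy_sets > 0) {
      sizes <- sample(set_size_range[1L]:set_size_range[2L], n_decoy_sets,
                      replace = TRUE)
      for (i in seq_len(n_decoy_sets)) {
        id <- sprintf("DECOY_%03d", i)
        sets[[id]] <- sample(genes, sizes[i])
        desc[id] <- "random decoy set"
      }
    }
    geneset_collection(sets, name = "synthetic", source = "synthetic",
                       descriptions = desc)
  })
}
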