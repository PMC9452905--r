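#' Pipeline configuration
#'
#' All tunable parameters of the end-to-end workflow with their defaults:
#' the detection/fold-change prefilters (`min_pct` 0.1, `logfc_threshold`
#' 0.25), the 500-gene enrichment cap, the 3-gene classifier floor, the
#' 10,000 normalization scale factor, the screen thresholds (alpha 0.05,
#' passing fraction 0.5), the per-subtype fold-change gates and the
#' validator settings. Unknown keys raise an error naming the key. The
#' configuration round-trips through YAML unchanged.
#'
#' @param ... Named overrides of the defaults.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    seed = 1,
    simulate = TRUE,
    # synthetic data conditions
    n_genes = 1200, n_cells = 800, n_subclusters = 3,
    n_samples = 150, prop_responders = 39 / 172,
    marker_effect = 2, abundance_shift = 1.5, hazard_coef = 0.7,
    censor_rate = 0.2, n_marker_genes = 30, dispersion = 0.5,
    noise_sd = 0.3, n_decoy_sets = 20, set_dilution = 5,
    # normalization and marker detection
    scale_factor = 1e4, min_pct = 0.1, logfc_threshold = 0.25,
    marker_adjust = "bonferroni",
    # enrichment
    enrich_max_genes = 500, enrich_top = 10, enrich_q_cutoff = 0.05,
    min_set_genes = 3,
    # screen
    screen_n_rep = 100, screen_alpha = 0.05, screen_frac = 0.5,
    screen_alpha_adj = 0.05,
    # fold-change gates: one per subcluster role
    gate_resistance = c("gt", -0.1), gate_response = c("lt", 0.1),
    gate_neutral = c("gt", -0.3),
    # elimination and selection
    cycle_n_rep = 50, min_panel_size = 3, select_delta = 0.01,
    select_target_size = NULL,
    # reporting validator
    validate_n_rep = 100, train_frac = 2 / 3,
    # survival
    dichotomy_method = "median", maxstat_minprop = 0.1,
    # response mapping (RECIST categories to classes)
    response_mapping = list(CR = "R", PR = "R", SD = "NR", PD = "NR",
                            NE = "NE"))
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown)) stop("unknown config key(s): ",
                            paste(unknown, collapse = ", "))
  defaults[names(over)] <- over
  structure(defaults, class = c("pipeline_config", "list"))
}

#' Write / read a pipeline configuration as YAML
#'
#' @param config A [pipeline_config()].
#' @param path File path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path, precision = 17)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

#' Run the end-to-end signature-discovery workflow
#'
#' Executes simulate -> markers/DE -> enrichment -> predictiveness screen ->
#' subcluster localization -> candidate assembly -> greedy elimination ->
#' signature validation -> survival analysis on synthetic data with known
#' ground truth, writing every artifact plus a manifest (input hashes,
#' seeds, package version) to `out_dir`. Re-running with the same
#' configuration reproduces all numeric outputs exactly.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if absent).
#' @param quiet Suppress progress messages.
#' @return A list of class `pipeline_run` with every stage result and
#'   `out_dir`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = tempfile("run_"),
                         quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  seed <- config$seed

  say("[simulate] %d genes x %d cells, %d-sample cohort",
      config$n_genes, config$n_cells, config$n_samples)
  tp <- synthetic_truth_params(
    marker_effect = config$marker_effect,
    abundance_shift = config$abundance_shift,
    hazard_coef = config$hazard_coef, censor_rate = config$censor_rate,
    n_marker_genes = config$n_marker_genes, dispersion = config$dispersion)
  sc <- generate_single_cell_dataset(config$n_genes, config$n_cells,
                                     config$n_subclusters, tp, seed = seed)
  bulk <- generate_bulk_cohort(config$n_samples, config$prop_responders,
                               sc$truth, noise_sd = config$noise_sd,
                               seed = seed)
  gmt <- generate_geneset_collection(sc$truth, config$n_decoy_sets,
                                     seed = seed,
                                     dilution = config$set_dilution)
  write_gmt(gmt, file.path(out_dir, "collection.gmt"))
  utils::write.table(sc$cell_meta, file.path(out_dir, "cell_meta.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(bulk$sample_meta, file.path(out_dir, "sample_meta.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  say("[markers] log-normalize and find subcluster markers")
  lognorm <- log_normalize(sc$expr, config$scale_factor)
  subs <- stats::setNames(sc$cell_meta$subcluster_id, sc$cell_meta$cell_id)
  markers <- find_all_markers(lognorm, subs, min_pct = config$min_pct,
                              logfc_threshold = config$logfc_threshold,
                              adjust = config$marker_adjust)

  say("[enrich] over-representation of top-%d marker lists",
      config$enrich_max_genes)
  measured <- rownames(lognorm)
  gmt_f <- filter_min_genes(gmt, measured, config$min_set_genes)
  enriched_map <- list()
  for (cid in names(markers)) {
    if (!nrow(markers[[cid]])) next
    dl <- rank_and_truncate(markers[[cid]], "padj_asc",
                            config$enrich_max_genes, id = cid)
    enr <- overrepresentation(dl$records$gene, gmt_f, measured,
                              q_cutoff = config$enrich_q_cutoff,
                              top = config$enrich_top)
    if (nrow(enr)) enriched_map[[cid]] <- enr$set_id
  }
  if (!length(enriched_map)) stop("stage enrich: no enriched sets found")

  say("[screen] %d (list, set) pairs against the cohort",
      sum(lengths(enriched_map)))
  resp <- bulk$sample_meta$response
  screen <- screen_genesets(enriched_map, gmt_f, bulk$expr, resp,
                            n_rep = config$screen_n_rep,
                            train_frac = config$train_frac, seed = seed)
  utils::write.table(screen, file.path(out_dir, "screen.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  verdicts <- flag_de_lists(screen, alpha = config$screen_alpha,
                            frac = config$screen_frac)
  utils::write.table(verdicts, file.path(out_dir, "verdicts.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  say("[locate] GSVA localization of predictive sets")
  sig_ids <- unique(screen$set_id[screen$roc_p_adj < config$screen_alpha_adj])
  located <- NULL
  if (length(sig_ids)) {
    # localize the predictive sets of the most strongly flagged DE list
    sig_v <- verdicts[verdicts$significant, , drop = FALSE]
    top_list <- if (nrow(sig_v)) {
      sig_v$de_list_id[order(-sig_v$frac_pass, sig_v$de_list_id)][1L]
    } else unique(screen$de_list_id)[1L]
    loc_ids <- intersect(enriched_map[[top_list]], sig_ids)
    if (!length(loc_ids)) loc_ids <- sig_ids
    sig_col <- geneset_collection(gmt_f$sets[loc_ids], name = "significant",
                                  source = gmt_f$source)
    located <- locate_predictive_subcluster(lognorm, subs, sig_col)
    jsonlite::write_json(list(subcluster_id = located$subcluster_id,
                              ambiguous = located$ambiguous,
                              per_set = located$per_set),
                         file.path(out_dir, "localization.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }

  say("[build] candidate assembly and greedy elimination")
  if (!length(sig_ids)) stop("stage build: no set passes the adjusted screen")
  union_gl <- build_union_genelist(screen, gmt_f,
                                   alpha_adj = config$screen_alpha_adj)
  roles <- sc$truth$planted_subclusters
  gates <- fold_change_gates(
    names(roles),
    vapply(roles, function(r) config[[paste0("gate_", r)]][1L], ""),
    as.numeric(vapply(roles, function(r) config[[paste0("gate_", r)]][2L], "")))
  de_tables <- lapply(names(roles), function(scid) {
    cells <- sc$cell_meta$cell_id[sc$cell_meta$subcluster_id == scid]
    nr <- intersect(cells, sc$cell_meta$cell_id[sc$cell_meta$response == "NR"])
    r <- intersect(cells, sc$cell_meta$cell_id[sc$cell_meta$response == "R"])
    data.frame(gene = measured,
               avg_log2FC = avg_log2fc(lognorm, nr, r),
               stringsAsFactors = FALSE)
  })
  names(de_tables) <- names(roles)
  intersect_gl <- build_intersect_genelist(de_tables, gates)
  candidates <- assemble_candidates(union_gl, intersect_gl,
                                    rownames(bulk$expr))
  trace <- greedy_backward_elimination(
    candidates$genelist, bulk$expr, resp, n_rep = config$cycle_n_rep,
    train_frac = config$train_frac, min_size = config$min_panel_size,
    seed = seed)
  utils::write.table(trace$iterations[, c("iteration", "panel_size",
                                          "removed_gene", "best_auc")],
                     file.path(out_dir, "cycle_trace.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  panel <- select_signature(trace, target_size = config$select_target_size,
                            delta = config$select_delta)
  writeLines(panel$genes, file.path(out_dir, "signature_panel.txt"))

  say("[validate] %d-gene panel, %d-split validation", panel$size,
      config$validate_n_rep)
  report <- multiple_random_validation(
    bulk$expr, resp, panel$genes, n_rep = config$validate_n_rep,
    train_frac = config$train_frac, seed = derive_seed(seed, "final"))
  risk <- score_to_probability(report$z[!is.na(report$z)],
                               report$labels[!is.na(report$z)])
  jsonlite::write_json(
    list(auc = report$auc, auc_ci = unname(report$auc_ci),
         p_roc = report$p_roc, sens = report$sens,
         sens_ci = unname(report$sens_ci), spec = report$spec,
         spec_ci = unname(report$spec_ci),
         logistic = list(intercept = risk$intercept, slope = risk$slope)),
    file.path(out_dir, "validation.json"), auto_unbox = TRUE, digits = NA)

  say("[survive] signature score stratification")
  meta <- bulk$sample_meta  # NE samples stay in the survival analysis
  sig_scores <- gsva_score(bulk$expr, list(signature = panel$genes))[1L, ]
  dic <- dichotomize(sig_scores, config$dichotomy_method,
                     times = meta$os_time, events = meta$os_event,
                     minprop = config$maxstat_minprop)
  lr <- logrank_test(meta$os_time[dic$group == "high"],
                     meta$os_event[dic$group == "high"],
                     meta$os_time[dic$group == "low"],
                     meta$os_event[dic$group == "low"])
  cox <- cox_univariate(as.numeric(scale(sig_scores)), meta$os_time,
                        meta$os_event)
  jsonlite::write_json(
    list(method = dic$method, cutpoint = dic$cutpoint,
         logrank_chi2 = lr$chi2, logrank_p = lr$p,
         cox_beta = cox$beta, cox_hr = cox$hr, cox_p = cox$p_wald),
    file.path(out_dir, "survival.json"), auto_unbox = TRUE, digits = NA)

  write_config(config, file.path(out_dir, "config.yaml"))
  files <- setdiff(list.files(out_dir), "manifest.json")
  manifest <- list(
    package_version = as.character(utils::packageVersion("icbsig")),
    seed = seed,
    hashes = as.list(tools::md5sum(file.path(out_dir, files))))
  names(manifest$hashes) <- files
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE)

  structure(list(
    config = config, out_dir = out_dir, sc = sc, bulk = bulk,
    collection = gmt, markers = markers, enriched_map = enriched_map,
    screen = screen, verdicts = verdicts, located = located,
    candidates = candidates, trace = trace, panel = panel,
    report = report, risk = risk, dichotomy = dic, logrank = lr, cox = cox),
    class = "pipeline_run")
}

#' Human-readable summary of a pipeline run
#'
#' @param run A `pipeline_run` (or its output directory).
#' @param path Optional file to write the report to.
#' @return The report lines, invisibly when written to a file.
#' @export
report_summary <- function(run, path = NULL) {
  stopifnot(inherits(run, "pipeline_run"))
  v <- run$verdicts
  lines <- c(
    "Signature discovery run summary",
    "===============================",
    sprintf("Seed: %d | cohort: %d samples (%d R / %d NR)",
            run$config$seed, nrow(run$bulk$sample_meta),
            sum(run$bulk$sample_meta$response == "R"),
            sum(run$bulk$sample_meta$response == "NR")),
    "",
    sprintf("Screen: %d (list, set) evaluations over %d DE lists",
            nrow(run$screen), length(unique(run$screen$de_list_id))),
    paste(sprintf("  %s: %d/%d sets pass -> %s", v$de_list_id, v$n_pass,
                  v$n_sets, ifelse(v$significant, "SIGNIFICANT", "ns")),
          collapse = "\n"),
    "",
    sprintf("Located subcluster: %s%s",
            if (is.null(run$located)) "none" else
              ifelse(run$located$ambiguous, "ambiguous",
                     run$located$subcluster_id), ""),
    sprintf("Candidates: %d genes; cycle: %d evaluations over %d iterations",
            length(run$candidates$genelist), run$trace$n_evaluations,
            nrow(run$trace$iterations)),
    sprintf("Panel: %d genes (rule %s), AUC at selection %.3f",
            run$panel$size, run$panel$selection_rule,
            run$panel$auc_at_selection),
    sprintf("Validation: AUC %.3f (%.3f-%.3f), Welch p %.3g",
            run$report$auc, run$report$auc_ci[1L], run$report$auc_ci[2L],
            run$report$p_roc),
    sprintf("  sens %.0f%% (%.0f-%.0f%%), spec %.0f%% (%.0f-%.0f%%)",
            100 * run$report$sens, 100 * run$report$sens_ci[1L],
            100 * run$report$sens_ci[2L], 100 * run$report$spec,
            100 * run$report$spec_ci[1L], 100 * run$report$spec_ci[2L]),
    sprintf("Survival: log-rank chi2 %.2f (p %.3g), Cox HR %.2f (p %.3g)",
            run$logrank$chi2, run$logrank$p, run$cox$hr, run$cox$p_wald))
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat(paste(report_summary(x), collapse = "\n"), "\n")
  invisible(x)
}
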