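# End-to-end orchestration: load inputs, reconstruct the hallmark network,
# call differential interactions, build and pool modules, score diagnostics
# and prognostics, profile hallmark enrichment, screen druggability, and
# write stage TSVs plus a JSON summary.

#' Default pipeline configuration values
#'
#' Thresholds default to the reference analysis settings: q-value cut-offs
#' 0.10/0.90, observation-frequency floor 0.20, module size 10, pooling
#' overlap 0.70, diagnostic sensitivity/specificity 0.90, log-rank p 0.01,
#' enrichment adjusted-p 0.01, activity threshold 1 FPKM.
#'
#' @return Named list of defaults; any entry can be overridden in the config
#'   passed to \code{\link{run_pipeline}}.
#' @export
pipeline_defaults <- function() {
  list(cancer_type = "NA", network_dialect = "edge_list",
       binarize_rule = "fixed_threshold", tau = 1.0, alpha = 0.5,
       q_low = 0.10, q_high = 0.90, min_freq = 0.20,
       min_module_size = 10L, pooling_overlap = 0.70,
       diagnostic_threshold = 0.90, n_per_class = 30L, max_sims = 200L,
       logrank_p = 0.01, enrich_alpha = 0.01,
       min_samples = 30L, force = FALSE, seed = 1L)
}

#' Run the full differential-interactome pipeline
#'
#' @param config named list. Required keys: \code{expression},
#'   \code{phenotype}, \code{network}, \code{gene_sets} (input paths).
#'   Optional: \code{survival}, \code{drugs} (paths) and any override of
#'   \code{\link{pipeline_defaults}}.
#' @param out_dir output directory (created if missing). Writes
#'   \code{dHCPPIs.tsv}, \code{modules.tsv}, \code{modules.sif},
#'   \code{modules.graphml}, \code{diagnostics.tsv}, \code{prognostics.tsv},
#'   \code{enrichment.tsv}, \code{druggability.tsv} and
#'   \code{summary.json}.
#' @return Invisibly, the summary list written to \code{summary.json}.
#' @export
run_pipeline <- function(config, out_dir) {
  required <- c("expression", "phenotype", "network", "gene_sets")
  missing_keys <- setdiff(required, names(config))
  if (length(missing_keys) > 0L) {
    stop("config is missing required key(s): ",
         paste(missing_keys, collapse = ", "), call. = FALSE)
  }
  cfg <- utils::modifyList(pipeline_defaults(), config)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  ds <- load_expression(cfg$expression, cfg$phenotype, cfg$cancer_type)
  net_raw <- load_network(cfg$network, dialect = cfg$network_dialect)
  sets <- load_gene_sets(cfg$gene_sets)
  surv <- if (!is.null(cfg$survival)) load_survival(cfg$survival) else NULL
  drugs <- if (!is.null(cfg$drugs)) load_drug_table(cfg$drugs) else NULL

  hallmark_genes <- unique(unlist(sets, use.names = FALSE))
  net <- reconstruct_network(net_raw, hallmark_genes, rownames(ds$values))

  diffs <- run_differential_interactome(
    ds, net, rule = cfg$binarize_rule, tau = cfg$tau, alpha = cfg$alpha,
    q_low = cfg$q_low, q_high = cfg$q_high, min_freq = cfg$min_freq,
    min_samples = cfg$min_samples, force = cfg$force)
  utils::write.table(as.data.frame(diffs), file.path(out_dir, "dHCPPIs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  dihcps <- extract_dihcps(diffs)
  mods <- build_modules(diffs, cancer_type = cfg$cancer_type,
                        min_size = cfg$min_module_size)
  n_candidate <- length(mods)
  mods <- pool_modules(mods, overlap_threshold = cfg$pooling_overlap)
  modules_table(mods, file.path(out_dir, "modules.tsv"))
  write_modules_graph(mods, sif_path = file.path(out_dir, "modules.sif"),
                      graphml_path = file.path(out_dir, "modules.graphml"))

  diag_rows <- list(); prog_rows <- list()
  diag_ok <- prog_ok <- stats::setNames(logical(length(mods)),
                                        vapply(mods, `[[`, character(1), "name"))
  prog_results <- list()
  for (i in seq_along(mods)) {
    m <- mods[[i]]
    dr <- evaluate_diagnostic(ds, m$members, module_name = m$name,
                              n_per_class = cfg$n_per_class,
                              max_sims = cfg$max_sims,
                              threshold = cfg$diagnostic_threshold,
                              seed = derive_seed(cfg$seed, i, "diag"))
    diag_ok[m$name] <- dr$is_diagnostic
    diag_rows[[i]] <- data.frame(
      module = m$name, n_simulations = dr$n_simulations,
      mean_sensitivity = dr$mean_sensitivity,
      mean_specificity = dr$mean_specificity,
      top3_variance_fraction = dr$mean_top3_variance_fraction,
      is_diagnostic = dr$is_diagnostic, stringsAsFactors = FALSE)
    if (!is.null(surv)) {
      pr <- tryCatch(
        evaluate_prognostic(ds, surv, m$members, module_name = m$name,
                            p_cutoff = cfg$logrank_p),
        error = function(e) NULL)
      if (!is.null(pr)) {
        prog_ok[m$name] <- pr$is_prognostic
        prog_results[[m$name]] <- pr
        prog_rows[[length(prog_rows) + 1L]] <- data.frame(
          module = m$name, hazard_ratio = pr$hazard_ratio,
          logrank_chi2 = pr$logrank_chi2, logrank_p = pr$logrank_p,
          ridge_fallback = pr$ridge, is_prognostic = pr$is_prognostic,
          stringsAsFactors = FALSE)
      }
    }
  }
  write_stage_table(diag_rows, file.path(out_dir, "diagnostics.tsv"),
                    c("module", "n_simulations", "mean_sensitivity",
                      "mean_specificity", "top3_variance_fraction",
                      "is_diagnostic"))
  write_stage_table(prog_rows, file.path(out_dir, "prognostics.tsv"),
                    c("module", "hazard_ratio", "logrank_chi2", "logrank_p",
                      "ridge_fallback", "is_prognostic"))

  enr <- if (length(mods) > 0) {
    hallmark_profile(mods, sets, universe = net$nodes,
                     alpha = cfg$enrich_alpha)
  } else NULL
  write_stage_table(if (is.null(enr)) list() else list(enr),
                    file.path(out_dir, "enrichment.tsv"),
                    c("module", "hallmark", "count", "p", "p_adj",
                      "significant"))

  # druggability: diagnostic, prognostic (when survival data exist) and
  # uniformly activated or suppressed modules
  drug_rows <- list(); reports <- list()
  if (!is.null(drugs)) {
    for (m in mods) {
      eligible <- diag_ok[m$name] &&
        (is.null(surv) || isTRUE(prog_ok[m$name])) && m$state != "MIXED"
      if (!eligible) next
      rep_ <- screen_module(m, drugs)
      reports[[length(reports) + 1L]] <- rep_
      drug_rows[[length(drug_rows) + 1L]] <- data.frame(
        module = m$name, state = m$state,
        n_druggable = length(rep_$druggable_genes),
        n_undruggable = length(rep_$undruggable_genes),
        druggable_fraction = rep_$druggable_fraction,
        druggable_genes = paste(rep_$druggable_genes, collapse = ","),
        drugs = paste(sort(unique(unlist(rep_$matched_drugs))), collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  write_stage_table(drug_rows, file.path(out_dir, "druggability.tsv"),
                    c("module", "state", "n_druggable", "n_undruggable",
                      "druggable_fraction", "druggable_genes", "drugs"))
  spec <- if (length(reports) > 0) drug_specificity(reports) else NULL

  summary <- list(
    cancer_type = cfg$cancer_type,
    seed = cfg$seed,
    thresholds = cfg[c("q_low", "q_high", "min_freq", "min_module_size",
                       "pooling_overlap", "diagnostic_threshold",
                       "logrank_p", "enrich_alpha", "tau", "binarize_rule")],
    network = list(n_edges = net$n_edges, n_nodes = net$n_nodes),
    n_edges_tested = nrow(diffs),
    n_dhcppis = sum(diffs$state %in% c("ACTIVATED", "SUPPRESSED")),
    n_activated = sum(diffs$state == "ACTIVATED"),
    n_suppressed = sum(diffs$state == "SUPPRESSED"),
    n_dihcps = length(dihcps$all),
    n_candidate_modules = n_candidate,
    n_modules = length(mods),
    n_diagnostic = sum(diag_ok),
    n_prognostic = sum(prog_ok),
    n_both = sum(diag_ok & prog_ok),
    n_druggability_eligible = length(reports),
    mean_druggable_fraction = if (length(reports) > 0) {
      mean(vapply(reports, `[[`, numeric(1), "druggable_fraction"))
    } else NA,
    n_drugs = if (!is.null(spec)) nrow(spec$table) else 0L,
    fraction_drugs_single_cancer = if (!is.null(spec)) spec$fraction_specific else NA)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}

#' @noRd
write_stage_table <- function(rows, path, cols) {
  df <- if (length(rows) > 0) do.call(rbind, rows) else {
    as.data.frame(stats::setNames(rep(list(character(0)), length(cols)), cols))
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
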