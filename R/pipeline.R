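#' Pipeline configuration
#'
#' Collects every stage toggle, threshold and path of the end-to-end
#' screen in one validated object.  The defaults are the pipeline's
#' decision rules: signature cutoffs |log2FC| > 1 and adjusted p < 0.001,
#' candidate rule sRGES < -0.25 with at least 3 strong profiles and a
#' top-100 cap, consensus of the top 5 terms (20 for cell lines) at
#' adjusted p < 0.05, and segment retention at 25 probes for losses, 50
#' for gains, 5 Mb for cnLOH.  Unknown arguments are rejected.
#'
#' @param out_dir Output directory for the stage TSVs and the manifest.
#' @param seed Master seed; every stochastic stage derives from it.
#' @param sim A [sim_config()] describing the synthetic study (its seed is
#'   overridden by `seed`).
#' @param n_datasets Number of synthetic cohorts/signatures to build.
#' @param lfc_cut,alpha_de Signature cutoffs.
#' @param srges_cut,n_strong_min,top_n Candidate-selection rule.
#' @param consensus_k,consensus_k_lines,alpha_enrich Consensus rules for
#'   term and cell-line libraries.
#' @param probes_loss,probes_gain,cnloh_mb Segment retention thresholds.
#' @param n_low Lowest doses entering the low-dose sensitivity score.
#' @param run_reversal,run_enrichment,run_models,run_cn Stage toggles;
#'   stages downstream of a disabled stage are skipped.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = tempfile("revscreen_run_"),
                            seed = 0L,
                            sim = sim_config(),
                            n_datasets = 3,
                            lfc_cut = 1, alpha_de = 0.001,
                            srges_cut = -0.25, n_strong_min = 3, top_n = 100,
                            consensus_k = 5, consensus_k_lines = 20,
                            alpha_enrich = 0.05,
                            probes_loss = 25, probes_gain = 50, cnloh_mb = 5,
                            n_low = 3,
                            run_reversal = TRUE, run_enrichment = TRUE,
                            run_models = TRUE, run_cn = TRUE) {
  stopifnot(inherits(sim, "sim_config"))
  for (nm in c("lfc_cut", "alpha_de", "n_strong_min", "top_n", "consensus_k",
               "consensus_k_lines", "alpha_enrich", "probes_loss",
               "probes_gain", "cnloh_mb", "n_low", "n_datasets")) {
    check_positive(get(nm), nm)
  }
  sim$seed <- as.integer(seed)
  structure(
    list(out_dir = out_dir, seed = as.integer(seed), sim = sim,
         n_datasets = check_count(n_datasets, "n_datasets"),
         lfc_cut = lfc_cut, alpha_de = alpha_de,
         srges_cut = srges_cut, n_strong_min = n_strong_min, top_n = top_n,
         consensus_k = consensus_k, consensus_k_lines = consensus_k_lines,
         alpha_enrich = alpha_enrich,
         probes_loss = probes_loss, probes_gain = probes_gain,
         cnloh_mb = cnloh_mb, n_low = n_low,
         run_reversal = isTRUE(run_reversal),
         run_enrichment = isTRUE(run_enrichment),
         run_models = isTRUE(run_models), run_cn = isTRUE(run_cn)),
    class = "pipeline_config"
  )
}

#' Run the full synthetic screening pipeline
#'
#' Chains the stages end to end on synthetic data: cohort simulation and
#' signature building, reversal screening and candidate selection,
#' enrichment consensus, model-line matching, dose-response sensitivity
#' and biomarker correlation, and copy-number segment filtering with
#' gene-level calls.  Each stage writes its result tables as TSV under
#' `config$out_dir` and is logged with one structured line stating its
#' input/output row counts and the cutoffs applied, so every decision
#' threshold is auditable from the log.  Rerunning with the same
#' configuration and seed reproduces byte-identical outputs.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress per-stage log lines.
#' @return Invisibly, a list with the in-memory stage results
#'   (`signatures`, `srges`, `candidates`, `consensus`, `model_lines`,
#'   `metrics`, `correlations`, `cn`, ...) plus the `manifest` written to
#'   `manifest.json`.
#' @export
run_pipeline <- function(config = pipeline_config(), quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(seed = config$seed,
                   package_version = as.character(utils::packageVersion("revscreen")),
                   config_hash = rlang::hash(unclass(config)[setdiff(names(config), "out_dir")]),
                   stages = list())
  log_stage <- function(stage, msg, rows) {
    manifest$stages[[stage]] <<- rows
    if (!quiet) inform(paste0("[", stage, "] ", msg))
  }
  emit <- function(tbl, file) {
    readr::write_tsv(tbl, file.path(config$out_dir, file))
    nrow(tbl)
  }
  res <- list()

  # --- signatures ---------------------------------------------------------
  cohorts <- lapply(seq_len(config$n_datasets), function(i) {
    generate_expression_cohort(
      config$sim,
      noise_seed = split_seed(config$seed, "cohort_noise") + i
    )
  })
  truth <- cohorts[[1]]$truth
  sigs <- lapply(seq_along(cohorts), function(i) {
    de <- moderated_ttest(cohorts[[i]]$matrix)
    build_signature(de, sprintf("synthetic_%02d", i),
                    lfc_cut = config$lfc_cut, alpha = config$alpha_de)
  })
  res$signatures <- sigs
  sig_rows <- emit(dplyr::bind_rows(lapply(sigs, tidy)), "signatures.tsv")
  log_stage("signatures",
            paste0(config$n_datasets, " cohorts -> ", sig_rows,
                   " signature rows at |log2FC| > ", config$lfc_cut,
                   ", padj < ", config$alpha_de), sig_rows)
  overlap <- intersect_signatures(sigs)
  res$overlap <- overlap
  emit(overlap$top_deg, "shared_top_deg.tsv")

  # --- reversal screen ----------------------------------------------------
  if (config$run_reversal) {
    lib <- generate_perturbation_library(config$sim, truth)
    rges_all <- dplyr::bind_rows(lapply(sigs, function(s) {
      dplyr::mutate(compute_rges_table(s, lib), signature = s$dataset_id)
    }))
    offsets <- estimate_dose_time_offsets(rges_all)
    srges <- rges_all |>
      dplyr::group_by(.data$signature) |>
      dplyr::group_modify(function(df, key) {
        summarize_srges(df, offsets = offsets,
                        strong_cut = config$srges_cut)
      }) |>
      dplyr::ungroup()
    candidates <- select_candidates(srges, top_n = config$top_n,
                                    srges_cut = config$srges_cut,
                                    n_strong_min = config$n_strong_min)
    res$rges <- rges_all; res$srges <- srges; res$candidates <- candidates
    res$offsets <- offsets
    emit(rges_all, "rges.tsv")
    emit(srges, "srges.tsv")
    n_cand <- emit(candidates, "candidates.tsv")
    log_stage("reversal",
              paste0(nrow(rges_all), " profile scores -> ", n_cand,
                     " candidates at sRGES < ", config$srges_cut,
                     ", n_strong >= ", config$n_strong_min,
                     ", top ", config$top_n), n_cand)
  }

  # --- enrichment consensus ----------------------------------------------
  if (config$run_enrichment) {
    gsl <- generate_geneset_library(config$sim, truth)
    enr <- dplyr::bind_rows(lapply(sigs, function(s) {
      dplyr::mutate(
        enrich_query(union(s$up, s$down), gsl,
                     seed = split_seed(config$seed, "null_ranks")),
        signature = s$dataset_id
      )
    }))
    consensus <- build_consensus_list(enr, k = config$consensus_k,
                                      alpha = config$alpha_enrich)
    res$enrichment <- enr; res$consensus <- consensus
    emit(enr, "enrichment.tsv")
    n_terms <- emit(consensus$scores, "consensus_terms.tsv")
    log_stage("enrichment",
              paste0(length(gsl$sets), " sets -> ", n_terms,
                     " consensus terms (top ", config$consensus_k,
                     ", padj < ", config$alpha_enrich, ")"), n_terms)
  }

  # --- model lines, sensitivity, biomarker --------------------------------
  if (config$run_models && config$run_reversal) {
    screen <- generate_viability_screen(config$sim, truth)
    simil <- cellline_similarity(sigs[[1]], screen$expression)
    line_lib <- cellline_geneset_library(screen$expression)
    line_enr <- dplyr::bind_rows(lapply(sigs, function(s) {
      dplyr::mutate(
        enrich_query(union(s$up, s$down), line_lib,
                     seed = split_seed(config$seed, "null_ranks")),
        signature = s$dataset_id
      )
    }))
    line_consensus <- build_consensus_list(line_enr,
                                           k = config$consensus_k_lines,
                                           alpha = config$alpha_enrich)
    model_lines <- select_model_lines(simil, line_consensus,
                                      k = config$consensus_k_lines)
    metrics <- dose_response_metrics(screen$curves, n_low = config$n_low)
    correlations <- biomarker_correlation(
      metrics, cn = screen$cn, expression = screen$expression,
      genes = c(config$sim$biomarker_gene, config$sim$null_biomarker_gene)
    )
    res$screen <- screen; res$similarity <- simil
    res$model_lines <- model_lines
    res$metrics <- metrics; res$correlations <- correlations
    emit(simil, "cellline_similarity.tsv")
    emit(tibble::tibble(cell_line = model_lines), "model_lines.tsv")
    emit(metrics, "sensitivity_metrics.tsv")
    n_cor <- emit(correlations, "biomarker_correlations.tsv")
    log_stage("models",
              paste0(length(model_lines), " model lines; ", n_cor,
                     " biomarker correlations on metric auc"), n_cor)
  }

  # --- copy-number summaries ---------------------------------------------
  if (config$run_cn) {
    segs <- generate_cn_segments(config$sim)
    retained <- filter_cn_segments(segs, probes_loss = config$probes_loss,
                                   probes_gain = config$probes_gain,
                                   cnloh_mb = config$cnloh_mb)
    cn_sum <- gene_level_cn_summary(
      retained, synthetic_gene_coords(config$sim),
      samples = sprintf("P%03d", seq_len(config$sim$n_cn_samples))
    )
    res$segments <- segs; res$retained <- retained; res$cn <- cn_sum
    emit(segs, "segments.tsv")
    n_kept <- emit(retained, "segments_retained.tsv")
    emit(cn_sum$calls, "gene_cn_calls.tsv")
    emit(cn_sum$frequency, "gene_cn_frequency.tsv")
    log_stage("cn",
              paste0(nrow(segs), " segments -> ", n_kept,
                     " retained (loss >= ", config$probes_loss,
                     " probes, gain >= ", config$probes_gain,
                     " probes, cnLOH >= ", config$cnloh_mb, " Mb)"), n_kept)
  }

  manifest$stages <- manifest$stages
  jsonlite::write_json(manifest,
                       file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  res$manifest <- manifest
  invisible(res)
}
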