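#' Run the full synthetic end-to-end pipeline
#'
#' Orchestrates the stages — synthetic data generation, EST library
#' analysis, array QC/normalization, differential expression with Venn
#' partitioning, GO enrichment and qPCR cross-validation — as one
#' reproducible run driven by a single [synth_config()]. Stage outputs are
#' written as TSV files under `out_dir` together with a machine-readable
#' `summary.json`; the returned summary reports every count and percentage
#' the analysis produces (per-condition significant counts, fold-change
#' counts and percentages, Venn sizes, probe-removal percentage,
#' correlation-bin percentages, enrichment tables), each percentage
#' recomputable from the summary's own counts.
#'
#' @param config A [synth_config()] (all stage parameters and seeds flow
#'   from it).
#' @param out_dir Output directory (created if needed); `NULL` skips all
#'   file output.
#' @param stages Character vector of stages to run, a subset of
#'   `c("est", "array", "de", "enrich", "qpcr")`. Stages not listed are
#'   skipped and noted in the summary. `"de"` requires `"array"`;
#'   `"enrich"` and `"qpcr"` require `"de"`.
#' @param alpha,fc_threshold DE thresholds (see [call_de()]).
#' @param sd_band Percentile band retained by [sd_filter()]. The pipeline
#'   default trims only the bottom 1\% (dead/constant spots): with planted
#'   differential expression the most variable probes are the biology, so
#'   an aggressive upper cut would discard true positives. Tighten the
#'   band for data where high variance means artefacts.
#' @param min_identity,min_overlap Clustering thresholds
#'   (see [cluster_ests()]).
#' @param enrichment_threshold,min_total EST enrichment-rule parameters
#'   (see [enrichment_call()]).
#' @param min_set_size Minimum DE genes per tested GO term.
#' @param percentile Normalization percentile (see
#'   [percentile_shift_normalize()]).
#' @param de_method Test used by [call_de()].
#' @return A list of stage results plus `summary` (named list of counts
#'   and percentages) and `skipped` (stages not run).
#' @examples
#' \donttest{
#' res <- run_pipeline(synth_config(n_targets = 200, n_transcripts = 10,
#'                                  n_est_per_library = 60, seed = 7),
#'                     out_dir = NULL, stages = c("array", "de"))
#' res$summary$n_significant
#' }
#' @export
run_pipeline <- function(config = synth_config(),
                         out_dir = NULL,
                         stages = c("est", "array", "de", "enrich", "qpcr"),
                         alpha = 0.001, fc_threshold = 2,
                         sd_band = c(1, 100),
                         min_identity = 0.95, min_overlap = 40,
                         enrichment_threshold = 0.75, min_total = 4,
                         min_set_size = 4, percentile = 50,
                         de_method = "anova") {
  stopifnot(inherits(config, "synth_config"))
  known <- c("est", "array", "de", "enrich", "qpcr")
  bad <- setdiff(stages, known)
  if (length(bad) > 0) {
    input_error("run_pipeline: unknown stage(s): %s", paste(bad, collapse = ", "))
  }
  needs <- list(de = "array", enrich = "de", qpcr = "de")
  for (st in names(needs)) {
    if (st %in% stages && !needs[[st]] %in% stages) {
      input_error("run_pipeline: stage '%s' requires stage '%s'", st, needs[[st]])
    }
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  }
  emit <- function(df, name) {
    if (!is.null(out_dir)) write_tsv(df, file.path(out_dir, name))
  }
  log_stage <- function(fmt, ...) {
    message(sprintf(paste0("[pamparray] ", fmt), ...))
  }

  res <- list(config = config, skipped = setdiff(known, stages))
  summary <- list(seed = config$seed, stages_run = stages,
                  stages_skipped = res$skipped)

  if ("est" %in% stages) {
    log_stage("est: generating and clustering EST libraries")
    est <- generate_est_libraries(config)
    rep <- contig_report(est$ests, min_identity = min_identity,
                         min_overlap = min_overlap,
                         threshold = enrichment_threshold,
                         min_total = min_total)
    res$est <- list(truth = est$truth, ests = rep$ests, contigs = rep$contigs)
    emit(est$truth, "est_truth.tsv")
    emit(rep$contigs[, setdiff(names(rep$contigs), "member_ids")],
         "contig_report.tsv")
    summary$n_est_total <- nrow(est$ests)
    summary$n_est_retained <- nrow(rep$ests)
    summary$n_contigs <- nrow(rep$contigs)
    summary$n_contigs_enriched <- sum(rep$contigs$call != "not_enriched")
  }

  if ("array" %in% stages) {
    log_stage("array: generating scans, QC and normalization")
    arr <- generate_array_experiment(config)
    mat <- background_correct_and_log(arr$spots)
    norm <- percentile_shift_normalize(mat, percentile = percentile)
    filt <- sd_filter(norm, sd_band[1], sd_band[2])
    kept <- norm[filt$retained, , drop = FALSE]
    qc <- probe_pair_qc(kept, arr$probesets[arr$probesets$annotated, ],
                        seed = config$seed + 3L)
    gene <- summarize_gene_level(kept, arr$probesets)
    res$array <- list(experiment = arr, normalized = norm, filter = filt,
                      probe_qc = qc, gene_matrix = gene$matrix,
                      dropped_targets = gene$dropped)
    emit(arr$design, "design.tsv")
    emit(arr$truth, "de_truth.tsv")
    emit(data.frame(target_id = rownames(gene$matrix), gene$matrix,
                    check.names = FALSE), "gene_matrix.tsv")
    emit(filt$report, "probe_filter_report.tsv")
    emit(qc$bins, "probe_pair_bins.tsv")
    summary$n_probes_total <- filt$report$n_total
    summary$n_probes_removed <- filt$report$n_removed
    summary$pct_probes_removed <- filt$report$pct_removed
    summary$probe_pair_bins <- qc$bins
    summary$n_genes_summarized <- nrow(gene$matrix)
  }

  if ("de" %in% stages) {
    log_stage("de: per-treatment testing and Venn partition")
    treatments <- setdiff(config$conditions, "control")
    de <- lapply(treatments, function(cond) {
      call_de(res$array$gene_matrix, res$array$experiment$design, cond,
              alpha = alpha, fc_threshold = fc_threshold, method = de_method)
    })
    names(de) <- treatments
    res$de <- de
    for (cond in treatments) {
      emit(de[[cond]], sprintf("de_%s.tsv", cond))
    }
    summary$n_significant <- vapply(de, function(d) sum(d$significant), 1L)
    summary$n_passes_fc <- vapply(de, function(d) sum(d$passes_fc), 1L)
    summary$pct_passes_fc <- mapply(function(nfc, nsig) {
      if (nsig > 0) format_percent(nfc, nsig) else NA_character_
    }, summary$n_passes_fc, summary$n_significant)
    if (length(treatments) >= 2) {
      sig_sets <- lapply(de, function(d) d$target_id[d$significant])
      vp <- venn_partition(sig_sets[[1]], sig_sets[[2]])
      res$venn <- vp
      emit(vp$counts, "venn_counts.tsv")
      summary$venn <- vp$counts
    }
  }

  if ("enrich" %in% stages) {
    log_stage("enrich: GO term over-representation")
    background <- rownames(res$array$gene_matrix)
    enrich <- lapply(res$de, function(d) {
      de_ids <- d$target_id[d$significant]
      ann <- generate_go_annotation(background, de_ids,
                                    seed = config$seed + 4L)
      enrich_terms(de_ids, ann, background, min_set_size = min_set_size)
    })
    res$enrich <- enrich
    for (cond in names(enrich)) {
      emit(enrich[[cond]], sprintf("enrichment_%s.tsv", cond))
    }
    summary$n_terms_tested <- vapply(enrich, nrow, 1L)
  }

  if ("qpcr" %in% stages) {
    log_stage("qpcr: Pfaffl quantification and cross-platform correlation")
    q <- generate_qpcr(config, res$array$experiment$truth)
    qfc <- qpcr_fold_changes(q$cq, reference_gene = config$reference_gene)
    # pair with array fold changes for the same genes
    rows <- data.frame(gene = unique(qfc$gene), stringsAsFactors = FALSE)
    for (cond in unique(qfc$condition)) {
      d <- res$de[[cond]]
      rows[[paste0("fc_array_", cond)]] <-
        d$signed_fc[match(rows$gene, d$target_id)]
      qq <- qfc[qfc$condition == cond, ]
      rows[[paste0("fc_qpcr_", cond)]] <- qq$signed_fc[match(rows$gene, qq$gene)]
    }
    corr <- cross_platform_correlation(rows)
    res$qpcr <- list(cq = q$cq, truth = q$truth, fold_changes = qfc,
                     paired = rows, correlation = corr)
    emit(q$cq, "qpcr_cq.tsv")
    emit(rows, "qpcr_vs_array.tsv")
    emit(corr, "qpcr_correlation.tsv")
    summary$qpcr_spearman <- stats::setNames(corr$rho, corr$condition)
  }

  res$summary <- summary
  if (!is.null(out_dir)) {
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  res
}
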