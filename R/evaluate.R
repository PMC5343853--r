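#' Closed-loop recovery scoring against planted truth
#'
#' Benchmarking utilities that generate synthetic data under a
#' configuration, run the corresponding pipeline stages, and score the
#' calls against the planted ground truth. Because a single library pair
#' contains only a few dozen transcripts, the EST scores are aggregated
#' over replicate generations (differing only in seed) so the reported
#' rates carry small Monte-Carlo error; the array scores already average
#' over thousands of targets in one experiment.
#'
#' @name evaluate
NULL

#' Sensitivity and false-positive rate of differential-expression calls
#'
#' Generates an array experiment, runs background correction,
#' normalization, SD filtering and gene-level summarization, calls DE per
#' treatment, and scores the calls against the plant. Sensitivity is
#' measured on planted targets at or above `min_abs_log2fc`; the
#' false-positive rate on targets with no planted effect in any condition
#' (spike-ins excluded).
#'
#' @param config A [synth_config()].
#' @param alpha Significance level for [call_de()].
#' @param min_abs_log2fc Magnitude floor defining the "strong" planted
#'   set scored for sensitivity (default log2(8)).
#' @param sd_band Percentile band for [sd_filter()].
#' @return data.frame per treatment: condition, n_strong, n_recalled,
#'   sensitivity, n_null, n_false, fpr.
#' @export
evaluate_de_recovery <- function(config, alpha = 0.001,
                                 min_abs_log2fc = log2(8),
                                 sd_band = c(1, 100)) {
  arr <- generate_array_experiment(config)
  mat <- percentile_shift_normalize(background_correct_and_log(arr$spots))
  filt <- sd_filter(mat, sd_band[1], sd_band[2])
  g <- summarize_gene_level(mat[filt$retained, , drop = FALSE],
                            arr$probesets)$matrix
  nulls <- setdiff(rownames(g), c(arr$truth$target_id, arr$spikes$target_id))
  out <- lapply(setdiff(config$conditions, "control"), function(cond) {
    de <- call_de(g, arr$design, cond, alpha = alpha)
    called <- de$target_id[de$significant]
    truth <- arr$truth[arr$truth$condition == cond, ]
    strong <- intersect(truth$target_id[abs(truth$true_log2fc) >= min_abs_log2fc],
                        rownames(g))
    data.frame(
      condition = cond,
      n_strong = length(strong),
      n_recalled = sum(strong %in% called),
      sensitivity = mean(strong %in% called),
      n_null = length(nulls),
      n_false = sum(nulls %in% called),
      fpr = mean(nulls %in% called),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}

#' Sensitivity and precision of the EST library-enrichment rule
#'
#' Generates `n_replicates` independent EST library pairs (seeds
#' `config$seed + 0 ... n_replicates - 1`), runs the full contig pipeline
#' on each, attributes every contig to its majority transcript, and pools
#' the calls. Sensitivity is scored on planted transcripts with at least
#' `min_est` realized ESTs (tiny transcripts cannot carry a reliable
#' frequency signal); precision over all enriched calls.
#'
#' @param config A [synth_config()].
#' @param n_replicates Number of replicate library pairs to pool.
#' @param min_est Minimum realized EST count for a planted transcript to
#'   enter the sensitivity denominator.
#' @return One-row data.frame: n_planted_eligible, n_recalled,
#'   sensitivity, n_called, n_true_calls, precision.
#' @export
evaluate_est_recovery <- function(config, n_replicates = 8, min_est = 10) {
  n_eligible <- 0L
  n_recalled <- 0L
  n_called <- 0L
  n_true <- 0L
  for (r in seq_len(n_replicates)) {
    cfg_r <- config
    cfg_r$seed <- config$seed + (r - 1L)
    est <- generate_est_libraries(cfg_r)
    rep <- contig_report(est$ests)
    members <- rep$ests
    majority <- vapply(split(members$transcript_id, members$contig_id),
                       function(v) names(sort(table(v), decreasing = TRUE))[1],
                       "")
    calls <- rep$contigs
    calls$transcript_id <- majority[calls$contig_id]
    truth <- est$truth
    truth$n_total <- truth$n_est_bacterial + truth$n_est_viral
    planted <- truth$transcript_id[truth$enriched_in != "none"]
    eligible <- truth$transcript_id[truth$enriched_in != "none" &
                                      truth$n_total >= min_est]
    called <- calls$transcript_id[calls$call != "not_enriched"]
    n_eligible <- n_eligible + length(eligible)
    n_recalled <- n_recalled + sum(eligible %in% called)
    n_called <- n_called + length(called)
    n_true <- n_true + sum(called %in% planted)
  }
  data.frame(
    n_planted_eligible = n_eligible,
    n_recalled = n_recalled,
    sensitivity = n_recalled / n_eligible,
    n_called = n_called,
    n_true_calls = n_true,
    precision = n_true / n_called,
    stringsAsFactors = FALSE
  )
}
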