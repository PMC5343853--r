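#' Pfaffl efficiency-corrected qPCR quantification and cross-platform
#' validation
#'
#' Relative expression ratios are computed by the Pfaffl method
#' (`E_target^dCq_target / E_ref^dCq_ref`, dCq oriented control minus
#' treated so induction gives a ratio above 1) with 18S as the default
#' housekeeping reference, converted to the signed fold-change convention,
#' and compared to microarray fold changes by Spearman rank correlation.
#'
#' @name qpcr_validation
NULL

#' Pfaffl relative expression ratio
#'
#' @param E_target,E_ref Amplification efficiencies per cycle, in (1, 2].
#' @param dCq_target,dCq_ref Quantification-cycle differences in cycles,
#'   oriented control minus treated.
#' @return `E_target^dCq_target / E_ref^dCq_ref` (vectorized).
#' @examples
#' pfaffl_ratio(2, 3, 2, 0)  # 8
#' @export
pfaffl_ratio <- function(E_target, dCq_target, E_ref, dCq_ref) {
  if (any(E_target <= 1 | E_target > 2) || any(E_ref <= 1 | E_ref > 2)) {
    input_error("pfaffl_ratio: efficiencies must lie in (1, 2]")
  }
  E_target^dCq_target / E_ref^dCq_ref
}

#' Per-gene signed fold changes from a Cq table
#'
#' Technical/biological replicate Cq values are averaged on the Cq scale
#' per gene and condition; dCq is the control mean minus the treated mean;
#' the Pfaffl ratio against the reference gene is then reported on the
#' signed linear scale of [signed_fold_change()].
#'
#' @param records data.frame `gene`, `sample_id`, `condition`, `Cq`,
#'   optionally `efficiency` (default 2 when absent or NA).
#' @param reference_gene Housekeeping gene name (default `"18S"`); must be
#'   measured in every sample.
#' @return data.frame `gene`, `condition`, `ratio`, `signed_fc` for every
#'   non-control condition.
#' @export
qpcr_fold_changes <- function(records, reference_gene = "18S") {
  assert_columns(records, c("gene", "sample_id", "condition", "Cq"),
                 "qPCR table")
  if (is.null(records$efficiency)) {
    records$efficiency <- 2
  }
  records$efficiency[is.na(records$efficiency)] <- 2
  samples <- unique(records$sample_id)
  ref_samples <- unique(records$sample_id[records$gene == reference_gene])
  missing <- setdiff(samples, ref_samples)
  if (length(missing) > 0) {
    input_error("qpcr_fold_changes: reference gene '%s' missing in sample(s): %s",
                reference_gene, paste(missing, collapse = ", "))
  }
  if (!"control" %in% records$condition) {
    input_error("qpcr_fold_changes: no control condition in the table")
  }

  mean_cq <- stats::aggregate(Cq ~ gene + condition, data = records, FUN = mean)
  eff <- stats::aggregate(efficiency ~ gene, data = records, FUN = mean)
  conditions <- setdiff(unique(records$condition), "control")
  genes <- setdiff(unique(records$gene), reference_gene)

  cq_of <- function(g, cond) {
    v <- mean_cq$Cq[mean_cq$gene == g & mean_cq$condition == cond]
    if (length(v) != 1) {
      input_error("qpcr_fold_changes: gene '%s' has no Cq for condition '%s'",
                  g, cond)
    }
    v
  }
  out <- do.call(rbind, lapply(conditions, function(cond) {
    ratio <- vapply(genes, function(g) {
      pfaffl_ratio(
        E_target = eff$efficiency[eff$gene == g],
        dCq_target = cq_of(g, "control") - cq_of(g, cond),
        E_ref = eff$efficiency[eff$gene == reference_gene],
        dCq_ref = cq_of(reference_gene, "control") - cq_of(reference_gene, cond)
      )
    }, 1.0)
    data.frame(gene = genes, condition = cond, ratio = ratio,
               signed_fc = ifelse(ratio >= 1, ratio, -1 / ratio),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Cross-platform correlation between array and qPCR fold changes
#'
#' @param rows data.frame with one gene per row and paired fold-change
#'   columns named `fc_array_<condition>` and `fc_qpcr_<condition>`.
#' @param method `"spearman"` (default, average ranks for ties) or
#'   `"pearson"`.
#' @return data.frame `condition`, `rho`, `n`; a constant column yields
#'   `NA` with a warning.
#' @export
cross_platform_correlation <- function(rows, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  array_cols <- grep("^fc_array_", names(rows), value = TRUE)
  conditions <- sub("^fc_array_", "", array_cols)
  if (length(conditions) == 0) {
    input_error("cross_platform_correlation: no fc_array_* columns found")
  }
  out <- do.call(rbind, lapply(conditions, function(cond) {
    x <- rows[[paste0("fc_array_", cond)]]
    y <- rows[[paste0("fc_qpcr_", cond)]]
    if (is.null(y)) {
      input_error("cross_platform_correlation: missing fc_qpcr_%s column", cond)
    }
    ok <- stats::complete.cases(x, y)
    x <- x[ok]; y <- y[ok]
    if (length(x) < 3) {
      input_error("cross_platform_correlation: need >= 3 genes for '%s'", cond)
    }
    rho <- if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      warning(sprintf("constant fold-change column for '%s'; correlation undefined",
                      cond))
      NA_real_
    } else {
      stats::cor(x, y, method = method)
    }
    data.frame(condition = cond, rho = rho, n = length(x),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Packaged cross-platform reference data set
#'
#' The published comparison of microarray and RT-qPCR signed fold changes
#' for twelve immune-relevant genes in *Sparus aurata* macrophages after
#' 6 h of LPS or PGN stimulation. Used to validate the array platform:
#' both treatments show a Spearman correlation above 0.7 between the two
#' measurement methods.
#'
#' @return data.frame `gene`, `fc_array_LPS`, `fc_array_PGN`,
#'   `fc_qpcr_LPS`, `fc_qpcr_PGN`.
#' @examples
#' cross_platform_correlation(crossplatform_reference())
#' @export
crossplatform_reference <- function() {
  path <- system.file("extdata", "crossplatform_fc_reference.tsv",
                      package = "pamparray", mustWork = TRUE)
  read_tsv(path)
}
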