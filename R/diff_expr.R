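#' Differential expression with signed fold changes and Venn partitioning
#'
#' Each treatment is contrasted separately against control: a two-group
#' one-way ANOVA (or Kruskal-Wallis) p-value per gene, a signed linear
#' fold change from the log2 group means, the `p < alpha` significance
#' filter and the `|FC| > fc_threshold` intensity filter, then a set
#' partition of the two treatments' significant genes into exclusive and
#' common transcripts.
#'
#' @name diff_expr
NULL

#' Signed linear fold change from log2 means
#'
#' The linear ratio `2^(mean_trt - mean_ctl)` is reported as is when at
#' least 1, and as the negative reciprocal when below 1, so down-regulation
#' carries a negative sign and `|FC| >= 1` always.
#'
#' @param mean_trt,mean_ctl Log2 group means (vectorized).
#' @return Signed fold changes.
#' @examples
#' signed_fold_change(c(1, -1, 0), 0)  # 2, -2, 1
#' @export
signed_fold_change <- function(mean_trt, mean_ctl) {
  if (any(!is.finite(mean_trt)) || any(!is.finite(mean_ctl))) {
    input_error("signed_fold_change: means must be finite")
  }
  ratio <- 2^(mean_trt - mean_ctl)
  ifelse(ratio >= 1, ratio, -1 / ratio)
}

#' Two-group differential-expression test
#'
#' One-way fixed-effects ANOVA for two groups (an F test with 1 and
#' `n - 2` degrees of freedom, identical to the squared pooled-variance t
#' test), or Kruskal-Wallis as the non-parametric alternative.
#'
#' Degenerate inputs: when both groups have zero within-group variance the
#' p-value is 1 for equal means and 0 for unequal means (perfect
#' separation with no residual noise).
#'
#' @param ctl_values,trt_values Numeric vectors, each of length >= 2.
#' @param method `"anova"` (default) or `"kruskal"`.
#' @return The p-value.
#' @export
de_test <- function(ctl_values, trt_values, method = c("anova", "kruskal")) {
  method <- match.arg(method)
  if (length(ctl_values) < 2 || length(trt_values) < 2) {
    input_error("de_test: need >= 2 values per group")
  }
  if (method == "kruskal") {
    values <- c(ctl_values, trt_values)
    groups <- rep(c("ctl", "trt"), c(length(ctl_values), length(trt_values)))
    return(stats::kruskal.test(values, factor(groups))$p.value)
  }
  mat <- matrix(c(ctl_values, trt_values), nrow = 1)
  row_f_test(mat, rep(c(0L, 1L), c(length(ctl_values), length(trt_values))))
}

# vectorized two-group one-way ANOVA over the rows of a matrix;
# group is a 0/1 vector over columns
#' @noRd
row_f_test <- function(mat, group) {
  g0 <- group == 0L
  g1 <- !g0
  n0 <- sum(g0)
  n1 <- sum(g1)
  m0 <- rowMeans(mat[, g0, drop = FALSE])
  m1 <- rowMeans(mat[, g1, drop = FALSE])
  grand <- (n0 * m0 + n1 * m1) / (n0 + n1)
  ss_between <- n0 * (m0 - grand)^2 + n1 * (m1 - grand)^2
  ss_within <- rowSums((mat[, g0, drop = FALSE] - m0)^2) +
    rowSums((mat[, g1, drop = FALSE] - m1)^2)
  df2 <- n0 + n1 - 2L
  f <- (ss_between / 1) / (ss_within / df2)
  p <- stats::pf(f, 1, df2, lower.tail = FALSE)
  # zero residual variance: separation decides the p-value
  degenerate <- ss_within == 0
  p[degenerate & ss_between == 0] <- 1
  p[degenerate & ss_between > 0] <- 0
  p
}

#' Call differential expression per treatment condition
#'
#' For each gene: a p-value from [de_test()] against control, the signed
#' fold change of the log2 means, the significance flag `p < alpha` and
#' the intensity flag `|FC| > fc_threshold` (evaluated within the
#' significant set, the denominator used for the printed percentages).
#' Optionally Benjamini-Hochberg adjusted q-values are added; the raw-p
#' threshold remains the default significance rule.
#'
#' @param gene_matrix Gene x array matrix of normalized log2 values.
#' @param design data.frame `array_id`, `condition` covering every column.
#' @param condition Treatment condition to contrast against `"control"`.
#' @param alpha Significance level on the raw p-value.
#' @param fc_threshold Linear fold-change filter (strict `>`).
#' @param method Test passed to [de_test()].
#' @param fdr Also compute BH q-values (`q_bh` column).
#' @return data.frame per gene: `target_id`, `condition`, `p_value`,
#'   (`q_bh`,) `signed_fc`, `direction`, `significant`, `passes_fc`.
#' @export
call_de <- function(gene_matrix, design, condition, alpha = 0.001,
                    fc_threshold = 2, method = c("anova", "kruskal"),
                    fdr = TRUE) {
  method <- match.arg(method)
  assert_columns(design, c("array_id", "condition"), "design table")
  if (!condition %in% design$condition) {
    input_error("call_de: condition '%s' absent from the design", condition)
  }
  if (!"control" %in% design$condition) {
    input_error("call_de: design has no control arrays")
  }
  ctl_arrays <- design$array_id[design$condition == "control"]
  trt_arrays <- design$array_id[design$condition == condition]
  missing <- setdiff(c(ctl_arrays, trt_arrays), colnames(gene_matrix))
  if (length(missing) > 0) {
    input_error("call_de: design arrays missing from the matrix: %s",
                paste(missing, collapse = ", "))
  }
  if (length(ctl_arrays) < 2 || length(trt_arrays) < 2) {
    input_error("call_de: need >= 2 arrays per group")
  }
  sub <- gene_matrix[, c(ctl_arrays, trt_arrays), drop = FALSE]
  group <- rep(c(0L, 1L), c(length(ctl_arrays), length(trt_arrays)))
  p <- if (method == "anova") {
    row_f_test(sub, group)
  } else {
    apply(sub, 1, function(v) {
      stats::kruskal.test(v, factor(group))$p.value
    })
  }
  fc <- signed_fold_change(
    rowMeans(sub[, group == 1L, drop = FALSE]),
    rowMeans(sub[, group == 0L, drop = FALSE])
  )
  out <- data.frame(
    target_id = rownames(gene_matrix),
    condition = condition,
    p_value = p,
    signed_fc = fc,
    direction = ifelse(fc > 0, "up", "down"),
    significant = p < alpha,
    passes_fc = p < alpha & abs(fc) > fc_threshold,
    stringsAsFactors = FALSE
  )
  if (fdr) {
    out$q_bh <- stats::p.adjust(p, method = "BH")
    out <- out[, c("target_id", "condition", "p_value", "q_bh", "signed_fc",
                   "direction", "significant", "passes_fc")]
  }
  rownames(out) <- NULL
  out
}

#' Summary counts and printed percentages for a DE table
#'
#' @param de Output of [call_de()].
#' @return One-row data.frame: condition, number tested, significant
#'   count, FC-passing count, and the FC-passing percentage with the
#'   significant set as denominator (the convention used in the reports).
#' @export
de_summary <- function(de) {
  assert_columns(de, c("condition", "significant", "passes_fc"), "DE table")
  n_sig <- sum(de$significant)
  n_fc <- sum(de$passes_fc)
  data.frame(
    condition = de$condition[1],
    n_tested = nrow(de),
    n_significant = n_sig,
    n_passes_fc = n_fc,
    pct_passes_fc = if (n_sig > 0) format_percent(n_fc, n_sig) else NA_character_,
    stringsAsFactors = FALSE
  )
}

#' Partition two significant-gene sets into exclusive and common sets
#'
#' @param set_a,set_b Character vectors of gene ids (duplicates ignored).
#' @return A list of class `venn_partition`: `exclusive_a`, `common`,
#'   `exclusive_b`, plus a `counts` data.frame.
#' @examples
#' venn_partition(c("g1", "g2", "g3"), c("g2", "g3", "g4"))$counts
#' @export
venn_partition <- function(set_a, set_b) {
  a <- unique(as.character(set_a))
  b <- unique(as.character(set_b))
  out <- list(
    exclusive_a = setdiff(a, b),
    common = intersect(a, b),
    exclusive_b = setdiff(b, a)
  )
  out$counts <- data.frame(
    n_a = length(a),
    n_b = length(b),
    n_exclusive_a = length(out$exclusive_a),
    n_common = length(out$common),
    n_exclusive_b = length(out$exclusive_b)
  )
  class(out) <- "venn_partition"
  out
}

#' @export
print.venn_partition <- function(x, ...) {
  with(x$counts, cat(sprintf(
    "venn partition: |A| = %d (%d exclusive), |B| = %d (%d exclusive), common = %d\n",
    n_a, n_exclusive_a, n_b, n_exclusive_b, n_common)))
  invisible(x)
}
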