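#' Single-channel array quality control and summarization
#'
#' Probe-level scans (foreground/background intensity and their pixel SDs)
#' are scored with a per-spot quality ratio, background corrected, log2
#' transformed, percentile-shift normalized, filtered on the spread of
#' per-probe SDs, checked by probe-pair Pearson correlation, and
#' summarized to gene level (mean of probes within a probe set, median
#' across probe sets of a gene).
#'
#' @name array_qc
NULL

#' Per-spot quality ratio
#'
#' The signal-to-noise score of a spot: the background-corrected intensity
#' divided by the summed pixel standard deviations,
#' `R = (SI - SB) / (SDI + SDB)`. It is invariant under a common positive
#' rescaling of all four inputs and negative when background exceeds
#' signal.
#'
#' @param SI,SB Foreground and background intensity (linear units).
#' @param SDI,SDB Their pixel standard deviations (linear units).
#' @return Numeric vector of ratios; spots with `SDI + SDB == 0` are `NA`
#'   with a warning (the ratio is undefined there and such spots must be
#'   flagged, not passed through).
#' @examples
#' spot_quality_ratio(100, 20, 5, 3)  # 10
#' @export
spot_quality_ratio <- function(SI, SB, SDI, SDB) {
  if (any(c(SI, SB, SDI, SDB) < 0, na.rm = TRUE)) {
    input_error("spot_quality_ratio: intensities and SDs must be non-negative")
  }
  denom <- SDI + SDB
  bad <- !is.na(denom) & denom == 0
  if (any(bad)) {
    warning(sprintf("spot_quality_ratio: %d spot(s) with SDI + SDB == 0 flagged as NA",
                    sum(bad)))
  }
  out <- (SI - SB) / denom
  out[bad] <- NA_real_
  out
}

#' Background-correct spot intensities and build the log2 matrix
#'
#' Computes `log2(max(SI - SB, floor))` per spot and arranges the values
#' as a probe x array matrix. The floor (default 1 linear unit, i.e. log2
#' value 0) keeps spots whose background exceeds the signal finite.
#'
#' @param spots Spot table with columns `array_id`, `probe_id`, `SI`, `SB`.
#' @param floor Linear-scale floor applied before the log.
#' @return A numeric matrix (probes x arrays) with dimnames, carrying
#'   attribute `normalized = FALSE`.
#' @export
background_correct_and_log <- function(spots, floor = 1) {
  assert_columns(spots, c("array_id", "probe_id", "SI", "SB"), "spot table")
  if (floor <= 0) {
    input_error("background_correct_and_log: floor must be positive")
  }
  key <- paste(spots$array_id, spots$probe_id)
  if (anyDuplicated(key)) {
    input_error("background_correct_and_log: duplicate (array, probe) entries")
  }
  probes <- unique(spots$probe_id)
  arrays <- unique(spots$array_id)
  if (nrow(spots) != length(probes) * length(arrays)) {
    input_error("background_correct_and_log: spots do not cover a full probe x array grid")
  }
  value <- log2(pmax(spots$SI - spots$SB, floor))
  mat <- matrix(NA_real_, nrow = length(probes), ncol = length(arrays),
                dimnames = list(probes, arrays))
  mat[cbind(match(spots$probe_id, probes), match(spots$array_id, arrays))] <- value
  attr(mat, "normalized") <- FALSE
  mat
}

#' Percentile-shift normalization
#'
#' Each array (column) is shifted by its own percentile value, computed
#' with linear interpolation; at the default 50th percentile every
#' column's median becomes exactly zero. The operation is idempotent.
#'
#' @param mat Probe x array log2 matrix.
#' @param percentile Percentile in (0, 100) to subtract per column.
#' @return The shifted matrix with attribute `normalized = TRUE`.
#' @examples
#' m <- cbind(a = c(1, 2, 3))
#' percentile_shift_normalize(m)[, 1]  # -1 0 1
#' @export
percentile_shift_normalize <- function(mat, percentile = 50) {
  if (!is.matrix(mat) || !is.numeric(mat)) {
    input_error("percentile_shift_normalize: a numeric matrix is required")
  }
  if (percentile <= 0 || percentile >= 100) {
    input_error("percentile_shift_normalize: percentile must be in (0, 100)")
  }
  if (nrow(mat) < 2) {
    input_error("percentile_shift_normalize: need at least 2 values per array")
  }
  shifts <- apply(mat, 2, stats::quantile, probs = percentile / 100,
                  na.rm = TRUE, names = FALSE, type = 7)
  out <- sweep(mat, 2, shifts, `-`)
  attr(out, "normalized") <- TRUE
  out
}

#' Filter probes on the spread of their across-array SD
#'
#' Per-probe standard deviations across arrays are computed and probes
#' whose SD falls outside the `[low_pct, high_pct]` percentile band of
#' the SD distribution are removed: near-constant probes (dead spots) and
#' hyper-variable probes (noise) both go. Bounds are inclusive.
#'
#' @param mat Normalized probe x array matrix (>= 2 arrays).
#' @param low_pct,high_pct Percentile band to retain, `0 <= low < high
#'   <= 100`.
#' @return A list: `retained` (probe ids), `removed` (probe ids),
#'   `sd` (named per-probe SDs), and `report` (counts plus the removal
#'   percentage as printed, see [format_percent()]).
#' @export
sd_filter <- function(mat, low_pct = 5, high_pct = 95) {
  if (low_pct >= high_pct) {
    input_error("sd_filter: empty band (low_pct >= high_pct)")
  }
  if (ncol(mat) < 2) {
    input_error("sd_filter: need >= 2 arrays to compute per-probe SD")
  }
  sds <- apply(mat, 1, stats::sd, na.rm = TRUE)
  bounds <- stats::quantile(sds, probs = c(low_pct, high_pct) / 100,
                            na.rm = TRUE, names = FALSE, type = 7)
  keep <- sds >= bounds[1] & sds <= bounds[2]
  report <- data.frame(
    n_total = length(sds),
    n_removed = sum(!keep),
    n_retained = sum(keep),
    pct_removed = format_percent(sum(!keep), length(sds)),
    stringsAsFactors = FALSE
  )
  list(retained = rownames(mat)[keep], removed = rownames(mat)[!keep],
       sd = sds, report = report)
}

#' Deterministically pick two of a target's three probes
#'
#' Probe-pair QC uses a pseudo-random but reproducible choice of two of
#' the three technical probes of an annotated target.
#'
#' @param probe_ids Exactly 3 probe ids; sets of one probe are
#'   non-assessable and return `NULL`.
#' @param seed Integer seed making the choice reproducible.
#' @return Character vector of 2 probe ids, or `NULL` for 1-probe sets.
#' @export
probe_pair_select <- function(probe_ids, seed) {
  if (length(probe_ids) == 1) {
    return(NULL)
  }
  if (length(probe_ids) != 3) {
    input_error("probe_pair_select: expected 1 or 3 probe ids, got %d",
                length(probe_ids))
  }
  withr::local_seed(seed)
  sort(sample(probe_ids, 2))
}

#' Bin a Pearson correlation coefficient
#'
#' Bins partition `[-1, 1]`: strong `r > 0.7`, moderate `0.5 < r <= 0.7`,
#' weak_positive `0 <= r <= 0.5`, negative `r < 0`.
#'
#' @param r Numeric vector of correlations.
#' @return Character vector of bins (`NA` stays `NA`).
#' @export
bin_correlation <- function(r) {
  out <- rep(NA_character_, length(r))
  out[!is.na(r) & r < 0] <- "negative"
  out[!is.na(r) & r >= 0 & r <= 0.5] <- "weak_positive"
  out[!is.na(r) & r > 0.5 & r <= 0.7] <- "moderate"
  out[!is.na(r) & r > 0.7] <- "strong"
  out
}

#' Probe-pair Pearson correlation across arrays
#'
#' @param mat Normalized, filtered probe x array matrix (>= 3 arrays).
#' @param pair Character vector of 2 probe ids present in `mat`.
#' @param target_id Optional target label carried into the record.
#' @return A one-row data.frame: `target_id`, `probe_1`, `probe_2`, `r`,
#'   `bin`, `flagged` (TRUE when either probe has zero variance, making r
#'   undefined).
#' @export
probe_pair_correlation <- function(mat, pair, target_id = NA_character_) {
  if (length(pair) != 2 || !all(pair %in% rownames(mat))) {
    input_error("probe_pair_correlation: pair must name two probes in the matrix")
  }
  if (ncol(mat) < 3) {
    input_error("probe_pair_correlation: need >= 3 arrays")
  }
  x <- mat[pair[1], ]
  y <- mat[pair[2], ]
  flagged <- stats::sd(x) == 0 || stats::sd(y) == 0
  r <- if (flagged) NA_real_ else stats::cor(x, y)
  data.frame(target_id = target_id, probe_1 = pair[1], probe_2 = pair[2],
             r = r, bin = bin_correlation(r), flagged = flagged,
             stringsAsFactors = FALSE)
}

#' Probe-pair QC over all annotated targets
#'
#' Runs [probe_pair_select()] and [probe_pair_correlation()] for every
#' 3-probe target whose selected probes survived filtering, and summarizes
#' the correlation-bin distribution.
#'
#' @param mat Normalized probe x array matrix (filtered).
#' @param probesets data.frame `target_id`, `probe_id`.
#' @param seed Seed for the per-target probe-pair choice.
#' @return A list: `records` (one row per assessable target), `bins`
#'   (bin, count, percent of assessable targets) and
#'   `n_non_assessable` (1-probe targets or pairs lost to filtering).
#' @export
probe_pair_qc <- function(mat, probesets, seed = 1L) {
  assert_columns(probesets, c("target_id", "probe_id"), "probe-set table")
  sets <- split(probesets$probe_id, probesets$target_id)
  records <- list()
  n_skip <- 0L
  for (tid in names(sets)) {
    ids <- sets[[tid]]
    if (length(ids) != 3) {
      n_skip <- n_skip + 1L
      next
    }
    pair <- probe_pair_select(ids, seed = seed + length(records))
    if (!all(pair %in% rownames(mat))) {
      n_skip <- n_skip + 1L
      next
    }
    records[[tid]] <- probe_pair_correlation(mat, pair, target_id = tid)
  }
  records <- if (length(records)) do.call(rbind, records) else
    data.frame(target_id = character(), probe_1 = character(),
               probe_2 = character(), r = numeric(), bin = character(),
               flagged = logical(), stringsAsFactors = FALSE)
  rownames(records) <- NULL
  assessed <- records[!records$flagged, , drop = FALSE]
  bins <- data.frame(bin = c("strong", "moderate", "weak_positive", "negative"),
                     stringsAsFactors = FALSE)
  bins$count <- vapply(bins$bin, function(b) sum(assessed$bin == b), 1L)
  bins$percent <- if (nrow(assessed) > 0) {
    format_percent(bins$count, nrow(assessed), percent = FALSE)
  } else {
    NA_real_
  }
  list(records = records, bins = bins, n_non_assessable = n_skip)
}

#' Summarize probe-level values to gene level
#'
#' Within a probe set the retained probes are averaged per array; when a
#' gene is represented by several probe sets their values are combined by
#' the median. Genes whose probes were all filtered out are dropped and
#' reported.
#'
#' @param mat Normalized probe x array matrix restricted to retained
#'   probes.
#' @param probesets data.frame `target_id`, `probe_id`, optionally
#'   `probe_set_id` (defaults to one probe set per target).
#' @return A list: `matrix` (target x array), `dropped` (target ids with
#'   no surviving probe).
#' @export
summarize_gene_level <- function(mat, probesets) {
  assert_columns(probesets, c("target_id", "probe_id"), "probe-set table")
  ps <- probesets
  if (is.null(ps$probe_set_id)) {
    ps$probe_set_id <- ps$target_id
  }
  ps <- ps[ps$probe_id %in% rownames(mat), , drop = FALSE]
  all_targets <- unique(probesets$target_id)
  kept_targets <- unique(ps$target_id)

  set_key <- paste(ps$target_id, ps$probe_set_id, sep = "\r")
  set_means <- rowsum(mat[ps$probe_id, , drop = FALSE], set_key) /
    as.vector(table(set_key)[sort(unique(set_key))])
  set_target <- sub("\r.*$", "", rownames(set_means))

  out <- do.call(rbind, lapply(kept_targets, function(tid) {
    rows <- set_means[set_target == tid, , drop = FALSE]
    apply(rows, 2, stats::median)
  }))
  rownames(out) <- kept_targets
  attr(out, "normalized") <- attr(mat, "normalized")
  list(matrix = out, dropped = setdiff(all_targets, kept_targets))
}
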