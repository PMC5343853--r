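test_that("spot quality ratio follows (SI - SB)/(SDI + SDB)", {
  expect_equal(spot_quality_ratio(100, 20, 5, 3), 10)
  expect_equal(spot_quality_ratio(50, 50, 4, 4), 0)
  # invariant under positive rescaling of all four inputs
  expect_equal(spot_quality_ratio(200, 40, 10, 6), 10)
  withr::with_seed(1, {
    si <- runif(20, 10, 100); sb <- runif(20, 0, 10)
    sdi <- runif(20, 1, 5); sdb <- runif(20, 1, 5)
  })
  for (s in c(0.5, 3, 17)) {
    expect_equal(spot_quality_ratio(s * si, s * sb, s * sdi, s * sdb),
                 spot_quality_ratio(si, sb, sdi, sdb))
  }
  # background above signal gives a negative ratio
  expect_lt(spot_quality_ratio(10, 30, 2, 2), 0)
  # undefined ratio is flagged, not passed through
  expect_warning(r <- spot_quality_ratio(10, 5, 0, 0), "flagged")
  expect_true(is.na(r))
  expect_error(spot_quality_ratio(-1, 0, 1, 1), "non-negative")
})

test_that("background correction floors and logs spot intensities", {
  spots <- data.frame(array_id = "a1", probe_id = c("p1", "p2", "p3"),
                      SI = c(1024, 10, 3), SB = c(0, 10, 7))
  m <- background_correct_and_log(spots)
  expect_equal(m["p1", "a1"], 10)
  expect_equal(m["p2", "a1"], 0)   # SI <= SB hits the floor, log2(1) = 0
  expect_equal(m["p3", "a1"], 0)
  expect_false(attr(m, "normalized"))
  dup <- rbind(spots, spots[1, ])
  expect_error(background_correct_and_log(dup), "duplicate")
  partial <- rbind(spots,
                   data.frame(array_id = "a2", probe_id = "p1",
                              SI = 5, SB = 1))
  expect_error(background_correct_and_log(partial), "grid")
})

test_that("percentile-shift normalization zeroes each column median", {
  m <- cbind(a = c(1, 2, 3), b = c(5, 5, 5))
  n <- percentile_shift_normalize(m)
  expect_equal(unname(n[, "a"]), c(-1, 0, 1))
  expect_equal(unname(n[, "b"]), c(0, 0, 0))
  expect_true(attr(n, "normalized"))

  withr::with_seed(2, big <- matrix(rnorm(3000), nrow = 500, ncol = 6))
  rownames(big) <- sprintf("p%03d", 1:500)
  nb <- percentile_shift_normalize(big)
  expect_true(all(abs(apply(nb, 2, median)) < 1e-12))
  # idempotence
  expect_equal(percentile_shift_normalize(nb), nb, ignore_attr = TRUE)
  # a non-median percentile shifts by that quantile instead
  q25 <- percentile_shift_normalize(big, percentile = 25)
  expect_true(all(abs(apply(q25, 2, quantile, 0.25) ) < 1e-12))
})

test_that("sd filter removes probes outside the percentile band", {
  withr::with_seed(3, m <- matrix(rnorm(8000), nrow = 1000, ncol = 8))
  rownames(m) <- sprintf("p%04d", 1:1000)
  all_kept <- sd_filter(m, 0, 100)
  expect_equal(length(all_kept$retained), 1000)

  band <- sd_filter(m, 5, 95)
  # continuous SDs: removal fraction matches band width within ties
  expect_equal(length(band$removed), 100, tolerance = 0.02)
  expect_equal(band$report$n_removed + band$report$n_retained, 1000)

  # a constant probe has SD zero and falls below any positive low cut
  m2 <- m
  m2["p0001", ] <- 7
  expect_true("p0001" %in% sd_filter(m2, 5, 95)$removed)
  expect_error(sd_filter(m, 95, 5), "empty band")
  expect_error(sd_filter(m[, 1, drop = FALSE], 5, 95), ">= 2 arrays")
})

test_that("probe pair selection is deterministic and covers all pairs", {
  ids <- c("x", "y", "z")
  p1 <- probe_pair_select(ids, seed = 7)
  expect_identical(p1, probe_pair_select(ids, seed = 7))
  expect_length(p1, 2)
  pairs <- unique(vapply(1:50, function(s)
    paste(probe_pair_select(ids, seed = s), collapse = "+"), ""))
  expect_setequal(pairs, c("x+y", "x+z", "y+z"))
  # single-probe sets are non-assessable, not an error
  expect_null(probe_pair_select("solo", seed = 1))
  expect_error(probe_pair_select(c("a", "b"), seed = 1), "1 or 3")
})

test_that("probe pair correlation and binning behave on known cases", {
  m <- rbind(p1 = c(1, 2, 3, 4), p2 = c(1, 2, 3, 4), p3 = c(-1, -2, -3, -4),
             p4 = c(1, 3, 2, 4), p5 = c(2, 2, 2, 2))
  colnames(m) <- paste0("a", 1:4)
  expect_equal(probe_pair_correlation(m, c("p1", "p2"))$r, 1)
  expect_equal(probe_pair_correlation(m, c("p1", "p2"))$bin, "strong")
  expect_equal(probe_pair_correlation(m, c("p1", "p3"))$r, -1)
  expect_equal(probe_pair_correlation(m, c("p1", "p3"))$bin, "negative")
  # hand-computed: cov = 4/3, sd^2 = 5/3 each, r = 0.8
  expect_equal(probe_pair_correlation(m, c("p1", "p4"))$r, 0.8)
  flagged <- probe_pair_correlation(m, c("p1", "p5"))
  expect_true(flagged$flagged)
  expect_true(is.na(flagged$r))
})

test_that("correlation bins partition [-1, 1]", {
  r <- seq(-1, 1, by = 0.001)
  bins <- bin_correlation(r)
  expect_false(anyNA(bins))
  expect_equal(bin_correlation(c(0.7, 0.7 + 1e-9, 0.5, 0, -1e-9)),
               c("moderate", "strong", "weak_positive", "weak_positive",
                 "negative"))
})

test_that("probe-pair QC summarizes bins over assessable targets", {
  cfg <- synth_config(n_targets = 60, n_arrays_per_condition = 3,
                      single_probe_fraction = 0.3, seed = 9)
  arr <- generate_array_experiment(cfg)
  mat <- percentile_shift_normalize(background_correct_and_log(arr$spots))
  qc <- probe_pair_qc(mat, arr$probesets[arr$probesets$annotated, ], seed = 1)
  n3 <- sum(table(arr$probesets$target_id[arr$probesets$annotated]) == 3)
  expect_equal(nrow(qc$records) + qc$n_non_assessable, n3)
  assessed <- sum(!qc$records$flagged)
  expect_equal(sum(qc$bins$count), assessed)
})

test_that("gene-level summarization is mean within set, median across sets", {
  m <- rbind(g1_a = 2, g1_b = 4, g1_c = 6)
  colnames(m) <- "a1"
  ps <- data.frame(target_id = "g1", probe_id = c("g1_a", "g1_b", "g1_c"))
  expect_equal(unname(summarize_gene_level(m, ps)$matrix["g1", ]), 4)

  # several probe sets of one gene combine by the median
  m2 <- rbind(s1 = 1, s2 = 5, s3 = 9)
  colnames(m2) <- "a1"
  ps2 <- data.frame(target_id = "g", probe_id = c("s1", "s2", "s3"),
                    probe_set_id = c("ps1", "ps2", "ps3"))
  expect_equal(unname(summarize_gene_level(m2, ps2)$matrix["g", ]), 5)

  # single surviving probe passes through; fully filtered genes are dropped
  m3 <- rbind(p1 = c(1.5, 2.5))
  colnames(m3) <- c("a1", "a2")
  ps3 <- data.frame(target_id = c("g1", "g1", "g2"),
                    probe_id = c("p1", "p_gone", "p_gone2"))
  out <- summarize_gene_level(m3, ps3)
  expect_equal(unname(out$matrix["g1", ]), c(1.5, 2.5))
  expect_equal(out$dropped, "g2")
})

test_that("summarization commutes with array-column permutation", {
  cfg <- synth_config(n_targets = 40, n_arrays_per_condition = 2, seed = 6)
  arr <- generate_array_experiment(cfg)
  mat <- background_correct_and_log(arr$spots)
  ref <- summarize_gene_level(mat, arr$probesets)$matrix
  perm <- sample(ncol(mat))
  got <- summarize_gene_level(mat[, perm], arr$probesets)$matrix
  expect_equal(got, ref[, perm])
})
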